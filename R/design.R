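#' Construct a multi-study design
#'
#' A study design records, for each RNA-seq study entering the meta-analysis,
#' the number of biological replicates in each of the two conditions
#' (condition 1 = cases, condition 2 = controls). Replicate totals per study
#' are the sole input to the study weights used by all combination methods.
#'
#' @param study Character vector of study identifiers (unique, non-empty).
#' @param cases Integer vector of case (condition 1) replicate counts, >= 1.
#' @param controls Integer vector of control (condition 2) replicate counts, >= 1.
#'
#' @return A `data.frame` of class `study_design` with columns `study`,
#'   `cases`, `controls`.
#' @examples
#' study_design(c("A", "B", "C"), cases = c(10, 15, 12), controls = c(10, 10, 16))
#' @export
study_design <- function(study, cases, controls) {
  study <- as.character(study)
  if (length(study) < 1L) stop("a design needs at least one study")
  if (anyDuplicated(study)) stop("duplicate study identifiers: ",
                                 paste(unique(study[duplicated(study)]), collapse = ", "))
  if (length(cases) != length(study) || length(controls) != length(study))
    stop("'cases' and 'controls' must match the number of studies")
  cases <- as.integer(cases); controls <- as.integer(controls)
  if (anyNA(cases) || anyNA(controls) || any(cases < 1L) || any(controls < 1L))
    stop("replicate counts must be positive integers")
  structure(
    data.frame(study = study, cases = cases, controls = controls,
               stringsAsFactors = FALSE),
    class = c("study_design", "data.frame")
  )
}

#' Read a design file
#'
#' Expects a delimited text file with header columns `study`, `cases`,
#' `controls` (case-insensitive).
#'
#' @param path Path to the design file.
#' @param sep Field delimiter, tab by default.
#' @return A [study_design()] object.
#' @export
read_design <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("study", "cases", "controls")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design file is missing column(s): ",
                         paste(miss, collapse = ", "))
  study_design(df$study, df$cases, df$controls)
}

replicate_totals <- function(design) {
  stats::setNames(design$cases + design$controls, design$study)
}

assert_design <- function(design) {
  if (!inherits(design, "study_design"))
    stop("'design' must be created with study_design() or read_design()")
  invisible(design)
}
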