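#' Read a per-study results table
#'
#' Delimited text with a header containing (case-insensitively) `gene`,
#' `pvalue` and `log2FC` columns. Duplicate gene ids, p-values outside
#' `[0, 1]` and unparseable numbers are rejected with informative errors.
#'
#' @param path Path to the file.
#' @param sep Field delimiter (default tab).
#' @return data.frame with columns `gene`, `pvalue`, `log2FC`.
#' @export
read_study_results <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(col) {
    i <- match(col, nm)
    if (is.na(i)) stop("'", path, "' is missing column '", col, "'")
    df[[i]]
  }
  gene <- as.character(pick("gene"))
  pvalue <- pick("pvalue")
  log2fc <- pick("log2fc")
  bad <- which(!is.finite(suppressWarnings(as.numeric(pvalue))) |
                 !is.finite(suppressWarnings(as.numeric(log2fc))))
  if (length(bad))
    stop("'", path, "' has unparseable numbers at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  pvalue <- as.numeric(pvalue); log2fc <- as.numeric(log2fc)
  out <- data.frame(gene = gene, pvalue = pvalue, log2FC = log2fc,
                    stringsAsFactors = FALSE)
  validate_study_table(out, basename(path))
  out
}

#' Write / read a meta-analysis result table
#'
#' Tab-separated, deterministic column order, combined p-values in
#' scientific notation with 6 significant digits, missing values as `NA`.
#' `read_meta_table(write_meta_table(x))` reproduces all modeled fields.
#'
#' @param results A [run_meta()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(results, path) {
  out <- results
  for (col in c("pvalue_combined", "fdr"))
    out[[col]] <- formatC(out[[col]], format = "e", digits = 5)
  for (col in c("Ng", "mean_abs_log2FC"))
    out[[col]] <- formatC(out[[col]], format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_meta_table
#' @export
read_meta_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(effect = "character"))
}

#' Write a simulated dataset to a directory
#'
#' One counts TSV per study (first column `gene`), a `truth.tsv`
#' (`gene`, `is_de`, `true_direction`, `true_lfc`), a `design.tsv`, and a
#' YAML `manifest.yaml` recording the simulation parameters and seeds.
#'
#' @param dataset A [simulate_counts()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(dataset, dir) {
  if (!inherits(dataset, "sim_dataset")) stop("'dataset' must be a sim_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(dataset$studies)) {
    st <- dataset$studies[[s]]
    df <- data.frame(gene = rownames(st$counts), st$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(s, "_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = colnames(st$counts), condition = st$labels),
      file.path(dir, paste0(s, "_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- dataset$params$design
  utils::write.table(as.data.frame(d), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    G = dataset$params$G, sigma = dataset$params$sigma,
    n_de = sum(dataset$params$is_de),
    studies = as.list(stats::setNames(paste0("(", d$cases, ",", d$controls, ")"),
                                      d$study)),
    params_seed = dataset$params$seed, counts_seed = dataset$seed)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a counts TSV (first column gene id)
#'
#' @param path Path to a counts file as written by [write_counts()].
#' @return Numeric matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
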