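#' Assemble per-study evidence into a gene-by-study container
#'
#' Builds the meta-analysis input from one result table per study. The gene
#' universe is the union of the genes reported by the individual studies
#' (genes need not be present everywhere; weights are later renormalized
#' over the studies a gene was observed in). Directions are derived from the
#' sign of the study log2 fold change, with an exact zero counted as "+".
#'
#' @param tables Named list of per-study data.frames with columns `gene`,
#'   `pvalue`, `log2FC` (as produced by [run_study_de()] or
#'   [read_study_results()]). Names must match the design's study ids.
#' @param design A [study_design()]; its study order fixes the column order
#'   and the rendering of effect strings.
#' @param intersect If `TRUE`, restrict the universe to genes present in
#'   every study instead of the union.
#'
#' @return An object of class `gene_evidence`: a list with `genes`,
#'   `studies`, and gene-by-study matrices `pvalues` and `log2fc`
#'   (`NA` where a gene is absent from a study).
#' @export
assemble_evidence <- function(tables, design, intersect = FALSE) {
  assert_design(design)
  if (length(tables) < 1L) stop("at least one study table is required")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list (names = study identifiers)")
  extra <- setdiff(names(tables), design$study)
  if (length(extra)) stop("study tables not in the design: ",
                          paste(extra, collapse = ", "))
  missing_st <- setdiff(design$study, names(tables))
  if (length(missing_st)) stop("design studies without a table: ",
                               paste(missing_st, collapse = ", "))
  tables <- tables[design$study]
  for (s in names(tables)) validate_study_table(tables[[s]], s)

  gene_sets <- lapply(tables, function(t) as.character(t$gene))
  genes <- if (intersect) Reduce(intersect, gene_sets) else
    unique(unlist(gene_sets, use.names = FALSE))
  if (length(genes) == 0L) stop("empty gene universe")

  S <- nrow(design)
  P <- matrix(NA_real_, length(genes), S,
              dimnames = list(genes, design$study))
  L <- P
  for (s in design$study) {
    t <- tables[[s]]
    idx <- match(as.character(t$gene), genes)
    ok <- !is.na(idx)
    P[idx[ok], s] <- t$pvalue[ok]
    L[idx[ok], s] <- t$log2FC[ok]
  }
  structure(list(genes = genes, studies = design$study,
                 pvalues = P, log2fc = L),
            class = "gene_evidence")
}

validate_study_table <- function(t, name = "study") {
  need <- c("gene", "pvalue", "log2FC")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("table '", name, "' is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(t$gene)) {
    dup <- unique(t$gene[duplicated(t$gene)])
    stop("table '", name, "' has duplicated gene id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(!is.finite(t$pvalue)) || any(t$pvalue < 0 | t$pvalue > 1))
    stop("table '", name, "' has p-values outside [0, 1]")
  if (any(!is.finite(t$log2FC)))
    stop("table '", name, "' has non-finite log2FC values")
  invisible(t)
}

#' @export
print.gene_evidence <- function(x, ...) {
  cat("gene_evidence:", length(x$genes), "genes x", length(x$studies),
      "studies (", sum(!is.na(x$pvalues)), "observations )\n")
  invisible(x)
}
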