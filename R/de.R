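# Per-study two-group differential expression: CPM filter -> TMM ->
# common/tagwise NB dispersion -> NB GLM with likelihood-ratio test.
# The heavy lifting is delegated to edgeR; this file defines the stable
# surface the rest of the package (and the CLI) is written against.

normalize_labels <- function(labels, n) {
  if (length(labels) != n)
    stop("condition labels must match the number of samples")
  lab <- as.character(labels)
  case <- lab %in% c("1", "case", "cases")
  ctrl <- lab %in% c("2", "control", "controls")
  if (!all(case | ctrl))
    stop("labels must be 1/'case' (condition 1) or 2/'control' (condition 2)")
  if (!any(case) || !any(ctrl))
    stop("both conditions must be represented")
  factor(ifelse(case, "case", "control"), levels = c("control", "case"))
}

check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(colSums(counts) <= 0)) stop("zero library size in counts")
  counts
}

#' Counts per million
#'
#' Scales each count by its sample's library size (column sum) times 1e6.
#'
#' @param counts Non-negative gene-by-sample count matrix.
#' @return Matrix of CPM values, same dimensions.
#' @export
cpm <- function(counts) {
  counts <- check_counts(counts)
  sweep(counts, 2L, colSums(counts), "/") * 1e6
}

#' Remove lowly expressed genes
#'
#' Keeps genes whose CPM reaches `cpm_threshold` in at least `min_samples`
#' samples. Low-expression filtering is what makes the per-study p-values
#' approximately uniform under the null, the assumption the downstream
#' inverse-normal combination rests on.
#'
#' @param counts Gene-by-sample count matrix.
#' @param cpm_threshold CPM cutoff (default 0.85).
#' @param min_samples Minimum number of samples reaching the cutoff;
#'   defaults to the smaller group size when `labels` are given, else 1.
#' @param labels Optional condition labels used for the `min_samples`
#'   default.
#' @return The filtered count matrix, with a logical attribute `kept`
#'   (named by gene) recording the decision for every input gene.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.85,
                                  min_samples = NULL, labels = NULL) {
  counts <- check_counts(counts)
  if (cpm_threshold < 0) stop("'cpm_threshold' must be non-negative")
  if (is.null(min_samples)) {
    min_samples <- if (is.null(labels)) 1L else
      min(table(normalize_labels(labels, ncol(counts))))
  }
  if (min_samples < 1L) stop("'min_samples' must be at least 1")
  keep <- rowSums(cpm(counts) >= cpm_threshold) >= min_samples
  if (!any(keep)) stop("empty matrix after filtering")
  out <- counts[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (via [edgeR::calcNormFactors()]):
#' per-sample factors correcting for RNA composition so that, combined with
#' library sizes, effective sizes are comparable across samples. Factors
#' have geometric mean 1.
#'
#' @param counts Gene-by-sample count matrix (>= 2 samples).
#' @return Numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts) {
  counts <- check_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  edgeR::calcNormFactors(counts, method = "TMM")
}

#' Common and tagwise NB dispersion estimates
#'
#' Cox-Reid adjusted profile likelihood estimates: a single common
#' dispersion shared by all genes, and per-gene (tagwise) dispersions
#' shrunk toward the common value with a fixed prior weight
#' (`prior_df` residual degrees of freedom worth of shrinkage).
#'
#' @param counts Filtered count matrix.
#' @param labels Condition labels (see [run_study_de()]).
#' @param factors Optional TMM factors; computed if missing.
#' @param prior_df Prior degrees of freedom for tagwise shrinkage
#'   (default 10).
#' @return List with elements `common` (scalar) and `tagwise`
#'   (per-gene vector), all non-negative.
#' @export
estimate_dispersions <- function(counts, labels, factors = NULL,
                                 prior_df = 10) {
  counts <- check_counts(counts)
  group <- normalize_labels(labels, ncol(counts))
  if (all(table(group) < 2L))
    stop("dispersion not estimable: no condition has replication")
  y <- edgeR::DGEList(counts = counts, group = group)
  y$samples$norm.factors <- if (is.null(factors)) tmm_factors(counts) else factors
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateGLMCommonDisp(y, design)
  y <- edgeR::estimateGLMTagwiseDisp(y, design, prior.df = prior_df)
  list(common = y$common.dispersion, tagwise = y$tagwise.dispersion)
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Fits, per gene, a log-linear NB model with an intercept and a condition
#' effect (offsets = log effective library size) and tests the condition
#' coefficient against the intercept-only null by a likelihood-ratio test
#' (chi-square, 1 df). Delegates to [edgeR::glmFit()]/[edgeR::glmLRT()].
#' log2FC is positive when cases exceed controls.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions Per-gene dispersion vector (or list as returned by
#'   [estimate_dispersions()], whose `tagwise` component is used).
#' @return data.frame with columns `gene`, `pvalue`, `log2FC`, `direction`.
#' @export
nb_glm_lrt <- function(counts, labels, factors = NULL, dispersions) {
  counts <- check_counts(counts)
  group <- normalize_labels(labels, ncol(counts))
  if (is.list(dispersions)) dispersions <- dispersions$tagwise
  y <- edgeR::DGEList(counts = counts, group = group)
  y$samples$norm.factors <- if (is.null(factors)) tmm_factors(counts) else factors
  design <- stats::model.matrix(~group)
  fit <- edgeR::glmFit(y, design, dispersion = dispersions)
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tab <- lrt$table
  data.frame(
    gene = rownames(counts),
    pvalue = tab$PValue,
    log2FC = tab$logFC,
    direction = ifelse(tab$logFC >= 0, 1L, -1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-study differential expression pipeline
#'
#' Composition of [filter_low_expression()], [tmm_factors()],
#' [estimate_dispersions()] and [nb_glm_lrt()] with the package defaults
#' (CPM threshold 0.85; tagwise shrinkage with prior df 10). Produces the
#' per-study result table consumed by [assemble_evidence()]. Deterministic:
#' identical input gives identical output.
#'
#' @param counts Gene-by-sample raw count matrix (rownames = gene ids).
#' @param labels Condition labels: `1`/`"case"` for condition 1 (cases),
#'   `2`/`"control"` for condition 2.
#' @param cpm_threshold CPM filter cutoff (default 0.85).
#' @param min_samples Minimum samples reaching the cutoff; defaults to the
#'   smaller group size.
#' @param prior_df Tagwise-dispersion shrinkage prior df (default 10).
#' @return data.frame with columns `gene`, `pvalue`, `log2FC`, `direction`
#'   for the genes kept by the filter.
#' @export
run_study_de <- function(counts, labels, cpm_threshold = 0.85,
                         min_samples = NULL, prior_df = 10) {
  counts <- check_counts(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  kept <- filter_low_expression(counts, cpm_threshold, min_samples, labels)
  f <- tmm_factors(kept)
  disp <- estimate_dispersions(kept, labels, factors = f, prior_df = prior_df)
  nb_glm_lrt(kept, labels, factors = f, dispersions = disp)
}
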