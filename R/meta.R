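#' Effective direction of a meta-analysed gene
#'
#' For a gene whose per-study directions all agree, the shared direction is
#' kept. For a gene with conflicting directions the effective direction is
#' the sign of the combined statistic \eqn{N_g}: the direction backed by the
#' heavier-weighted, stronger evidence wins. An exactly zero statistic on
#' the mismatched branch is resolved to "+" with a warning (evidence for the
#' two directions cancels exactly).
#'
#' @param n_g Combined statistic.
#' @param branch `"concordant"` or `"mismatched"`.
#' @param shared_dir The common per-study direction (+1/-1); used only on
#'   the concordant branch.
#' @return `"+"` or `"-"`.
#' @export
effective_direction <- function(n_g, branch, shared_dir = NULL) {
  if (branch == "concordant") {
    if (is.null(shared_dir)) stop("shared_dir required for concordant genes")
    return(if (shared_dir >= 0) "+" else "-")
  }
  if (n_g == 0) {
    warning("mismatched gene with N_g exactly 0; direction set to '+'")
    return("+")
  }
  if (n_g > 0) "+" else "-"
}

#' Run an inverse-normal meta-analysis over a gene evidence table
#'
#' Combines per-study differential-expression evidence gene by gene with one
#' of three weighted inverse-normal methods:
#' \describe{
#'   \item{IN}{the classical one-sided weighted z-score
#'     \eqn{N_g = \sum_s w_s \Phi^{-1}(1 - p_{gs})}. Genes with conflicting
#'     per-study directions cannot be interpreted and are, by default,
#'     removed from the DEG list post hoc (flagged `conflicting`).}
#'   \item{MIN}{the direction-signed statistic
#'     \eqn{N_g = \sum_s w_s B_{gs} |\Phi^{-1}(1 - p_{gs})|}, tested
#'     two-sided; discordant studies cancel rather than disqualify.}
#'   \item{FIN}{the fused method: IN (one-sided) for genes whose directions
#'     agree across present studies, MIN (two-sided) for genes with
#'     conflicting directions, a single pooled BH correction over both
#'     branches.}
#' }
#' Weights are recomputed per gene over the studies the gene is present in
#' (squared weights sum to 1 over that subset). A gene is declared
#' differentially expressed when its BH-adjusted combined p-value is below
#' `alpha` and, if `fc_filter` is `TRUE`, its mean absolute log2 fold change
#' over present studies exceeds `lfc_threshold`.
#'
#' @param evidence A [assemble_evidence()] object.
#' @param design The matching [study_design()].
#' @param method `"FIN"`, `"MIN"` or `"IN"`.
#' @param alpha FDR level for DEG calling (default 0.05).
#' @param lfc_threshold Mean |log2FC| cutoff for DEG calling (default 1).
#' @param fc_filter Apply the fold-change criterion? Disable to call DEGs on
#'   FDR alone, as in simulation benchmarking.
#' @param in_conflict For IN only: `"posthoc"` (default) computes BH over
#'   all genes and then drops conflicting genes from the DEG list;
#'   `"prefilter"` removes conflicting genes before the BH correction.
#'
#' @return A data.frame with one row per gene: `gene`, `method`, `Ng`,
#'   `branch`, `n_present`, `effect` (one `+`/`-` per study in design order,
#'   `.` where absent), `mean_abs_log2FC`, `pvalue_combined`, `fdr`,
#'   `effective_direction`, `conflicting`, `is_DEG`.
#' @examples
#' d <- study_design(c("s1", "s2"), c(5, 5), c(5, 5))
#' t1 <- data.frame(gene = c("g1", "g2"), pvalue = c(1e-4, 0.2),
#'                  log2FC = c(2.1, 0.3))
#' t2 <- data.frame(gene = c("g1", "g2"), pvalue = c(1e-3, 0.4),
#'                  log2FC = c(1.8, -0.2))
#' ev <- assemble_evidence(list(s1 = t1, s2 = t2), d)
#' run_meta(ev, d, method = "FIN")
#' @export
run_meta <- function(evidence, design, method = c("FIN", "MIN", "IN"),
                     alpha = 0.05, lfc_threshold = 1, fc_filter = TRUE,
                     in_conflict = c("posthoc", "prefilter")) {
  method <- match.arg(method)
  in_conflict <- match.arg(in_conflict)
  assert_design(design)
  if (!inherits(evidence, "gene_evidence"))
    stop("'evidence' must come from assemble_evidence()")
  if (!identical(evidence$studies, design$study))
    stop("evidence and design disagree on studies")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")

  P <- evidence$pvalues
  L <- evidence$log2fc
  present <- !is.na(P)
  npres <- rowSums(present)
  if (any(npres == 0L)) {
    warning(sum(npres == 0L), " gene(s) absent from every study dropped")
    keep <- npres > 0L
    P <- P[keep, , drop = FALSE]; L <- L[keep, , drop = FALSE]
    present <- present[keep, , drop = FALSE]; npres <- npres[keep]
  }
  G <- nrow(P)
  genes <- rownames(P)

  # per-gene weights over present studies: w_gs = sqrt(t_s / sum_present t)
  totals <- replicate_totals(design)
  denom <- as.vector(present %*% totals)
  W <- sqrt(sweep(present * rep(totals, each = G), 1L, denom, "/"))

  Z <- z_transform(clamp_p(P, warn = FALSE))
  B <- ifelse(L >= 0, 1, -1) # exact zero counts as "+"

  n_in <- rowSums(W * Z, na.rm = TRUE)
  n_min <- rowSums(W * B * abs(Z), na.rm = TRUE)
  n_up <- rowSums(present & B == 1, na.rm = TRUE)
  concordant <- n_up == 0L | n_up == npres
  branch <- ifelse(concordant, "concordant", "mismatched")
  shared_dir <- ifelse(n_up > 0L, 1, -1) # meaningful on the concordant branch

  n_g <- switch(method,
    IN  = n_in,
    MIN = n_min,
    FIN = ifelse(concordant, n_in, n_min))
  p_comb <- switch(method,
    IN  = combined_p(n_g, "one_sided"),
    MIN = combined_p(n_g, "two_sided"),
    FIN = ifelse(concordant,
                 combined_p(n_g, "one_sided"),
                 combined_p(n_g, "two_sided")))

  conflicting <- if (method == "IN") !concordant else rep(FALSE, G)

  fdr <- rep(NA_real_, G)
  if (method == "IN" && in_conflict == "prefilter") {
    fdr[concordant] <- bh_adjust(p_comb[concordant])
  } else {
    fdr <- bh_adjust(p_comb)
  }

  mean_lfc <- rowMeans(abs(L), na.rm = TRUE)
  eff_dir <- character(G)
  eff_dir[concordant] <- ifelse(shared_dir[concordant] >= 0, "+", "-")
  mm <- !concordant
  if (any(mm & n_g == 0))
    warning(sum(mm & n_g == 0),
            " mismatched gene(s) with N_g exactly 0; direction set to '+'")
  eff_dir[mm] <- ifelse(n_g[mm] >= 0, "+", "-")

  is_deg <- !is.na(fdr) & fdr < alpha
  if (fc_filter) is_deg <- is_deg & mean_lfc > lfc_threshold
  if (method == "IN") is_deg <- is_deg & !conflicting

  effect <- apply(ifelse(present, ifelse(B == 1, "+", "-"), "."), 1L,
                  paste0, collapse = "")

  data.frame(
    gene = genes, method = method, Ng = n_g, branch = branch,
    n_present = npres, effect = effect, mean_abs_log2FC = mean_lfc,
    pvalue_combined = p_comb, fdr = fdr, effective_direction = eff_dir,
    conflicting = conflicting, is_DEG = is_deg,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
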