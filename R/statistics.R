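check_stat_args <- function(p, w, dirs = NULL) {
  if (length(p) != length(w))
    stop("p-values and weights must have the same length")
  if (!is.null(dirs)) {
    if (length(dirs) != length(p))
      stop("directions and p-values must have the same length")
    if (!all(dirs %in% c(-1, 1)))
      stop("directions must be +1 or -1")
  }
  invisible(NULL)
}

#' Weighted inverse-normal (Stouffer) statistic
#'
#' \deqn{N_g = \sum_s w_s \Phi^{-1}(1 - p_{gs})}
#' The classical weighted z-score combination: large when the gene has small
#' p-values across studies, irrespective of the direction of expression.
#'
#' @param p Per-study p-values for one gene (present studies only).
#' @param w Matching study weights (see [compute_weights()]).
#' @return The combined statistic, standard normal under the null.
#' @export
stat_in <- function(p, w) {
  check_stat_args(p, w)
  sum(w * z_transform(p))
}

#' Direction-signed (modified) inverse-normal statistic
#'
#' \deqn{N_g = \sum_s w_s B_{gs} |\Phi^{-1}(1 - p_{gs})|}
#' Each study's contribution is the magnitude of its z-score signed by the
#' observed direction of expression \eqn{B_{gs} \in \{+1, -1\}} (the sign of
#' the study's log2 fold change). Studies that disagree in direction cancel;
#' the statistic is antisymmetric under a global direction flip. Standard
#' normal under the null (the signed absolute normal is again normal).
#'
#' @param p Per-study p-values for one gene.
#' @param dirs Per-study directions, +1 (over-expressed) or -1.
#' @param w Matching study weights.
#' @return The combined statistic.
#' @export
stat_min <- function(p, dirs, w) {
  check_stat_args(p, w, dirs)
  sum(w * dirs * abs(z_transform(p)))
}

#' Fused inverse-normal statistic
#'
#' Dispatches on direction concordance: genes whose present-study directions
#' all agree use the one-sided inverse-normal statistic ([stat_in()],
#' "concordant" branch); genes with conflicting directions use the
#' direction-signed statistic ([stat_min()], "mismatched" branch). A gene
#' present in a single study is vacuously concordant.
#'
#' @inheritParams stat_min
#' @return List with elements `n_g` (the statistic) and `branch`
#'   (`"concordant"` or `"mismatched"`).
#' @export
stat_fin <- function(p, dirs, w) {
  check_stat_args(p, w, dirs)
  if (length(unique(dirs)) <= 1L) {
    # per-study p-values are direction-free, so a concordant gene (up or
    # down) has a large positive IN statistic when its p-values are small
    list(n_g = stat_in(p, w), branch = "concordant")
  } else {
    list(n_g = stat_min(p, dirs, w), branch = "mismatched")
  }
}
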