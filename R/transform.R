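# p-values are clamped before the normal quantile so the transform stays
# finite; the clamp changes no ranks.
.P_MIN <- 1e-300
.P_MAX <- 1 - 1e-16

clamp_p <- function(p, warn = TRUE) {
  out <- pmin(pmax(p, .P_MIN), .P_MAX)
  if (warn && any(p <= 0 | p >= 1, na.rm = TRUE))
    warning("p-values at 0 or 1 clamped to the open unit interval")
  out
}

#' Normal-quantile transform of a p-value
#'
#' Returns \eqn{\Phi^{-1}(1 - p)}, the standard-normal quantile at the upper
#' tail probability `p`; strictly decreasing in `p`. Values of exactly 0 or 1
#' are clamped (with a warning) so the result is finite.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of z-scores.
#' @examples
#' z_transform(0.5)    # 0
#' z_transform(0.025)  # 1.96
#' @export
z_transform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  # qnorm upper tail keeps full precision for tiny p (vs qnorm(1 - p))
  stats::qnorm(clamp_p(p), lower.tail = FALSE)
}

#' Combined p-value of an inverse-normal statistic
#'
#' Under the null the combined statistic \eqn{N_g} is standard normal, so the
#' one-sided (right tail) p-value is \eqn{1 - \Phi(N_g)} and the two-sided
#' p-value is \eqn{2[1 - \Phi(|N_g|)]}. The one-sided test is used for the
#' plain inverse-normal method and the concordant branch of the fused method;
#' the two-sided test for the direction-signed statistic.
#'
#' @param n_g Numeric vector of combined statistics.
#' @param sidedness `"one_sided"` or `"two_sided"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
combined_p <- function(n_g, sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  if (sidedness == "one_sided") {
    stats::pnorm(n_g, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(n_g), lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (wrapper over
#' [stats::p.adjust()] with `method = "BH"`). Adjusted values are pairwise
#' at least the raw values and monotone in the sorted order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
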