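#' Study weights for inverse-normal combination
#'
#' Computes the per-study weights
#' \deqn{w_s = \sqrt{\frac{\sum_c R_{cs}}{\sum_{k} \sum_c R_{ck}}}}
#' where \eqn{R_{cs}} is the number of biological replicates in condition
#' \eqn{c} of study \eqn{s} and the denominator sums over the studies in
#' `present` only. Larger studies therefore receive larger weights, and the
#' squared weights sum to one over the present subset. When a gene is absent
#' from some studies, weights are renormalized over the studies in which it
#' was observed.
#'
#' @param design A [study_design()].
#' @param present Character vector of study identifiers the gene is present
#'   in; defaults to all studies in the design.
#'
#' @return Named numeric vector of weights, one per present study, with
#'   `sum(w^2) == 1`.
#' @examples
#' d <- study_design(c("A", "B", "C"), c(10, 15, 12), c(10, 10, 16))
#' compute_weights(d)                # 0.5234 0.5852 0.6193
#' compute_weights(d, c("A", "B"))  # renormalized over two studies
#' @export
compute_weights <- function(design, present = design$study) {
  assert_design(design)
  present <- as.character(present)
  if (length(present) == 0L) stop("no study evidence: 'present' is empty")
  unknown <- setdiff(present, design$study)
  if (length(unknown)) stop("unknown studies in 'present': ",
                            paste(unknown, collapse = ", "))
  totals <- replicate_totals(design)[present]
  sqrt(totals / sum(totals))
}
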