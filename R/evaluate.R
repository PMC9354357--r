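#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a randomly chosen truly-DE gene scores higher than a randomly
#' chosen non-DE gene, ties counted half.
#'
#' @param scores Numeric scores, larger = more likely DE (use the negative
#'   combined p-value).
#' @param truth Logical vector, `TRUE` for truly DE genes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores) # midranks
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical false discovery proportion
#'
#' Fraction of called genes that are not truly DE; 0 when nothing is called
#' (by convention).
#'
#' @param called Character vector of called gene ids.
#' @param true_de Character vector of truly DE gene ids.
#' @return Proportion in `[0, 1]`.
#' @export
empirical_fdr <- function(called, true_de) {
  if (length(called) == 0L) return(0)
  mean(!(called %in% true_de))
}

#' True-positive proportion among method-unique discoveries
#'
#' Among genes called by `calls_method` but not by `calls_reference`, the
#' fraction that are truly DE. `NA` when the unique set is empty.
#'
#' @param calls_method,calls_reference Character vectors of called gene ids
#'   over the same gene universe.
#' @param true_de Character vector of truly DE gene ids.
#' @return Proportion in `[0, 1]`, or `NA` if no unique calls.
#' @export
unique_tp_proportion <- function(calls_method, calls_reference, true_de) {
  uniq <- setdiff(calls_method, calls_reference)
  if (length(uniq) == 0L) return(NA_real_)
  mean(uniq %in% true_de)
}

#' Direction recovery among a gene subset
#'
#' Fraction of `subset` genes whose effective direction in `meta` matches
#' the simulated true direction. `NA` for an empty subset.
#'
#' @param meta A [run_meta()] result table.
#' @param truth Truth data.frame with columns `gene` and `true_direction`
#'   (+1/-1).
#' @param subset Character vector of gene ids to assess (typically the
#'   truly-DE genes uniquely discovered by one method).
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
direction_recovery <- function(meta, truth, subset) {
  if (length(subset) == 0L) return(NA_real_)
  eff <- meta$effective_direction[match(subset, meta$gene)]
  tru <- truth$true_direction[match(subset, truth$gene)]
  mean(eff == ifelse(tru >= 0, "+", "-"))
}

run_one_trial <- function(setting, G, pi_de, trial_seed,
                          methods = c("MIN", "IN", "FIN"),
                          cpm_threshold = 0.85, alpha = 0.05) {
  st <- sim_setting(setting)
  params <- default_sim_params(G, pi_de = pi_de, design = st$design,
                               sigma = st$sigma, seed = trial_seed)
  sim <- simulate_counts(params, seed = trial_seed + 1L)

  tables <- lapply(sim$studies, function(s)
    run_study_de(s$counts, s$labels, cpm_threshold = cpm_threshold))
  ev <- assemble_evidence(tables, st$design)
  truth <- sim$truth
  true_de <- truth$gene[truth$is_de]

  metas <- lapply(stats::setNames(nm = unique(c(methods, "IN"))), function(m)
    run_meta(ev, st$design, method = m, alpha = alpha, fc_filter = FALSE))
  calls <- lapply(metas, function(m) m$gene[m$is_DEG])

  out <- lapply(stats::setNames(nm = methods), function(m) {
    meta <- metas[[m]]
    tr <- truth$is_de[match(meta$gene, truth$gene)]
    auc <- roc_auc(-meta$pvalue_combined, tr)
    fdr <- empirical_fdr(calls[[m]], true_de)
    if (m == "IN") {
      list(auc = auc, fdr = fdr, unique_tp = NA_real_, dir_rec = NA_real_)
    } else {
      uniq <- setdiff(calls[[m]], calls[["IN"]])
      utp <- unique_tp_proportion(calls[[m]], calls[["IN"]], true_de)
      dr <- direction_recovery(meta, truth, intersect(uniq, true_de))
      list(auc = auc, fdr = fdr, unique_tp = utp, dir_rec = dr)
    }
  })
  out
}

#' Run the multi-setting simulation benchmark
#'
#' For each requested setting (see [sim_setting()]) and trial: simulate
#' counts, run the per-study DE stage, combine with each method, call DEGs
#' at BH-adjusted combined p < `alpha` (no fold-change filter, as
#' appropriate when truth is known), and score AUC, empirical FDR,
#' unique-discovery true-positive proportion and direction recovery against
#' the IN baseline. Trial `t` of setting `k` is seeded deterministically
#' from `seed`, so the full table is reproducible.
#'
#' @param settings Integer vector of settings (subset of 1:4).
#' @param n_trials Trials per setting (default 20).
#' @param G Genes per trial (default 5000).
#' @param pi_de Proportion truly DE (default 0.1).
#' @param seed Base integer seed.
#' @param methods Methods to score (IN is always also run as reference).
#' @param cpm_threshold Per-study CPM filter (default 0.85).
#' @param alpha FDR level for DEG calling (default 0.05).
#' @return data.frame with one row per setting x method: `setting`,
#'   `sigma`, `n_studies`, `method`, `mean_auc`, `sd_auc`, `mean_fdr`,
#'   `sd_fdr`, `unique_tp_prop`, `direction_recovery`, `n_trials`. Unique-discovery
#'   columns are `NA` for IN (it is its own reference); trial-level `NA`s
#'   (empty unique sets) are dropped from the averages.
#' @export
run_simulation_study <- function(settings = 1:4, n_trials = 20, G = 5000,
                                 pi_de = 0.1, seed = 1L,
                                 methods = c("MIN", "IN", "FIN"),
                                 cpm_threshold = 0.85, alpha = 0.05) {
  if (n_trials < 1L) stop("'n_trials' must be at least 1")
  rows <- list()
  for (k in settings) {
    st <- sim_setting(k)
    per_method <- lapply(stats::setNames(nm = methods), function(m)
      list(auc = numeric(0), fdr = numeric(0),
           utp = numeric(0), dr = numeric(0)))
    for (t in seq_len(n_trials)) {
      trial_seed <- (as.integer(seed) + 100000L * k + 2L * t) %%
        .Machine$integer.max
      res <- run_one_trial(k, G, pi_de, trial_seed, methods,
                           cpm_threshold, alpha)
      for (m in methods) {
        per_method[[m]]$auc <- c(per_method[[m]]$auc, res[[m]]$auc)
        per_method[[m]]$fdr <- c(per_method[[m]]$fdr, res[[m]]$fdr)
        per_method[[m]]$utp <- c(per_method[[m]]$utp, res[[m]]$unique_tp)
        per_method[[m]]$dr <- c(per_method[[m]]$dr, res[[m]]$dir_rec)
      }
    }
    for (m in methods) {
      x <- per_method[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        setting = k, sigma = st$sigma, n_studies = nrow(st$design),
        method = m,
        mean_auc = mean(x$auc), sd_auc = stats::sd(x$auc),
        mean_fdr = mean(x$fdr), sd_fdr = stats::sd(x$fdr),
        unique_tp_prop = if (all(is.na(x$utp))) NA_real_ else
          mean(x$utp, na.rm = TRUE),
        direction_recovery = if (all(is.na(x$dr))) NA_real_ else
          mean(x$dr, na.rm = TRUE),
        n_trials = n_trials, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
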