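# Multi-study negative-binomial count simulator with known DE truth.
#
# Per gene g and condition c there is a base mean mu_gc; per study s a
# lognormal study effect exp(eps_gs), eps_gs ~ N(0, sigma^2), drawn once per
# gene-study and shared by both conditions, moves the gene's expression
# level between studies without breaking the within-study null. On top of
# that, truly DE genes carry random-effects heterogeneity: the realized
# case-condition effect in study s is perturbed by exp(eta_gs),
# eta_gs ~ N(0, effect_sd^2), so a gene's realized log2 fold change varies
# (and for weak genes can reverse sign) between studies while null genes
# stay exact nulls in every study. Counts are NB with gene-wise dispersion
# phi_g: Var = mu + phi mu^2 (phi = 0 falls back to Poisson).

#' Synthetic simulation parameters
#'
#' Draws a reproducible parameter set for the multi-study simulator: base
#' means lognormal across genes, dispersions gamma, a DE gene set of size
#' `round(pi_de * G)` with equiprobable up/down directions and |log2FC|
#' drawn from a right-skewed (truncated lognormal) distribution on
#' `lfc_range`. Non-DE genes get equal means in both conditions; for a DE
#' gene the case mean is the control mean times
#' `2^(direction * |log2FC|)`.
#'
#' @param G Number of genes.
#' @param pi_de Proportion of truly DE genes (default 0.1).
#' @param design A [study_design()] giving studies and replicate counts.
#' @param sigma Inter-study variability: sd of the lognormal study effect on
#'   gene means (0.15 = low, 0.5 = high heterogeneity between human
#'   studies).
#' @param lfc_range Range (truncation bounds) of true |log2FC| for DE
#'   genes. The default `c(0.1, 2.5)` emulates a truth set classified from
#'   a large real case-control cohort at BH < 0.05, where most true DEGs
#'   carry sub-unit fold changes; weak-effect DE genes are what produce
#'   conflicting observed directions across studies.
#' @param lfc_distribution `"lognormal"` (default) draws |log2FC| from a
#'   lognormal with median 0.4 (meanlog `log(0.4)`, sdlog 0.7) truncated
#'   to `lfc_range`, matching the right-skewed effect sizes of
#'   cohort-derived truth sets; `"uniform"` draws uniformly on
#'   `lfc_range`.
#' @param mean_meanlog,mean_sdlog Lognormal parameters of the base-mean
#'   distribution (defaults give a median around 55 counts, long right
#'   tail, as in bulk RNA-seq).
#' @param disp_shape,disp_rate Gamma parameters of the dispersion
#'   distribution (defaults give mean 0.25, typical of heterogeneous human
#'   cohorts).
#' @param effect_sd Between-study effect heterogeneity for DE genes: sd (on
#'   the natural-log scale) of the per-study perturbation of a DE gene's
#'   case-condition effect, the random-effects component of a meta-analysis.
#'   Defaults to `sigma`, so one parameter governs both how far studies
#'   drift apart in expression level and how much a true effect varies
#'   between them. Null genes are never perturbed.
#' @param seed Integer seed; the same seed reproduces the parameter set.
#' @return List of class `sim_params`: `G`, `design`, `sigma`, `mu` (G x 2
#'   matrix, columns case/control), `dispersion`, and truth vectors
#'   `is_de`, `true_direction`, `true_lfc`.
#' @export
default_sim_params <- function(G, pi_de = 0.1, design, sigma = 0.15,
                               lfc_range = c(0.1, 2.5),
                               lfc_distribution = c("lognormal", "uniform"),
                               mean_meanlog = 4, mean_sdlog = 1.5,
                               disp_shape = 2, disp_rate = 10,
                               effect_sd = sigma, seed = 1L) {
  if (G < 1L) stop("'G' must be at least 1")
  if (pi_de < 0 || pi_de > 1) stop("'pi_de' must lie in [0, 1]")
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (length(lfc_range) != 2L || lfc_range[1] > lfc_range[2] ||
      lfc_range[1] < 0)
    stop("'lfc_range' must be an increasing non-negative pair")
  lfc_distribution <- match.arg(lfc_distribution)
  assert_design(design)

  set.seed(as.integer(seed))
  base <- stats::rlnorm(G, meanlog = mean_meanlog, sdlog = mean_sdlog)
  phi <- stats::rgamma(G, shape = disp_shape, rate = disp_rate)

  n_de <- round(pi_de * G)
  is_de <- rep(FALSE, G)
  is_de[sample.int(G, n_de)] <- TRUE
  dir <- integer(G)
  lfc <- numeric(G)
  if (n_de > 0L) {
    dir[is_de] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    lfc[is_de] <- if (lfc_distribution == "uniform") {
      stats::runif(n_de, lfc_range[1], lfc_range[2])
    } else {
      # inverse-CDF draw from the lognormal truncated to lfc_range
      lo <- stats::plnorm(lfc_range[1], log(0.4), 0.7)
      hi <- stats::plnorm(lfc_range[2], log(0.4), 0.7)
      stats::qlnorm(stats::runif(n_de, lo, hi), log(0.4), 0.7)
    }
  }
  mu <- cbind(case = base * 2^(dir * lfc), control = base)

  structure(list(G = G, design = design, sigma = sigma,
                 effect_sd = effect_sd, mu = mu,
                 dispersion = phi, is_de = is_de,
                 true_direction = dir, true_lfc = lfc, seed = seed),
            class = "sim_params")
}

#' Estimate simulation parameters from a real count matrix
#'
#' Derives a `sim_params` object from an observed two-condition count
#' matrix: per-gene condition means from average CPM scaled to the mean
#' library size, gene-wise dispersions by method of moments (pooled
#' within-condition, floored at 0), and the DE truth set from
#' [run_study_de()] on the same matrix at BH < 0.05 with the observed
#' log2FC as the true fold change.
#'
#' @param counts Gene-by-sample count matrix.
#' @param labels Condition labels (see [run_study_de()]).
#' @param design A [study_design()] for the simulated studies.
#' @param sigma Inter-study variability for the simulation.
#' @param alpha BH level classifying a gene as truly DE (default 0.05).
#' @return A `sim_params` object.
#' @export
estimate_base_params <- function(counts, labels, design, sigma = 0.15,
                                 alpha = 0.05) {
  counts <- check_counts(counts)
  group <- normalize_labels(labels, ncol(counts))
  if (nlevels(droplevels(group)) < 2L) stop("two conditions are required")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  assert_design(design)

  libsize <- colSums(counts)
  cpm_mat <- cpm(counts)
  scale_to <- mean(libsize) / 1e6
  mu_case <- rowMeans(cpm_mat[, group == "case", drop = FALSE]) * scale_to
  mu_ctrl <- rowMeans(cpm_mat[, group == "control", drop = FALSE]) * scale_to

  # method-of-moments dispersion: phi = (Var - mu) / mu^2, pooled over
  # conditions, floored at 0
  mom <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1L, stats::var)
    ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  }
  n_case <- sum(group == "case"); n_ctrl <- sum(group == "control")
  phi <- (mom(counts[, group == "case", drop = FALSE]) * (n_case - 1) +
          mom(counts[, group == "control", drop = FALSE]) * (n_ctrl - 1)) /
    (n_case + n_ctrl - 2)

  de <- run_study_de(counts, labels)
  q <- bh_adjust(de$pvalue)
  de_genes <- de$gene[q < alpha]
  idx <- match(de_genes, rownames(counts))
  is_de <- seq_len(nrow(counts)) %in% idx
  dir <- integer(nrow(counts)); lfc <- numeric(nrow(counts))
  dir[idx] <- ifelse(de$log2FC[q < alpha] >= 0, 1L, -1L)
  lfc[idx] <- abs(de$log2FC[q < alpha])

  # non-DE genes get a single shared mean so the simulated null is exact
  shared <- (mu_case * n_case + mu_ctrl * n_ctrl) / (n_case + n_ctrl)
  mu <- cbind(case = ifelse(is_de, mu_case, shared),
              control = ifelse(is_de, mu_ctrl, shared))

  structure(list(G = nrow(counts), design = design, sigma = sigma,
                 effect_sd = sigma, mu = mu,
                 dispersion = phi, is_de = is_de, true_direction = dir,
                 true_lfc = lfc, seed = NA_integer_),
            class = "sim_params")
}

#' Simulate multi-study RNA-seq counts
#'
#' Generates one count matrix per study in the design. For study `s`, a
#' gene-wise study effect `eps[g, s] ~ N(0, sigma^2)` multiplies both
#' condition means by `exp(eps)`; counts are then drawn NB with the gene's
#' dispersion. Condition 1 columns (cases) come first in each matrix.
#'
#' @param params A `sim_params` object.
#' @param seed Integer seed for the count draw.
#' @param study_effect_model `"shared"` (default) draws one effect per
#'   gene-study applied to both conditions, perturbing expression level
#'   between studies while leaving each study's true fold change at its
#'   base value (the null stays an exact null within every study, so
#'   combined p-values remain calibrated); `"condition"` draws an
#'   independent effect per gene, study and condition, so the realized
#'   within-study fold change itself varies between studies — more
#'   heterogeneity, but null genes then carry genuine within-study
#'   signal and FDR control is lost by construction.
#' @return List of class `sim_dataset`: `studies` (named list with
#'   `counts` and `labels` per study), `truth` (data.frame `gene`, `is_de`,
#'   `true_direction`, `true_lfc`), `params`, `seed`.
#' @export
simulate_counts <- function(params, seed = 1L,
                            study_effect_model = c("shared", "condition")) {
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params")
  study_effect_model <- match.arg(study_effect_model)
  set.seed(as.integer(seed))
  G <- params$G
  genes <- paste0("gene", seq_len(G))
  phi <- params$dispersion

  studies <- vector("list", nrow(params$design))
  names(studies) <- params$design$study
  for (i in seq_len(nrow(params$design))) {
    n1 <- params$design$cases[i]; n2 <- params$design$controls[i]
    k <- if (study_effect_model == "condition") 2L else 1L
    eps <- matrix(if (params$sigma > 0)
      stats::rnorm(G * k, 0, params$sigma) else 0, G, 2L)
    # random-effects heterogeneity: a DE gene's realized case effect in
    # this study is its base effect times exp(eta), eta ~ N(0, effect_sd^2)
    effect_sd <- params$effect_sd %||% params$sigma
    eta <- numeric(G)
    if (effect_sd > 0 && any(params$is_de))
      eta[params$is_de] <- stats::rnorm(sum(params$is_de), 0, effect_sd)
    mu <- cbind(matrix(params$mu[, "case"] * exp(eps[, 1L] + eta), G, n1),
                matrix(params$mu[, "control"] * exp(eps[, 2L]), G, n2))
    y <- matrix(0, G, n1 + n2)
    pois <- phi <= 0
    if (any(pois))
      y[pois, ] <- stats::rpois(sum(pois) * (n1 + n2), lambda = mu[pois, ])
    if (any(!pois))
      y[!pois, ] <- stats::rnbinom(sum(!pois) * (n1 + n2),
                                   mu = mu[!pois, ], size = 1 / phi[!pois])
    dimnames(y) <- list(genes,
                        c(paste0("case", seq_len(n1)),
                          paste0("control", seq_len(n2))))
    colnames(eps) <- c("case", "control")
    studies[[i]] <- list(counts = y,
                         labels = rep(c("case", "control"), c(n1, n2)),
                         realized_log_shift = eps)
  }

  truth <- data.frame(gene = genes, is_de = params$is_de,
                      true_direction = params$true_direction,
                      true_lfc = params$true_lfc,
                      stringsAsFactors = FALSE)
  structure(list(studies = studies, truth = truth, params = params,
                 seed = seed),
            class = "sim_dataset")
}

#' Table of preset simulation settings
#'
#' The four benchmark settings: low/high inter-study variability (sigma
#' 0.15 or 0.5) crossed with 3 or 5 studies with fixed replicate layouts.
#'
#' @param setting Integer 1-4.
#' @return List with `sigma` and a [study_design()].
#' @export
sim_setting <- function(setting) {
  if (!setting %in% 1:4) stop("'setting' must be 1, 2, 3 or 4")
  cases <- c(10, 15, 12, 14, 20)
  controls <- c(10, 10, 16, 12, 20)
  s <- if (setting %in% c(1, 3)) 3L else 5L
  sigma <- if (setting %in% c(1, 2)) 0.15 else 0.5
  list(sigma = sigma,
       design = study_design(paste0("study", seq_len(s)),
                             cases[seq_len(s)], controls[seq_len(s)]))
}
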