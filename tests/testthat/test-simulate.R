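test_that("parameter draws are reproducible and honor the DE fraction", {
  d <- equal_design(3, 8)
  p1 <- default_sim_params(10000, pi_de = 0.1, design = d, seed = 4)
  p2 <- default_sim_params(10000, pi_de = 0.1, design = d, seed = 4)
  expect_identical(p1, p2)
  expect_equal(sum(p1$is_de), 1000)
  expect_true(all(abs(p1$true_lfc[p1$is_de]) >= 0.1 &
                    abs(p1$true_lfc[p1$is_de]) <= 2.5))
  # null genes: equal means in both conditions
  p0 <- default_sim_params(500, pi_de = 0, design = d, seed = 4)
  expect_equal(sum(p0$is_de), 0)
  expect_identical(p0$mu[, "case"], p0$mu[, "control"])
})

test_that("sigma = 0 reproduces base means exactly", {
  d <- equal_design(2, 4)
  p <- default_sim_params(200, pi_de = 0.1, design = d, sigma = 0, seed = 6)
  sim <- simulate_counts(p, seed = 7)
  for (s in sim$studies)
    expect_true(all(s$realized_log_shift == 0))
})

test_that("simulated counts match NB moments", {
  d <- study_design("s1", cases = 5000, controls = 1)
  mu <- 200; phi <- 0.15
  p <- structure(list(G = 1L, design = d, sigma = 0, effect_sd = 0,
                      mu = cbind(case = mu, control = mu),
                      dispersion = phi, is_de = FALSE,
                      true_direction = 0L, true_lfc = 0, seed = 1L),
                 class = "sim_params")
  sim <- simulate_counts(p, seed = 3)
  y <- sim$studies$s1$counts[1, 1:5000]
  v <- mu + phi * mu^2
  expect_lt(abs(mean(y) - mu), 3 * sqrt(v / 5000))
  expect_lt(abs(var(y) - v) / v, 0.15)
})

test_that("the preset designs have the declared shape", {
  s2 <- sim_setting(2)
  expect_equal(s2$sigma, 0.15)
  expect_equal(nrow(s2$design), 5)
  expect_equal(sum(s2$design$cases + s2$design$controls), 139)
  sim <- simulate_counts(default_sim_params(50, 0.1, s2$design,
                                            s2$sigma, seed = 2), seed = 2)
  expect_equal(sum(vapply(sim$studies, function(s) ncol(s$counts), 1L)), 139)
  expect_equal(sim_setting(3)$sigma, 0.5)
  expect_equal(nrow(sim_setting(1)$design), 3)
  expect_error(sim_setting(5), "setting")
})

test_that("between-study variance of realized log means increases with sigma", {
  d <- equal_design(6, 4)
  bsv <- function(sigma) {
    p <- default_sim_params(400, pi_de = 0, design = d, sigma = sigma,
                            seed = 21)
    sim <- simulate_counts(p, seed = 22)
    eps <- sapply(sim$studies, function(s) s$realized_log_shift[, 1])
    mean(apply(eps, 1, var))
  }
  v0 <- bsv(0); v15 <- bsv(0.15); v50 <- bsv(0.5)
  expect_equal(v0, 0)
  expect_lt(v15, v50)
  expect_lt(abs(v15 - 0.15^2) / 0.15^2, 0.3)
})

test_that("direction conflicts among observed effects increase with sigma and S", {
  mismatch_frac <- function(setting, seed) {
    st <- sim_setting(setting)
    p <- default_sim_params(800, pi_de = 0.2, design = st$design,
                            sigma = st$sigma, seed = seed)
    sim <- simulate_counts(p, seed = seed + 1)
    tabs <- lapply(sim$studies, function(s)
      run_study_de(s$counts, s$labels))
    ev <- assemble_evidence(tabs, st$design)
    res <- run_meta(ev, st$design, "FIN", fc_filter = FALSE)
    de <- sim$truth$gene[sim$truth$is_de]
    mean(res$branch[res$gene %in% de] == "mismatched")
  }
  m1 <- mismatch_frac(1, 31) # sigma 0.15, 3 studies
  m4 <- mismatch_frac(4, 31) # sigma 0.5, 5 studies
  expect_gt(m4, m1)
})

test_that("parameters can be recovered from a simulated count matrix", {
  tc <- toy_counts(G = 2000, n_per_group = 25, de_frac = 0.05, lfc = 2,
                   phi = 0.1, mu = 150, seed = 15)
  est <- estimate_base_params(tc$counts, tc$labels,
                              design = equal_design(2, 5))
  expect_s3_class(est, "sim_params")
  ctrl <- est$mu[!est$is_de, "control"]
  expect_lt(abs(median(ctrl) - 150) / 150, 0.1)
  disp <- est$dispersion[est$dispersion > 0]
  expect_lt(abs(median(disp) - 0.1) / 0.1, 0.5)
  expect_true(all(est$dispersion >= 0))
  # most planted DE genes recovered in the truth set, few nulls
  planted <- rownames(tc$counts) %in% tc$de_genes
  expect_gt(mean(est$is_de[planted]), 0.8)
  expect_lt(mean(est$is_de[!planted]), 0.02)
  expect_error(estimate_base_params(tc$counts, rep("case", 50),
                                    equal_design(2, 5)))
})
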