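toy4 <- function() {
  d <- equal_design(2, 5)
  p <- list(g1 = c(1e-6, 1e-6), g2 = c(1e-6, 1e-6),
            g3 = c(0.5, 0.5), g4 = c(1e-6, NA))
  l <- list(g1 = c(2, 2), g2 = c(2, -2), g3 = c(0.1, 0.1), g4 = c(2, NA))
  list(ev = toy_evidence(p, l, d), design = d)
}

test_that("toy two-study meta-analysis calls the expected DEGs per method", {
  t <- toy4()
  expect_warning(
    fin <- run_meta(t$ev, t$design, "FIN", alpha = 0.05, lfc_threshold = 1),
    "exactly 0")
  expect_setequal(fin$gene[fin$is_DEG], c("g1", "g4"))
  # exactly cancelling conflicting evidence yields no combined signal
  g2 <- fin[fin$gene == "g2", ]
  expect_equal(g2$branch, "mismatched")
  expect_equal(g2$Ng, 0, tolerance = 1e-9)
  expect_equal(g2$pvalue_combined, 1, tolerance = 1e-9)
  # weak concordant evidence is not called
  expect_false(fin$is_DEG[fin$gene == "g3"])
  # effect strings render absent studies as '.'
  expect_equal(fin$effect[fin$gene == "g4"], "+.")
  expect_equal(fin$effect[fin$gene == "g2"], "+-")

  inr <- run_meta(t$ev, t$design, "IN", alpha = 0.05, lfc_threshold = 1)
  expect_setequal(inr$gene[inr$is_DEG], c("g1", "g4"))
  # IN sees strong combined evidence for g2 but must exclude it post hoc
  expect_true(inr$conflicting[inr$gene == "g2"])
  expect_lt(inr$pvalue_combined[inr$gene == "g2"], 1e-8)
  expect_false(inr$is_DEG[inr$gene == "g2"])

  minr <- suppressWarnings(
    run_meta(t$ev, t$design, "MIN", alpha = 0.05, lfc_threshold = 1))
  expect_setequal(minr$gene[minr$is_DEG], c("g1", "g4"))
})

test_that("a single-study gene reduces to that study's own test", {
  t <- toy4()
  inr <- run_meta(t$ev, t$design, "IN", fc_filter = FALSE)
  g4 <- inr[inr$gene == "g4", ]
  # weight 1, statistic = the study quantile, one-sided p = the raw p
  expect_equal(g4$pvalue_combined, 1e-6, tolerance = 1e-9)
  minr <- suppressWarnings(run_meta(t$ev, t$design, "MIN", fc_filter = FALSE))
  expect_equal(minr$pvalue_combined[minr$gene == "g4"], 2e-6,
               tolerance = 1e-9)
})

test_that("MIN and FIN agree exactly on mismatched genes", {
  set.seed(13)
  d <- design3()
  genes <- paste0("g", 1:60)
  p <- lapply(setNames(genes, genes), function(g) runif(3))
  l <- lapply(setNames(genes, genes), function(g)
    runif(3, -2, 2) + c(0, 0.001, -0.001)) # avoid exact zeros
  ev <- toy_evidence(p, l, d)
  minr <- run_meta(ev, d, "MIN", fc_filter = FALSE)
  fin <- run_meta(ev, d, "FIN", fc_filter = FALSE)
  mm <- fin$branch == "mismatched"
  expect_gt(sum(mm), 10)
  expect_identical(fin$Ng[mm], minr$Ng[mm])
  expect_identical(fin$pvalue_combined[mm], minr$pvalue_combined[mm])
  # concordant branch instead matches IN's statistic
  inr <- run_meta(ev, d, "IN", fc_filter = FALSE)
  expect_identical(fin$Ng[!mm], inr$Ng[!mm])
})

test_that("effective direction follows the sign rule of the statistic", {
  # mismatched genes take the sign of the combined statistic
  expect_equal(effective_direction(7.58, "mismatched"), "+")
  expect_equal(effective_direction(-7.53, "mismatched"), "-")
  # concordant genes keep the shared direction regardless of N_g
  expect_equal(effective_direction(-3, "concordant", shared_dir = 1), "+")
  expect_equal(effective_direction(10, "concordant", shared_dir = -1), "-")
  expect_warning(out <- effective_direction(0, "mismatched"), "exactly 0")
  expect_equal(out, "+")
})

test_that("IN conflict handling supports post-hoc and pre-filter BH", {
  t <- toy4()
  post <- run_meta(t$ev, t$design, "IN", in_conflict = "posthoc",
                   fc_filter = FALSE)
  pre <- run_meta(t$ev, t$design, "IN", in_conflict = "prefilter",
                  fc_filter = FALSE)
  # pre-filter mode never assigns an FDR to conflicting genes
  expect_true(is.na(pre$fdr[pre$gene == "g2"]))
  expect_false(is.na(post$fdr[post$gene == "g2"]))
  # BH pool sizes differ (4 vs 3 genes), so adjusted values can differ
  expect_equal(sum(!is.na(pre$fdr)), 3)
  expect_setequal(pre$gene[pre$is_DEG], post$gene[post$is_DEG])
})

test_that("meta results satisfy their structural invariants", {
  set.seed(29)
  d <- design3()
  genes <- paste0("g", 1:80)
  p <- lapply(setNames(genes, genes), function(g) {
    out <- runif(3); if (runif(1) < 0.3) out[sample(3, 1)] <- NA; out
  })
  l <- lapply(setNames(genes, genes), function(g)
    ifelse(is.na(p[[g]]), NA, rnorm(3)))
  ev <- toy_evidence(p, l, d)
  for (m in c("IN", "MIN", "FIN")) {
    r <- run_meta(ev, d, m, fc_filter = FALSE)
    expect_true(all(r$fdr >= r$pvalue_combined - 1e-12))
    expect_true(all(r$pvalue_combined >= 0 & r$pvalue_combined <= 1))
    expect_true(all(r$effective_direction %in% c("+", "-")))
    expect_true(all(nchar(r$effect) == 3))
    expect_equal(r$n_present, 3L - vapply(p[r$gene], function(x)
      sum(is.na(x)), 0L), ignore_attr = TRUE)
    # mean |log2FC| averages over present studies only
    expect_equal(r$mean_abs_log2FC, vapply(l[r$gene], function(x)
      mean(abs(x), na.rm = TRUE), 1), ignore_attr = TRUE)
    # determinism
    expect_identical(r, run_meta(ev, d, m, fc_filter = FALSE))
  }
})

test_that("meta rejects inconsistent input", {
  t <- toy4()
  expect_error(run_meta(t$ev, t$design, "XX"), "arg")
  expect_error(run_meta(t$ev, design3(), "FIN"), "disagree")
  expect_error(run_meta(t$ev, t$design, "FIN", alpha = 1.2), "alpha")
})
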