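test_that("per-probe OLS matches a hand-computed two-group comparison", {
  # 8 samples, no covariates beyond intercept: carrier coefficient is the
  # difference of group means, t the pooled-variance two-sample statistic
  y <- c(1.0, 1.2, 0.8, 1.1, 3.0, 3.3, 2.9, 3.1)
  carrier <- c(rep("non_carrier", 4), rep("carrier", 4))
  ds <- toy_dataset(list(cgA = y, cgB = rnorm(8)), carrier)
  res <- fit_probe_models(ds)
  row <- res$table[res$table$probe_id == "cgA", ]

  g1 <- y[5:8]; g0 <- y[1:4]
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)) / 6
  t_hand <- (mean(g1) - mean(g0)) / sqrt(sp2 * (1/4 + 1/4))
  expect_equal(row$coef, mean(g1) - mean(g0), tolerance = 1e-12)
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
})

test_that("OLS agrees with an independent normal-equations oracle under covariates", {
  set.seed(2)
  n <- 10
  cov <- data.frame(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5),
                    smoking_score = rnorm(n))
  carrier <- c(rep("carrier", 4), rep("non_carrier", 6))
  vals <- list(cg1 = rnorm(n), cg2 = rnorm(n) + (carrier == "carrier"),
               cg3 = rnorm(n, sd = 2))
  ds <- toy_dataset(vals, carrier, covariates = cov)
  res <- fit_probe_models(ds)
  X <- build_design(ds)
  for (pr in names(vals)) {
    orc <- ols_oracle(X, ds$m[, pr])
    row <- res$table[res$table$probe_id == pr, ]
    expect_equal(row$coef, orc$coef, tolerance = 1e-8)
    expect_equal(row$se, orc$se, tolerance = 1e-8)
    expect_equal(row$t, orc$t, tolerance = 1e-8)
    expect_equal(row$p, orc$p, tolerance = 1e-8)
  }
})

test_that("fit is invariant to sample order and flags zero-variance probes", {
  set.seed(3)
  n <- 30
  carrier <- sample(c("carrier", "non_carrier"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
  ds <- toy_dataset(list(cgA = rnorm(n), cgFlat = rep(1.7, n),
                         cgB = rnorm(n)), carrier)
  res <- fit_probe_models(ds)
  flat <- res$table[res$table$probe_id == "cgFlat", ]
  expect_true(flat$zero_variance)
  expect_equal(flat$coef, 0)
  expect_true(is.na(flat$p))

  perm <- sample(n)
  ds2 <- meth_dataset(ds$m[perm, ], carrier = carrier[perm])
  res2 <- fit_probe_models(ds2)
  expect_equal(res2$table, res$table, tolerance = 1e-12)
})

test_that("degenerate designs fail with informative errors", {
  n <- 20
  carrier <- c(rep("carrier", 10), rep("non_carrier", 10))
  cov <- data.frame(age = rnorm(n, 60, 5),
                    batch = ifelse(carrier == "carrier", "B1", "B2"))
  ds <- toy_dataset(list(cgA = rnorm(n)), carrier, covariates = cov)
  expect_error(fit_probe_models(ds), "rank deficient.*batch")

  small <- toy_dataset(list(cgA = rnorm(3)),
                       c("carrier", "carrier", "non_carrier"),
                       covariates = data.frame(age = rnorm(3), sex = c(0, 1, 0),
                                               smoking_score = rnorm(3)))
  expect_error(fit_probe_models(small), "at least")
})

test_that("moderation reduces to the pooled fit when variances are homogeneous", {
  # identical residual variance across probes: d0 infinite, posterior
  # variance equals every probe's own (common) sample variance
  set.seed(4)
  n <- 12
  carrier <- c(rep("carrier", 6), rep("non_carrier", 6))
  base <- rnorm(n)
  vals <- lapply(1:60, function(i) base + i)  # same spread, shifted means
  names(vals) <- sprintf("cg%02d", 1:60)
  ds <- toy_dataset(vals, carrier)
  res <- moderate_variances(fit_probe_models(ds))
  expect_true(is.infinite(res$d0))
  expect_equal(res$s2_posterior, res$s2, tolerance = 1e-12)
  expect_equal(res$table$t,
               fit_probe_models(ds)$table$coef / (sqrt(res$s2) * res$stdev_unscaled),
               tolerance = 1e-12)
})

test_that("disabling moderation returns the plain OLS fit", {
  coh <- null_cohort(n_bg = 300)
  raw <- fit_probe_models(coh$dataset)
  via_run <- run_dma(coh$dataset, moderate = FALSE)
  expect_equal(via_run$table$t, raw$table$t, tolerance = 1e-12)
  expect_equal(via_run$table$p, raw$table$p, tolerance = 1e-12)
})

test_that("moderation shrinks the spread of log variances and keeps t signs", {
  coh <- null_cohort(n_bg = 1000)
  raw <- fit_probe_models(coh$dataset)
  mod <- moderate_variances(raw)
  expect_true(is.finite(mod$d0) && mod$d0 > 0)
  expect_lt(var(log(mod$s2_posterior)), var(log(raw$s2)))
  ok <- !raw$table$zero_variance
  expect_true(all(sign(mod$table$t[ok]) == sign(raw$table$t[ok])))
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  coh <- null_cohort(n_bg = 1000)
  ds <- coh$dataset
  mod <- moderate_variances(fit_probe_models(ds))

  X <- build_design(ds)
  fit <- limma::eBayes(limma::lmFit(t(ds$m), X))
  expect_equal(mod$d0, unname(fit$df.prior), tolerance = 1e-6)
  expect_equal(mod$s0_sq, unname(fit$s2.prior), tolerance = 1e-6)
  expect_equal(unname(mod$table$t), unname(fit$t[, "carrier"]),
               tolerance = 1e-6)
  expect_equal(unname(mod$table$p), unname(fit$p.value[, "carrier"]),
               tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.04), 0.04)

  set.seed(5)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(adjust_pvalues(p), bh_oracle(p), tolerance = 1e-12)
  }

  # permutation invariance and rank monotonicity
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_pvalues(p)[perm], adjust_pvalues(p[perm]))
  adj <- adjust_pvalues(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))

  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # NAs (zero-variance probes) pass through without entering the adjustment
  expect_equal(adjust_pvalues(c(0.01, NA, 0.02, 0.03)),
               c(bh_oracle(c(0.01, 0.02, 0.03))[1], NA,
                 bh_oracle(c(0.01, 0.02, 0.03))[2:3]))
})

test_that("genomic inflation behaves at its anchors", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)

  set.seed(6)
  expect_equal(genomic_inflation(runif(1e5)), 1, tolerance = 0.02)

  enriched <- c(runif(900), runif(100, 0, 1e-4))
  expect_gt(genomic_inflation(enriched), 1)

  expect_warning(l <- genomic_inflation(rep(1, 200)), "lambda_gc = 0")
  expect_equal(l, 0)
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("null cohorts give calibrated type-I error and uniform p-values", {
  coh <- null_cohort(n_bg = 2000)
  res <- run_dma(coh$dataset)
  p <- res$table$p[!res$table$zero_variance]
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.25)  # 2023 probes
  expect_equal(res$lambda_gc, 1, tolerance = 0.1)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("significance calls are sorted, directional, and respect thresholds", {
  coh <- strong_cohort()
  res <- run_dma(coh$dataset)
  sig <- call_significant(res, 9e-8)
  expect_setequal(sig$probe_id, coh$truth$affected$probe_id)
  expect_true(all(diff(sig$p) >= 0))
  expect_true(all(sig$direction == "hyper"))
  expect_true(all(sig$coef > 0))

  empty <- call_significant(res, 1e-300)
  expect_equal(nrow(empty), 0L)
})
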