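# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Strong-effect cohort: 277 samples / 27 carriers, the 8 implanted locus
# probes at default effect sizes, and a modest null background.
strong_cohort <- function(n_bg = 2000, seed = 7) {
  memo(sprintf("strong_%d_%d", n_bg, seed),
       generate_cohort(implant_table1_profile(
         sim_config(n_background_probes = n_bg, seed = seed))))
}

# Null cohort: no carrier effect anywhere.
null_cohort <- function(n_bg = 2000, seed = 11) {
  memo(sprintf("null_%d_%d", n_bg, seed),
       generate_cohort(sim_config(n_background_probes = n_bg, seed = seed)))
}

# A tiny hand-buildable dataset: n samples, columns given as a list.
toy_dataset <- function(values, carrier, covariates = NULL) {
  m <- do.call(cbind, values)
  rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- names(values)
  meth_dataset(m, covariates = covariates, carrier = carrier)
}

# Independent brute-force least-squares oracle: normal equations, pooled
# residual variance, classical t — no shared code with fit_probe_models.
ols_oracle <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  covb <- s2 * solve(t(X) %*% X)
  cc <- which(colnames(X) == "carrier")
  tstat <- b[cc] / sqrt(covb[cc, cc])
  list(coef = b[cc], se = sqrt(covb[cc, cc]), t = tstat,
       p = 2 * pt(-abs(tstat), df))
}

# Hand transcription of the BH step-up formula.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  cummin_rev <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
  adj[o] <- cummin_rev
  adj
}

# Mean silhouette width of a 2-group labelling of a 1-d score.
silhouette_1d <- function(x, grp) {
  s <- numeric(length(x))
  for (i in seq_along(x)) {
    same <- setdiff(which(grp == grp[i]), i)
    a <- mean(abs(x[i] - x[same]))
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
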