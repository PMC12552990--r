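#' Build the covariate-adjusted design matrix
#'
#' Columns: intercept, carrier indicator, age, sex, five of the six cell
#' fractions (neutrophils dropped — the fractions sum to one, so keeping all
#' six would make the design singular), smoking score, and dummy-coded batch
#' with the first level as reference. Datasets without covariates yield an
#' intercept + carrier design.
#'
#' @param ds a `meth_dataset` with known carrier labels for every sample
#' @return numeric design matrix, samples in rows
#' @export
build_design <- function(ds) {
  stopifnot(inherits(ds, "meth_dataset"))
  if (any(ds$carrier == "unknown"))
    stop("carrier label must be known for every sample; subset first")
  X <- cbind(intercept = 1, carrier = as.numeric(ds$carrier == "carrier"))
  cov <- ds$covariates
  if (!is.null(cov)) {
    keep_frac <- setdiff(intersect(cell_fraction_names(), names(cov)), "Neu")
    for (v in c("age", "sex", keep_frac, "smoking_score"))
      if (v %in% names(cov)) X <- cbind(X, stats::setNames(list(cov[[v]]), v)[[1]])
    colnames(X) <- c("intercept", "carrier",
                     intersect(c("age", "sex", keep_frac, "smoking_score"),
                               names(cov)))
    if ("batch" %in% names(cov)) {
      b <- factor(cov$batch)
      if (nlevels(b) > 1L) {
        dummies <- stats::model.matrix(~ b)[, -1L, drop = FALSE]
        colnames(dummies) <- paste0("batch", levels(b)[-1L])
        X <- cbind(X, dummies)
      }
    }
  }
  rownames(X) <- ds$sample_ids
  X
}

check_design <- function(X) {
  n <- nrow(X)
  if (n < ncol(X) + 2L)
    stop(sprintf("need at least %d samples for %d design columns",
                 ncol(X) + 2L, ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  qx
}

#' Per-probe ordinary least squares of M-values on carrier status + covariates
#'
#' Fits, for every probe, M ~ intercept + carrier + age + sex + 5 cell
#' fractions + smoking + batch dummies by OLS and reports the carrier
#' coefficient (the effect on the M scale), its standard error, the t
#' statistic on residual degrees of freedom, and the two-sided p-value.
#' Probes with zero residual variance are flagged and excluded from p-value
#' ranking (p = NA). Probes with missing values must be removed first
#' (see [drop_incomplete_probes()]).
#'
#' @param ds a `meth_dataset` with known carrier labels
#' @param design optional pre-built design matrix (used by the permutation
#'   machinery); defaults to [build_design()]
#' @return object of class `dma_result`: `table` with columns `probe_id`,
#'   `coef`, `se`, `t`, `df_total`, `p`, `adj_p`, `zero_variance`; fields
#'   `df_residual`, `s2` (residual variances), `stdev_unscaled`, `moderated`
#' @export
fit_probe_models <- function(ds, design = NULL) {
  stopifnot(inherits(ds, "meth_dataset"))
  if (any(is.na(ds$m)))
    stop("dataset has missing M-values; run drop_incomplete_probes() first")
  X <- if (is.null(design)) build_design(ds) else design
  qx <- check_design(X)
  Y <- ds$m
  n <- nrow(X)
  df <- n - ncol(X)

  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  cc <- which(colnames(X) == "carrier")
  unscaled <- sqrt(xtx_inv[cc, cc])

  zero_var <- s2 < .Machine$double.eps * 100
  coef <- coefs[cc, ]
  se <- sqrt(s2) * unscaled
  tstat <- ifelse(zero_var, NA_real_, coef / se)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin  # keep p in (0, 1]

  tab <- data.frame(probe_id = colnames(Y), coef = unname(coef),
                    se = unname(se), t = unname(tstat),
                    df_total = df, p = unname(p), adj_p = NA_real_,
                    zero_variance = unname(zero_var),
                    row.names = NULL)
  structure(list(table = tab, df_residual = df, s2 = unname(s2),
                 stdev_unscaled = unscaled, moderated = FALSE,
                 d0 = 0, s0_sq = NA_real_, lambda_gc = NA_real_,
                 p_adjust_method = "BH", design_columns = colnames(X)),
            class = "dma_result")
}

#' @export
print.dma_result <- function(x, ...) {
  cat("dma_result:", nrow(x$table), "probes,", x$df_residual, "residual df,",
      if (x$moderated) sprintf("moderated (d0 = %.2f, s0^2 = %.4f)", x$d0, x$s0_sq)
      else "unmoderated", "\n")
  if (!is.na(x$lambda_gc)) cat("  lambda_gc =", x$lambda_gc, "\n")
  invisible(x)
}

# Newton solve of trigamma(y) = x, vectorised (monotone decreasing target).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Fit a scaled inverse-chi-square prior to sample variances by matching the
# first two moments of log s^2 (Smyth's method of moments).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond chi-square sampling noise: infinite prior df,
    # every probe shares the pooled variance
    list(d0 = Inf, s0_sq = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Shrinks each probe's residual variance toward a common prior fitted across
#' probes: a scaled inverse-chi-square with `d0` prior degrees of freedom and
#' prior value `s0^2`, estimated by matching moments of the log sample
#' variances. The posterior variance is
#' `(d0 * s0^2 + df * s^2) / (d0 + df)`; the moderated t statistic uses it
#' with `d0 + df` degrees of freedom. When the variances show no excess
#' spread beyond chi-square sampling noise, `d0` is infinite and every probe
#' shares the pooled prior variance (t is then referred to a normal).
#'
#' @param res an unmoderated `dma_result` (at least 50 probes with positive
#'   residual variance)
#' @return the `dma_result` with moderated `t`, `df_total`, `p` and fields
#'   `d0`, `s0_sq`
#' @export
moderate_variances <- function(res) {
  stopifnot(inherits(res, "dma_result"))
  if (res$moderated) return(res)
  ok <- res$s2 > 0
  if (sum(ok) < 50L)
    stop("need at least 50 probes with positive residual variance")
  prior <- fit_variance_prior(res$s2, res$df_residual)
  df <- res$df_residual
  if (is.finite(prior$d0)) {
    s2_post <- (prior$d0 * prior$s0_sq + df * res$s2) / (prior$d0 + df)
    df_total <- df + prior$d0
  } else {
    s2_post <- rep(prior$s0_sq, length(res$s2))
    df_total <- Inf
  }
  tab <- res$table
  tmod <- ifelse(tab$zero_variance, NA_real_,
                 tab$coef / (sqrt(s2_post) * res$stdev_unscaled))
  p <- 2 * stats::pt(-abs(tmod), df_total)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  tab$t <- tmod
  tab$se <- sqrt(s2_post) * res$stdev_unscaled
  tab$df_total <- df_total
  tab$p <- p
  res$table <- tab
  res$s2_posterior <- s2_post
  res$d0 <- prior$d0
  res$s0_sq <- prior$s0_sq
  res$moderated <- TRUE
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment mapped back to input order. Missing entries (e.g.
#' zero-variance probes excluded from ranking) stay missing and do not enter
#' the adjustment.
#'
#' @param p numeric vector of p-values in (0, 1] (NA allowed)
#' @return numeric vector of adjusted p-values
#' @export
adjust_pvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Genomic inflation factor of a p-value distribution
#'
#' lambda_gc = median of the 1-df chi-square quantiles of the two-sided
#' p-values, divided by the null median qchisq(0.5, 1) = 0.4549. Values near
#' 1 indicate no systematic test-statistic inflation. Reported to three
#' decimals.
#'
#' @param p numeric vector of at least 100 p-values (NA dropped)
#' @return lambda_gc (scalar)
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100L) stop("need at least 100 p-values")
  if (all(p == 1)) {
    warning("all p-values are 1; lambda_gc = 0")
    return(0)
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  round(stats::median(chisq) / stats::qchisq(0.5, df = 1), 3)
}

#' Run the full differential methylation analysis
#'
#' OLS per probe, optional empirical-Bayes moderation, BH adjustment, and the
#' genomic inflation factor.
#'
#' @param ds a `meth_dataset` with known carrier labels
#' @param moderate apply [moderate_variances()] (default TRUE)
#' @param design optional pre-built design matrix
#' @return a `dma_result`
#' @export
run_dma <- function(ds, moderate = TRUE, design = NULL) {
  res <- fit_probe_models(ds, design = design)
  if (moderate) res <- moderate_variances(res)
  res$table$adj_p <- adjust_pvalues(res$table$p)
  ranked <- res$table$p[!res$table$zero_variance]
  res$lambda_gc <- if (sum(!is.na(ranked)) >= 100L) genomic_inflation(ranked)
                   else NA_real_
  res
}

#' Probes passing a significance threshold
#'
#' Returns probes with `p < threshold` (strictly more significant than the
#' threshold), sorted by ascending p, with the direction of the carrier
#' effect annotated (`hyper` for positive M-scale coefficients, `hypo`
#' otherwise). Zero-variance probes never qualify.
#'
#' @param res a `dma_result`
#' @param threshold the active significance cut: either the literature
#'   epigenome-wide value 9e-8 or a permutation-derived threshold
#' @return data.frame of significant probes with `direction`
#' @export
call_significant <- function(res, threshold = 9e-8) {
  stopifnot(inherits(res, "dma_result"), threshold > 0, threshold < 1)
  tab <- res$table
  hit <- !tab$zero_variance & !is.na(tab$p) & tab$p < threshold
  out <- tab[hit, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  out$direction <- ifelse(out$coef > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}
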