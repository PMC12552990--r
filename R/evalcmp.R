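#' Repeated train/test evaluation of the locus classifier
#'
#' Runs `n_iter` independent 70/30 stratified splits; each iteration trains a
#' fresh L1 logistic model (penalty chosen by cross-validated deviance) on
#' the training part and scores the held-out part. Per-iteration seeds are
#' `root_seed + i` for auditability; the whole procedure is deterministic
#' given `root_seed`.
#'
#' @param ds a `meth_dataset` with known carrier labels
#' @param probes feature probe ids
#' @param n_iter number of repeated splits (default 100)
#' @param root_seed integer root seed
#' @param train_fraction training proportion (default 0.7)
#' @param cv_folds CV folds for the penalty search (default 10)
#' @param threshold classification probability cut (default 0.5)
#' @return object of class `evaluation_result`: `metrics` (one row per
#'   iteration: seed, accuracy, type1, type2, tp, fp, tn, fn) and `summary`
#'   (mean and SD of each metric)
#' @export
repeated_evaluation <- function(ds, probes, n_iter = 100L, root_seed = 1L,
                                train_fraction = 0.7, cv_folds = 10L,
                                threshold = 0.5) {
  stopifnot(inherits(ds, "meth_dataset"), n_iter >= 2L)
  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    seed_i <- root_seed + i
    res <- tryCatch({
      sp <- split_train_test(ds, train_fraction, seed = seed_i,
                             stratified = TRUE)
      model <- train_lasso(sp$train, probes, cv_folds = cv_folds,
                           seed = seed_i)
      pred <- predict_carriers(model, sp$test, threshold = threshold)
      met <- split_metrics(sp$test$carrier, pred$label)
      data.frame(iteration = i, seed = seed_i,
                 accuracy = met$accuracy, type1 = met$type1,
                 type2 = met$type2, tp = met$tp, fp = met$fp,
                 tn = met$tn, fn = met$fn)
    }, error = function(e) {
      stop(sprintf("iteration %d (seed %d) failed: %s", i, seed_i,
                   conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- res
  }
  metrics <- do.call(rbind, rows)
  summarise <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  structure(list(metrics = metrics,
                 summary = list(accuracy = summarise(metrics$accuracy),
                                type1 = summarise(metrics$type1),
                                type2 = summarise(metrics$type2)),
                 n_iterations = n_iter, root_seed = root_seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result:", x$n_iterations, "repeated splits\n")
  for (m in c("accuracy", "type1", "type2"))
    cat(sprintf("  %-8s mean %.4f (sd %.4f)\n", m,
                x$summary[[m]]["mean"], x$summary[[m]]["sd"]))
  invisible(x)
}

welch_or_degenerate <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # identical constant distributions: no evidence of difference
    if (isTRUE(all.equal(mean(a), mean(b)))) return(list(statistic = 0, p.value = 1))
    return(list(statistic = Inf, p.value = 0))
  }
  tt <- stats::t.test(a, b)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Compare classifier performance across array platform probe subsets
#'
#' Evaluates the classifier on the probe subsets present on each array
#' generation (EPICv2/EPICv1/Methyl450K/Methyl27K: 23/12/5/2 probes with the
#' packaged manifest) and compares the per-iteration metric distributions
#' between every platform pair with a two-sided Welch t-test (a Wilcoxon
#' rank-sum alternative is available). By default the same root seed is
#' shared across platforms so every platform sees identical splits (paired
#' design); `paired = FALSE` draws independent splits per platform.
#'
#' @param ds a `meth_dataset`
#' @param ann probe annotation with platform flags
#' @param n_iter repeated splits per platform (default 100)
#' @param root_seed integer root seed
#' @param platforms platform columns to evaluate
#' @param test `"welch"` (default) or `"wilcoxon"`
#' @param paired share split seeds across platforms (default TRUE)
#' @param ... passed to [repeated_evaluation()]
#' @return list with `evaluations` (named list of `evaluation_result`) and
#'   `comparison` (data.frame platform_a, platform_b, metric, statistic,
#'   p_value, test)
#' @export
platform_degradation <- function(ds, ann, n_iter = 100L, root_seed = 1L,
                                 platforms = c("epicv2", "epicv1",
                                               "m450k", "m27k"),
                                 test = c("welch", "wilcoxon"),
                                 paired = TRUE, ...) {
  test <- match.arg(test)
  evaluations <- list()
  for (k in seq_along(platforms)) {
    pf <- platforms[k]
    probes <- tryCatch(select_locus_probes(ann, platform = pf),
                       error = function(e) character(0))
    if (length(probes) == 0L) {
      warning("platform ", pf, " has no locus probes; skipped")
      next
    }
    seed_pf <- if (paired) root_seed else root_seed + (k - 1L) * 100000L
    evaluations[[pf]] <- repeated_evaluation(ds, probes, n_iter = n_iter,
                                             root_seed = seed_pf, ...)
  }
  pfs <- names(evaluations)
  comp <- list()
  for (i in seq_along(pfs)) for (j in seq_along(pfs)) {
    if (i >= j) next
    for (metric in c("accuracy", "type1", "type2")) {
      a <- evaluations[[pfs[i]]]$metrics[[metric]]
      b <- evaluations[[pfs[j]]]$metrics[[metric]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      r <- if (test == "welch") welch_or_degenerate(a, b)
           else { w <- stats::wilcox.test(a, b, exact = FALSE)
                  list(statistic = unname(w$statistic), p.value = w$p.value) }
      comp[[length(comp) + 1L]] <-
        data.frame(platform_a = pfs[i], platform_b = pfs[j], metric = metric,
                   statistic = r$statistic,
                   p_value = max(r$p.value, .Machine$double.xmin),
                   test = if (test == "welch") "welch_t" else "wilcoxon")
    }
  }
  list(evaluations = evaluations, comparison = do.call(rbind, comp))
}

#' Apply a frozen model to an independent cohort
#'
#' Scores every sample with [predict_carriers()] and summarises the predicted
#' carriers: ids, count, and cohort prevalence (= predicted carriers / total
#' samples).
#'
#' @param model a `predictor_model`
#' @param ds a `meth_dataset`; carrier labels may be unknown
#' @param threshold probability cut (default 0.5)
#' @return list with `predictions` (per-sample data.frame),
#'   `predicted_carriers` (ids), `n_predicted`, `prevalence`
#' @export
apply_model <- function(model, ds, threshold = 0.5) {
  stopifnot(inherits(ds, "meth_dataset"))
  if (nrow(ds$m) == 0L) stop("dataset has no samples")
  pred <- predict_carriers(model, ds, threshold = threshold)
  ids <- pred$sample_id[pred$label == "carrier"]
  list(predictions = pred,
       predicted_carriers = ids,
       n_predicted = length(ids),
       prevalence = length(ids) / nrow(pred))
}
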