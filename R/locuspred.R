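#' Select locus probes present on a given array platform
#'
#' Restricts the annotation to probes within the target region (the
#' `in_region` flag, i.e. the gene body plus 1-kb flanks, or an explicit
#' `region` when the flag is absent) that are present on the requested
#' platform generation, ordered by genomic position. The packaged C9orf72
#' manifest yields 23 (EPICv2), 12 (EPICv1), 5 (Methyl450K) and 2 (Methyl27K)
#' probes.
#'
#' @param ann probe annotation data.frame
#' @param platform one of `"epicv2"`, `"epicv1"`, `"m450k"`, `"m27k"`
#' @param region optional `list(chrom=, start=, end=)`, 1-based inclusive,
#'   used instead of `in_region` when supplied
#' @return character vector of probe ids ordered by position
#' @export
select_locus_probes <- function(ann,
                                platform = c("epicv2", "epicv1", "m450k", "m27k"),
                                region = NULL) {
  platform <- match.arg(platform)
  if (!platform %in% names(ann)) stop("annotation lacks platform column ", platform)
  in_reg <- if (!is.null(region)) {
    ann$chrom == region$chrom & ann$pos >= region$start & ann$pos <= region$end
  } else if ("in_region" %in% names(ann)) {
    ann$in_region
  } else stop("annotation has no in_region column and no region was given")
  keep <- in_reg & ann[[platform]]
  if (!any(keep))
    stop("no probes selected; check the region coordinates and platform flag")
  ann$probe_id[keep][order(ann$pos[keep])]
}

#' Stratified train/test split of a cohort
#'
#' Splits samples into disjoint, exhaustive train and test sets. Under
#' stratification (the default) each carrier class contributes
#' `round(train_fraction * n_class)` samples to the training set, so the
#' carrier proportion is preserved within one sample in each part. The
#' unstratified mode draws `round(train_fraction * n)` samples ignoring
#' class, in which case a part may lose a class entirely.
#'
#' @param ds a `meth_dataset` with known carrier labels
#' @param train_fraction proportion in (0, 1) (default 0.7)
#' @param seed integer seed
#' @param stratified preserve class balance (default TRUE)
#' @return list with `train` and `test` datasets
#' @export
split_train_test <- function(ds, train_fraction = 0.7, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(ds, "meth_dataset"),
            train_fraction > 0, train_fraction < 1)
  if (any(ds$carrier == "unknown"))
    stop("carrier label must be known for every sample")
  classes <- unique(ds$carrier)
  if (length(classes) < 2L) stop("both carrier classes must be present")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_train <- integer(0)
  if (stratified) {
    for (cl in c("carrier", "non_carrier")) {
      cl_idx <- which(ds$carrier == cl)
      k <- round(train_fraction * length(cl_idx))
      if (k == 0L || k == length(cl_idx))
        stop("class '", cl, "' would be absent from one part; too few samples")
      idx_train <- c(idx_train, sample(cl_idx, k))
    }
  } else {
    idx_train <- sample(nrow(ds$m), round(train_fraction * nrow(ds$m)))
  }
  idx_train <- sort(idx_train)
  list(train = subset_dataset(ds, samples = ds$sample_ids[idx_train]),
       test = subset_dataset(ds, samples = ds$sample_ids[-idx_train]))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train an L1-penalised logistic carrier classifier on locus probes
#'
#' Standardises each probe by its training mean and SD, then fits a LASSO
#' logistic regression over a penalty path, choosing the penalty that
#' minimises the mean cross-validated binomial deviance over stratified
#' folds, and refits on the full training set at that penalty. The fitted
#' coefficients are stored on the standardised scale together with the
#' centring/scaling transform, so a frozen model is portable.
#'
#' @param train a `meth_dataset` with >= 2 carriers, no missing values in the
#'   selected probes
#' @param probes probe ids to use as features
#' @param cv_folds number of CV folds (default 10)
#' @param seed integer seed (fold assignment and glmnet internals)
#' @return object of class `predictor_model` with `probe_ids`, `intercept`,
#'   `coefficients` (standardised scale), `penalty`, `cv_folds`, `center`,
#'   `scale`, `training_meta`
#' @export
train_lasso <- function(train, probes, cv_folds = 10L, seed = 1L) {
  stopifnot(inherits(train, "meth_dataset"))
  missing <- setdiff(probes, train$probe_ids)
  if (length(missing))
    stop("probes absent from training matrix: ", paste(missing, collapse = ", "))
  if (sum(train$carrier == "carrier") < 2L)
    stop("need at least 2 carriers in the training set")
  X <- train$m[, probes, drop = FALSE]
  if (any(is.na(X))) stop("missing values among selected probes")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant features: ",
            paste(probes[sds == 0], collapse = ", "))
    probes <- probes[sds > 0]
    X <- X[, probes, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (length(probes) == 0L) stop("no non-constant features remain")
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  y <- as.numeric(train$carrier == "carrier")

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  foldid <- stratified_folds(y, cv_folds, seed)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(list(probe_ids = probes,
                 intercept = co[1L],
                 coefficients = stats::setNames(co[-1L], probes),
                 penalty = cv$lambda.min,
                 cv_folds = as.integer(cv_folds),
                 center = ctr, scale = sds,
                 training_meta = list(seed = seed,
                                      n_train = nrow(X),
                                      n_carriers = sum(y),
                                      lambda_rule = "lambda.min")),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("predictor_model:", length(x$probe_ids), "probes,", nz,
      "with nonzero coefficients\n")
  cat(sprintf("  penalty (lambda): %.5g; %d-fold CV; trained on %d samples (%d carriers)\n",
              x$penalty, x$cv_folds, x$training_meta$n_train,
              x$training_meta$n_carriers))
  invisible(x)
}

#' Predict carrier status with a frozen model
#'
#' probability = logistic(intercept + sum of coefficient * standardised
#' M-value); a sample is called a carrier when its probability exceeds the
#' threshold. Every model probe must be present — missing probes are an
#' error, never silently imputed.
#'
#' @param model a `predictor_model`
#' @param ds a `meth_dataset` containing all model probes
#' @param threshold probability cut in (0, 1), default 0.5
#' @return data.frame with `sample_id`, `probability`, `label`
#' @export
predict_carriers <- function(model, ds, threshold = 0.5) {
  stopifnot(inherits(model, "predictor_model"), inherits(ds, "meth_dataset"),
            threshold > 0, threshold < 1)
  if (nrow(ds$m) == 0L) stop("dataset has no samples")
  missing <- setdiff(model$probe_ids, ds$probe_ids)
  if (length(missing))
    stop("model probes absent from dataset: ", paste(missing, collapse = ", "))
  X <- ds$m[, model$probe_ids, drop = FALSE]
  Xs <- scale(X, center = model$center, scale = model$scale)
  eta <- model$intercept + drop(Xs %*% model$coefficients)
  prob <- stats::plogis(eta)
  data.frame(sample_id = ds$sample_ids,
             probability = unname(prob),
             label = ifelse(prob > threshold, "carrier", "non_carrier"),
             row.names = NULL)
}

#' Write / read a frozen predictor model as plain text
#'
#' Key-value header followed by a probe/center/scale/coefficient table; a
#' round trip reproduces the model to full double precision.
#'
#' @param model a `predictor_model`
#' @param path file path
#' @return `read_predictor_model` returns a `predictor_model`
#' @export
write_predictor_model <- function(model, path) {
  stopifnot(inherits(model, "predictor_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("intercept\t%.17g", model$intercept),
               sprintf("penalty\t%.17g", model$penalty),
               sprintf("cv_folds\t%d", model$cv_folds),
               sprintf("seed\t%d", model$training_meta$seed),
               sprintf("n_train\t%d", model$training_meta$n_train),
               sprintf("n_carriers\t%d", model$training_meta$n_carriers),
               "probe_id\tcenter\tscale\tcoefficient"), con)
  writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", model$probe_ids,
                     model$center, model$scale, model$coefficients), con)
  invisible(path)
}

#' @rdname write_predictor_model
#' @export
read_predictor_model <- function(path) {
  lines <- readLines(path)
  hdr_n <- which(startsWith(lines, "probe_id\t"))[1L]
  kv <- do.call(rbind, strsplit(lines[seq_len(hdr_n - 1L)], "\t"))
  key <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.delim(textConnection(lines[hdr_n:length(lines)]),
                           sep = "\t")
  structure(list(probe_ids = tab$probe_id,
                 intercept = as.numeric(key[["intercept"]]),
                 coefficients = stats::setNames(tab$coefficient, tab$probe_id),
                 penalty = as.numeric(key[["penalty"]]),
                 cv_folds = as.integer(key[["cv_folds"]]),
                 center = stats::setNames(tab$center, tab$probe_id),
                 scale = stats::setNames(tab$scale, tab$probe_id),
                 training_meta = list(seed = as.integer(key[["seed"]]),
                                      n_train = as.integer(key[["n_train"]]),
                                      n_carriers = as.integer(key[["n_carriers"]]),
                                      lambda_rule = "lambda.min")),
            class = "predictor_model")
}

#' First two principal components of the locus probes
#'
#' Column-centred PCA of the sample x probe submatrix; returns the score
#' matrix for components 1 and 2 with the sign fixed so that the loading of
#' the first (left-most) probe is non-negative on each component.
#'
#' @param ds a `meth_dataset` (at least 3 samples)
#' @param probes at least 2 probe ids present in the dataset
#' @return numeric matrix samples x 2 (`PC1`, `PC2`)
#' @export
locus_pca <- function(ds, probes) {
  stopifnot(inherits(ds, "meth_dataset"), length(probes) >= 2L,
            nrow(ds$m) >= 3L)
  X <- ds$m[, probes, drop = FALSE]
  if (all(apply(X, 2L, stats::sd) == 0)) stop("all probes have zero variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  flip <- ifelse(pc$rotation[1L, seq_len(k)] < 0, -1, 1)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Confusion-matrix metrics for carrier prediction
#'
#' type I error = FP / (FP + TN) (false-positive rate among true
#' non-carriers); type II error = FN / (FN + TP) (false-negative rate among
#' true carriers). A part without true carriers yields `type2 = NA`.
#'
#' @param truth character vector of true labels (`carrier` / `non_carrier`)
#' @param predicted character vector of predicted labels
#' @return list with `accuracy`, `type1`, `type2`, `tp`, `fp`, `tn`, `fn`
#' @export
split_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == "carrier" & predicted == "carrier")
  fp <- sum(truth == "non_carrier" & predicted == "carrier")
  tn <- sum(truth == "non_carrier" & predicted == "non_carrier")
  fn <- sum(truth == "carrier" & predicted == "non_carrier")
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       type1 = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       type2 = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
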