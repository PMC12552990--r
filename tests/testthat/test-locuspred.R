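test_that("locus probe selection reflects platform content", {
  ann <- read_probe_manifest()
  expect_length(select_locus_probes(ann, "epicv2"), 23L)
  expect_length(select_locus_probes(ann, "epicv1"), 12L)
  expect_length(select_locus_probes(ann, "m450k"), 5L)
  m27k <- select_locus_probes(ann, "m27k")
  expect_setequal(m27k, c("cg23074747", "cg11613875"))

  probes <- select_locus_probes(ann, "epicv2")
  expect_true(all(diff(ann$pos[match(probes, ann$probe_id)]) > 0))

  expect_error(select_locus_probes(ann, "epicv2",
                                   region = list(chrom = "chr9",
                                                 start = 1, end = 100)),
               "no probes")
  # explicit region overrides the flag
  reg <- select_locus_probes(ann, "epicv2",
                             region = list(chrom = "chr9",
                                           start = 27573800, end = 27573900))
  expect_setequal(reg, c("cg23074747", "cg13533397", "cg11613875"))
})

test_that("stratified splits preserve class balance and partition the cohort", {
  ds <- strong_cohort(n_bg = 0)$dataset
  sp <- split_train_test(ds, 0.7, seed = 13)
  expect_equal(nrow(sp$train$m), 194L)  # round(0.7*27) + round(0.7*250)
  expect_equal(sum(sp$train$carrier == "carrier"), 19L)
  expect_equal(sum(sp$test$carrier == "carrier"), 8L)

  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), ds$sample_ids)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0L)

  sp2 <- split_train_test(ds, 0.7, seed = 13)
  expect_identical(sp2$train$sample_ids, sp$train$sample_ids)

  tiny <- toy_dataset(list(cgA = rnorm(4)),
                      c("carrier", rep("non_carrier", 3)))
  expect_error(split_train_test(tiny, 0.7, seed = 1), "absent")
})

test_that("a perfectly separating probe yields a perfect, sparse model", {
  set.seed(14)
  n <- 100; ncar <- 15
  carrier <- c(rep("carrier", ncar), rep("non_carrier", n - ncar))
  vals <- list(cgSep = ifelse(carrier == "carrier", 4, -1) + rnorm(n, 0, 0.1))
  for (i in 1:6) vals[[sprintf("cgN%02d", i)]] <- rnorm(n)
  ds <- toy_dataset(vals, carrier)
  sp <- split_train_test(ds, 0.7, seed = 14)
  model <- train_lasso(sp$train, names(vals), seed = 14)
  expect_true(model$coefficients["cgSep"] != 0)
  pred <- predict_carriers(model, sp$test)
  expect_equal(split_metrics(sp$test$carrier, pred$label)$accuracy, 1)
})

test_that("pure-noise probes collapse predictions toward the majority class", {
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 120; ncar <- 12
    carrier <- sample(c(rep("carrier", ncar), rep("non_carrier", n - ncar)))
    vals <- lapply(1:10, function(i) rnorm(n))
    names(vals) <- sprintf("cg%02d", 1:10)
    ds <- toy_dataset(vals, carrier)
    sp <- split_train_test(ds, 0.7, seed = s)
    # few carriers per fold here; glmnet warns about small class counts
    model <- suppressWarnings(
      train_lasso(sp$train, names(vals), cv_folds = 5, seed = s))
    pred <- predict_carriers(model, sp$test)
    split_metrics(sp$test$carrier, pred$label)$accuracy
  }, numeric(1))
  expect_equal(mean(accs), 108 / 120, tolerance = 0.05)
})

test_that("fitted probabilities ignore duplicated or affinely rescaled features", {
  ds <- strong_cohort(n_bg = 0)$dataset
  probes <- ds$probe_ids
  sp <- split_train_test(ds, 0.7, seed = 15)
  model <- train_lasso(sp$train, probes, seed = 15)
  base <- predict_carriers(model, sp$test)$probability

  # duplicate a feature column
  m2 <- cbind(sp$train$m, dup = sp$train$m[, probes[1]])
  colnames(m2)[ncol(m2)] <- "cgDup"
  tr2 <- meth_dataset(m2, covariates = sp$train$covariates,
                      carrier = sp$train$carrier)
  m2t <- cbind(sp$test$m, cgDup = sp$test$m[, probes[1]])
  te2 <- meth_dataset(m2t, covariates = sp$test$covariates,
                      carrier = sp$test$carrier)
  model2 <- train_lasso(tr2, c(probes, "cgDup"), seed = 15)
  expect_equal(predict_carriers(model2, te2)$probability, base,
               tolerance = 1e-6)

  # affine rescaling of one input feature is absorbed by standardisation
  m3 <- sp$train$m; m3[, probes[2]] <- 10 * m3[, probes[2]] + 5
  tr3 <- meth_dataset(m3, carrier = sp$train$carrier)
  m3t <- sp$test$m; m3t[, probes[2]] <- 10 * m3t[, probes[2]] + 5
  te3 <- meth_dataset(m3t, carrier = sp$test$carrier)
  model3 <- train_lasso(tr3, probes, seed = 15)
  expect_equal(predict_carriers(model3, te3)$probability, base,
               tolerance = 1e-6)
})

test_that("prediction uses the stored standardisation and refuses missing probes", {
  model <- structure(list(probe_ids = c("a", "b"), intercept = 0,
                          coefficients = c(a = 0, b = 0),
                          penalty = 0.1, cv_folds = 10,
                          center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
                          training_meta = list(seed = 1, n_train = 0,
                                               n_carriers = 0,
                                               lambda_rule = "lambda.min")),
                     class = "predictor_model")
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  ds <- meth_dataset(m)
  pred <- predict_carriers(model, ds)
  expect_equal(pred$probability, rep(0.5, 3))  # null model
  expect_true(all(pred$label == "non_carrier"))  # 0.5 is not > 0.5

  ds2 <- meth_dataset(matrix(rnorm(3), 3, 1,
                             dimnames = list(paste0("s", 1:3), "a")))
  expect_error(predict_carriers(model, ds2), "\\bb\\b")
})

test_that("a trained model beats the intercept-only model on its own training data", {
  ds <- strong_cohort(n_bg = 0)$dataset
  sp <- split_train_test(ds, 0.7, seed = 16)
  model <- train_lasso(sp$train, ds$probe_ids, seed = 16)
  pred <- predict_carriers(model, sp$train)
  acc <- split_metrics(sp$train$carrier, pred$label)$accuracy
  majority <- mean(sp$train$carrier == "non_carrier")
  expect_gte(acc, majority)

  # a prototype sample sitting at the training carrier means is confidently called
  car_mean <- colMeans(sp$train$m[sp$train$carrier == "carrier", , drop = FALSE])
  proto <- meth_dataset(matrix(car_mean, 1, dimnames = list("proto",
                                                            names(car_mean))))
  expect_gt(predict_carriers(model, proto)$probability, 0.9)
})

test_that("frozen models survive a plain-text round trip", {
  ds <- strong_cohort(n_bg = 0)$dataset
  sp <- split_train_test(ds, 0.7, seed = 18)
  model <- train_lasso(sp$train, ds$probe_ids, seed = 18)
  path <- withr::local_tempfile(fileext = ".model")
  write_predictor_model(model, path)
  back <- read_predictor_model(path)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$center, model$center)
  expect_equal(back$scale, model$scale)
  expect_equal(predict_carriers(back, sp$test), predict_carriers(model, sp$test))
})

test_that("locus PCA separates shifted clusters and respects conventions", {
  set.seed(19)
  n <- 60
  grp <- c(rep("carrier", 20), rep("non_carrier", 40))
  vals <- lapply(1:10, function(i) {
    shift <- if (i <= 5) 3 else 0
    rnorm(n) + ifelse(grp == "carrier", shift, 0)
  })
  names(vals) <- sprintf("cg%02d", 1:10)
  ds <- toy_dataset(vals, grp)
  sc <- locus_pca(ds, names(vals))
  expect_gt(silhouette_1d(sc[, "PC1"], grp), 0.5)

  # probe order only affects the sign convention
  sc2 <- locus_pca(ds, rev(names(vals)))
  expect_true(all(abs(abs(sc2) - abs(sc)) < 1e-8))

  # duplicated sample pattern gets identical scores
  m <- ds$m; m[2, ] <- m[1, ]
  ds3 <- meth_dataset(m, carrier = grp)
  sc3 <- locus_pca(ds3, names(vals))
  expect_equal(sc3[1, ], sc3[2, ])

  flat <- meth_dataset(matrix(1, 5, 3, dimnames = list(paste0("s", 1:5),
                                                       paste0("cg", 1:3))))
  expect_error(locus_pca(flat, paste0("cg", 1:3)), "zero variance")
})

test_that("confusion metrics satisfy their identities", {
  truth <- c(rep("carrier", 5), rep("non_carrier", 15))
  pred <- c(rep("carrier", 3), rep("non_carrier", 2),
            "carrier", rep("non_carrier", 14))
  met <- split_metrics(truth, pred)
  expect_equal(met$tp, 3); expect_equal(met$fn, 2)
  expect_equal(met$fp, 1); expect_equal(met$tn, 14)
  expect_equal(met$accuracy, (met$tp + met$tn) / 20)
  expect_equal(met$type1, met$fp / (met$fp + met$tn))
  expect_equal(met$type2, met$fn / (met$fn + met$tp))

  # no true carriers: type II undefined, not zero
  met0 <- split_metrics(rep("non_carrier", 5), rep("non_carrier", 5))
  expect_true(is.na(met0$type2))
})
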