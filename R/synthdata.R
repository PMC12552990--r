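#' Simulation configuration for a synthetic EPIC-style cohort
#'
#' The defaults reproduce the study conditions the analysis assumes: 277
#' whole-blood samples of which 27 carry a pathogenic C9orf72 repeat
#' expansion, the packaged 23-probe locus manifest, and a genome-wide
#' background of null probes carrying covariate and batch structure but no
#' carrier effect.
#'
#' Residual noise is homoscedastic per probe on the M scale. Locus probes use
#' the fixed `noise_sd_m`; background probes draw their SD from a right-skewed
#' lognormal (median 0.4 M, sdlog 0.4) so that empirical-Bayes moderation has
#' variance heterogeneity to shrink.
#'
#' @param n_samples cohort size
#' @param n_carriers number of repeat-expansion carriers
#' @param n_background_probes number of genome-wide null probes
#' @param locus_manifest probe annotation for the target locus (default: the
#'   packaged C9orf72 manifest)
#' @param affected_probes `data.frame(probe_id, delta_m)`: carrier minus
#'   non-carrier mean M-value shift per affected locus probe (M units);
#'   `NULL` means no carrier effect anywhere
#' @param baseline_beta_by_context named mean beta per island relation
#' @param noise_sd_m residual SD (M units) for locus probes
#' @param background_sd_meanlog,background_sd_sdlog lognormal parameters for
#'   per-probe residual SD of background probes
#' @param covariate_effect_fraction fraction of probes receiving covariate
#'   slopes (confounding structure)
#' @param batch_effect_sd SD of per-batch, per-probe mean offsets (M units)
#' @param n_batches number of experimental batches
#' @param missing_rate proportion of matrix entries set missing at random
#' @param n_failing_samples samples forced above a 5% missingness call-rate
#'   threshold (emulating array failures)
#' @param n_unknown_carrier samples (drawn from non-carriers) whose carrier
#'   label is recorded as `"unknown"`, emulating subjects without repeat
#'   length data
#' @param seed integer seed governing all randomness of the generator
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_samples = 277L,
                       n_carriers = 27L,
                       n_background_probes = 20000L,
                       locus_manifest = read_probe_manifest(),
                       affected_probes = NULL,
                       baseline_beta_by_context = c(island = 0.15, shore = 0.35,
                                                    shelf = 0.55, open_sea = 0.75),
                       noise_sd_m = 0.35,
                       background_sd_meanlog = log(0.4),
                       background_sd_sdlog = 0.4,
                       covariate_effect_fraction = 0.1,
                       batch_effect_sd = 0.15,
                       n_batches = 4L,
                       missing_rate = 0,
                       n_failing_samples = 0L,
                       n_unknown_carrier = 0L,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_carriers = as.integer(n_carriers),
              n_background_probes = as.integer(n_background_probes),
              locus_manifest = locus_manifest,
              affected_probes = affected_probes,
              baseline_beta_by_context = baseline_beta_by_context,
              noise_sd_m = noise_sd_m,
              background_sd_meanlog = background_sd_meanlog,
              background_sd_sdlog = background_sd_sdlog,
              covariate_effect_fraction = covariate_effect_fraction,
              batch_effect_sd = batch_effect_sd,
              n_batches = as.integer(n_batches),
              missing_rate = missing_rate,
              n_failing_samples = as.integer(n_failing_samples),
              n_unknown_carrier = as.integer(n_unknown_carrier),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_carriers <= cfg$n_samples,
            cfg$n_samples > 0, cfg$n_background_probes >= 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_failing_samples >= 0, cfg$n_unknown_carrier >= 0,
            cfg$n_batches >= 1, cfg$noise_sd_m > 0)
  if (!is.null(cfg$affected_probes)) {
    stopifnot(is.data.frame(cfg$affected_probes),
              all(c("probe_id", "delta_m") %in% names(cfg$affected_probes)),
              all(is.finite(cfg$affected_probes$delta_m)))
    absent <- setdiff(cfg$affected_probes$probe_id, cfg$locus_manifest$probe_id)
    if (length(absent))
      stop("affected probes absent from locus manifest: ",
           paste(absent, collapse = ", "))
  }
  invisible(cfg)
}

#' Mark the eight differentially methylated locus probes as affected
#'
#' Flags the eight CpGs found hypermethylated in expansion carriers
#' (cg13533410, cg01589701, cg01589155, cg14363787, cg23074747, cg03854581,
#' cg13533404, cg05151778) with a decreasing effect-size profile from
#' `delta_max` down to `delta_min` M units, in that order. Idempotent.
#'
#' @param cfg a `sim_config` whose manifest contains the eight probes
#' @param delta_max,delta_min end points of the implanted M shift profile
#' @return the updated `sim_config`
#' @export
implant_table1_profile <- function(cfg, delta_max = 4.0, delta_min = 1.5) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- c("cg13533410", "cg01589701", "cg01589155", "cg14363787",
           "cg23074747", "cg03854581", "cg13533404", "cg05151778")
  absent <- setdiff(ids, cfg$locus_manifest$probe_id)
  if (length(absent))
    stop("locus manifest lacks affected probes: ", paste(absent, collapse = ", "))
  cfg$affected_probes <- data.frame(
    probe_id = ids,
    delta_m = seq(delta_max, delta_min, length.out = length(ids)))
  validate_sim_config(cfg)
  cfg
}

# Dirichlet draw via normalized gammas; neutrophil-dominant blood means.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

draw_covariates <- function(n, n_batches) {
  age <- stats::rnorm(n, 63, 8)
  while (any(out <- age < 30 | age > 95)) age[out] <- stats::rnorm(sum(out), 63, 8)
  frac <- rdirichlet(n, 60 * c(CD8T = 0.08, CD4T = 0.15, NK = 0.06,
                               B = 0.07, Mono = 0.08, Neu = 0.56))
  colnames(frac) <- cell_fraction_names()
  data.frame(age = age,
             sex = stats::rbinom(n, 1, 0.4),
             frac,
             smoking_score = stats::rnorm(n),
             batch = paste0("B", sample.int(n_batches, n, replace = TRUE)))
}

build_probe_annotation <- function(cfg) {
  locus <- cfg$locus_manifest
  if (cfg$n_background_probes == 0L) return(locus)
  nbg <- cfg$n_background_probes
  bg <- data.frame(
    probe_id = sprintf("bg%06d", seq_len(nbg)),
    chrom = paste0("chr", sample.int(22L, nbg, replace = TRUE)),
    pos = sample.int(2e8L, nbg, replace = TRUE),
    island_relation = sample(c("island", "shore", "shelf", "open_sea"), nbg,
                             replace = TRUE, prob = c(0.3, 0.25, 0.1, 0.35)),
    gene = "", in_region = FALSE,
    epicv2 = TRUE, epicv1 = TRUE, m450k = TRUE, m27k = TRUE,
    qc_flags = "")
  rbind(locus[names(bg)], bg)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed`. Carriers receive the configured `delta_m`
#' mean shift at affected probes only; all other probes satisfy the null while
#' carrying covariate and batch structure. Covariates: age ~ N(63, 8) truncated
#' to \[30, 95\], sex ~ Bernoulli(0.4), cell fractions ~ neutrophil-dominant
#' Dirichlet (summing to 1 exactly), smoking score ~ N(0, 1), batch uniform.
#'
#' @param cfg a `sim_config`
#' @return list with `dataset` (a [meth_dataset()] with carrier labels),
#'   `annotation` (probe table spanning locus + background probes), and
#'   `truth` (carrier labels, affected probe table, per-probe null indicator)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  carrier <- rep("non_carrier", n)
  carrier[sample(n, cfg$n_carriers)] <- "carrier"

  cov <- draw_covariates(n, cfg$n_batches)
  ann <- build_probe_annotation(cfg)
  p <- nrow(ann)
  is_locus <- ann$in_region

  baseline_beta <- cfg$baseline_beta_by_context[ann$island_relation]
  baseline_m <- beta_to_m(unname(baseline_beta)) + stats::rnorm(p, 0, 0.5)

  sd_probe <- ifelse(is_locus, cfg$noise_sd_m,
                     stats::rlnorm(p, cfg$background_sd_meanlog,
                                   cfg$background_sd_sdlog))

  # covariate confounding on a random subset of probes
  n_conf <- round(cfg$covariate_effect_fraction * p)
  conf_idx <- if (n_conf > 0) sample(p, n_conf) else integer(0)
  slope_age <- slope_sex <- slope_smoke <- slope_cell <- numeric(p)
  cell_pick <- sample(6L, p, replace = TRUE)
  if (n_conf > 0) {
    slope_age[conf_idx] <- stats::rnorm(n_conf, 0, 0.005)
    slope_sex[conf_idx] <- stats::rnorm(n_conf, 0, 0.15)
    slope_smoke[conf_idx] <- stats::rnorm(n_conf, 0, 0.10)
    slope_cell[conf_idx] <- stats::rnorm(n_conf, 0, 0.8)
  }
  batch_offsets <- matrix(stats::rnorm(cfg$n_batches * p, 0, cfg$batch_effect_sd),
                          nrow = cfg$n_batches)

  delta <- numeric(p)
  if (!is.null(cfg$affected_probes))
    delta[match(cfg$affected_probes$probe_id, ann$probe_id)] <-
      cfg$affected_probes$delta_m

  cellmat <- as.matrix(cov[cell_fraction_names()])
  cell_val <- cellmat[, cell_pick, drop = FALSE]  # n x p, chosen fraction per probe
  batch_idx <- as.integer(sub("^B", "", cov$batch))
  is_carrier <- carrier == "carrier"

  m <- matrix(baseline_m, nrow = n, ncol = p, byrow = TRUE) +
    outer(cov$age - 63, slope_age) +
    outer(cov$sex, slope_sex) +
    outer(cov$smoking_score, slope_smoke) +
    sweep(cell_val, 2L, slope_cell, `*`) +
    batch_offsets[batch_idx, , drop = FALSE] +
    outer(as.numeric(is_carrier), delta) +
    matrix(stats::rnorm(n * p), n, p) * matrix(sd_probe, n, p, byrow = TRUE)
  dimnames(m) <- list(sample_ids, ann$probe_id)

  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * length(m))
    if (nmiss > 0) m[sample(length(m), nmiss)] <- NA_real_
  }
  # call-rate failures and missing-repeat-data subjects are disjoint and both
  # drawn from non-carriers, so the carriers survive the cohort accounting
  nc_idx <- which(carrier == "non_carrier")
  if (cfg$n_failing_samples + cfg$n_unknown_carrier > length(nc_idx))
    stop("not enough non-carriers for the failing/unknown sample counts")
  fail <- integer(0)
  if (cfg$n_failing_samples > 0) {
    fail <- sample(nc_idx, cfg$n_failing_samples)
    for (i in fail) m[i, sample(p, ceiling(0.10 * p))] <- NA_real_
  }
  observed <- carrier
  if (cfg$n_unknown_carrier > 0)
    observed[sample(setdiff(nc_idx, fail), cfg$n_unknown_carrier)] <- "unknown"

  truth <- list(carrier = stats::setNames(carrier, sample_ids),
                affected = if (is.null(cfg$affected_probes))
                  data.frame(probe_id = character(0), delta_m = numeric(0))
                else cfg$affected_probes,
                is_null = stats::setNames(delta == 0, ann$probe_id))

  list(dataset = meth_dataset(m, covariates = cov, carrier = observed),
       annotation = ann, truth = truth)
}

#' Generate an independent validation cohort with hidden carrier labels
#'
#' Same probe universe and generative model as [generate_cohort()], but the
#' dataset's carrier field is `"unknown"` for every sample; true labels live
#' only in the returned ground truth. Used to test frozen-model application.
#'
#' @param cfg a `sim_config`; `cfg$n_carriers` is ignored
#' @param n_hidden_carriers number of true carriers hidden in the cohort
#' @return list with `dataset`, `annotation`, `truth`
#' @export
generate_independent_cohort <- function(cfg, n_hidden_carriers) {
  stopifnot(inherits(cfg, "sim_config"),
            n_hidden_carriers <= cfg$n_samples, n_hidden_carriers >= 0)
  cfg$n_carriers <- as.integer(n_hidden_carriers)
  cfg$n_unknown_carrier <- 0L
  out <- generate_cohort(cfg)
  out$dataset$carrier <- rep("unknown", cfg$n_samples)
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
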