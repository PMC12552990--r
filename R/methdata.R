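#' Construct a methylation dataset
#'
#' Bundles a sample x probe matrix of M-values with per-sample covariates and
#' a tri-state carrier label. M-values are log2 methylated/unmethylated odds;
#' all modelling in this package happens on the M scale.
#'
#' @param m numeric matrix, samples in rows, probes in columns, with row and
#'   column names. Missing values are `NA`, never zero.
#' @param covariates optional `data.frame` keyed by row to the samples of `m`,
#'   with columns `age`, `sex` (0/1), the six blood cell fractions `CD8T`,
#'   `CD4T`, `NK`, `B`, `Mono`, `Neu` (proportions summing to 1 within 0.02),
#'   `smoking_score`, and `batch` (categorical).
#' @param carrier optional character/factor of length `nrow(m)` with values
#'   `"carrier"`, `"non_carrier"` or `"unknown"`; defaults to all `"unknown"`.
#' @return An object of class `meth_dataset` with elements `m`, `covariates`,
#'   `carrier`, `sample_ids`, `probe_ids`.
#' @export
meth_dataset <- function(m, covariates = NULL, carrier = NULL) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("`m` must be a numeric matrix (samples x probes)")
  if (is.null(rownames(m))) {
    if (nrow(m) > 0L) stop("`m` must have sample row names")
    rownames(m) <- character(0)
  }
  if (is.null(colnames(m))) {
    if (ncol(m) > 0L) stop("`m` must have probe column names")
    colnames(m) <- character(0)
  }
  dup_s <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_s)) stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  dup_p <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_p)) stop("duplicate probe ids: ", paste(dup_p, collapse = ", "))
  if (any(is.infinite(m))) stop("`m` contains non-finite values")

  if (is.null(carrier)) carrier <- rep("unknown", nrow(m))
  carrier <- as.character(carrier)
  bad <- setdiff(unique(carrier), c("carrier", "non_carrier", "unknown"))
  if (length(bad)) stop("invalid carrier labels: ", paste(bad, collapse = ", "))
  if (length(carrier) != nrow(m)) stop("carrier length does not match sample count")

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(m)) stop("covariate rows do not match sample count")
    cf <- intersect(cell_fraction_names(), names(covariates))
    if (length(cf) == 6L) {
      frac <- as.matrix(covariates[, cf])
      if (any(frac < 0 | frac > 1)) stop("cell fractions must lie in [0, 1]")
      if (any(abs(rowSums(frac) - 1) > 0.02))
        stop("cell fractions must sum to 1 within 0.02 per sample")
    }
    rownames(covariates) <- rownames(m)
  }

  structure(
    list(m = m, covariates = covariates, carrier = carrier,
         sample_ids = rownames(m), probe_ids = colnames(m)),
    class = "meth_dataset")
}

cell_fraction_names <- function() c("CD8T", "CD4T", "NK", "B", "Mono", "Neu")

#' @export
print.meth_dataset <- function(x, ...) {
  cat("meth_dataset:", nrow(x$m), "samples x", ncol(x$m), "probes\n")
  cat("  carrier:", sum(x$carrier == "carrier"), "carrier /",
      sum(x$carrier == "non_carrier"), "non-carrier /",
      sum(x$carrier == "unknown"), "unknown\n")
  cat("  covariates:", if (is.null(x$covariates)) "none"
      else paste(names(x$covariates), collapse = ", "), "\n")
  cat("  missing values:", sum(is.na(x$m)), "\n")
  invisible(x)
}

#' @export
dim.meth_dataset <- function(x) dim(x$m)

#' Subset a dataset by sample and/or probe ids
#'
#' Order of the retained samples and probes follows the original dataset.
#'
#' @param ds a `meth_dataset`
#' @param samples,probes character vectors of ids to keep (default: all)
#' @return a `meth_dataset`
#' @export
subset_dataset <- function(ds, samples = NULL, probes = NULL) {
  stopifnot(inherits(ds, "meth_dataset"))
  keep_s <- if (is.null(samples)) rep(TRUE, nrow(ds$m)) else ds$sample_ids %in% samples
  keep_p <- if (is.null(probes)) rep(TRUE, ncol(ds$m)) else ds$probe_ids %in% probes
  meth_dataset(ds$m[keep_s, keep_p, drop = FALSE],
               covariates = if (is.null(ds$covariates)) NULL
                            else ds$covariates[keep_s, , drop = FALSE],
               carrier = ds$carrier[keep_s])
}

infer_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a methylation matrix from delimited text
#'
#' Reads a TSV (or CSV) with a header row of ids and the first column holding
#' row ids. The file may store samples in rows or probes in rows; the
#' orientation is declared, never guessed, and the returned dataset is always
#' samples x probes. The missing token is "NA" and is kept as missing.
#'
#' @param path file path
#' @param orientation `"samples_by_probes"` (rows are samples) or
#'   `"probes_by_samples"` (rows are probes)
#' @param covariates,carrier passed to [meth_dataset()]
#' @return a `meth_dataset` (covariates `NULL` unless supplied)
#' @export
read_methylation_matrix <- function(path,
                                    orientation = c("samples_by_probes",
                                                    "probes_by_samples"),
                                    covariates = NULL, carrier = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, sep = infer_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate row ids in ", path, ": ", paste(dup, collapse = ", "))
  cn <- colnames(raw)[-1L]
  dup <- unique(cn[duplicated(cn)])
  if (length(dup)) stop("duplicate column ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value %s at row '%s', column '%s' in %s",
                 dQuote(vals[bad[1, 1], bad[1, 2]]), ids[bad[1, 1]],
                 cn[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, cn)
  if (orientation == "probes_by_samples") num <- t(num)
  meth_dataset(num, covariates = covariates, carrier = carrier)
}

#' Write a methylation matrix as delimited text
#'
#' @param ds a `meth_dataset`
#' @param path output path
#' @param orientation as in [read_methylation_matrix()]
#' @param sep field separator (tab default)
#' @export
write_methylation_matrix <- function(ds, path,
                                     orientation = c("samples_by_probes",
                                                     "probes_by_samples"),
                                     sep = "\t") {
  stopifnot(inherits(ds, "meth_dataset"))
  orientation <- match.arg(orientation)
  m <- if (orientation == "samples_by_probes") ds$m else t(ds$m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "samples_by_probes") "sample_id" else "probe_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert beta-values to M-values
#'
#' M = log2(beta / (1 - beta)), with beta clipped to `[eps, 1 - eps]` so that
#' fully (un)methylated probes map to finite values.
#'
#' @param beta numeric vector of methylation proportions in \[0, 1\]
#' @param eps clipping bound (default 1e-6)
#' @return numeric vector of M-values
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values to beta-values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector of finite M-values
#' @return numeric vector of proportions in (0, 1)
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m) & !is.na(m))) stop("M-values must be finite")
  1 / (1 + 2^(-m))
}

#' Remove samples with excessive missingness
#'
#' Emulates sample call-rate filtering: a sample is dropped when its fraction
#' of missing probe values exceeds `max_missing_fraction`.
#'
#' @param ds a `meth_dataset`
#' @param max_missing_fraction threshold in \[0, 1\] (default 0.05)
#' @return list with `dataset` (filtered) and `removed` (data.frame of
#'   `sample_id`, `missing_fraction` for dropped samples)
#' @export
filter_samples <- function(ds, max_missing_fraction = 0.05) {
  stopifnot(inherits(ds, "meth_dataset"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(ds$m))
  drop <- frac > max_missing_fraction
  if (all(drop)) stop("all samples exceed the missingness threshold")
  removed <- data.frame(sample_id = ds$sample_ids[drop],
                        missing_fraction = unname(frac[drop]))
  list(dataset = subset_dataset(ds, samples = ds$sample_ids[!drop]),
       removed = removed)
}

#' Remove probes carrying QC flags
#'
#' A probe is removed when any of its `qc_flags` intersects `flags_to_drop`.
#' A probe carrying several offending flags is removed (and counted in the
#' total) once, but appears in each per-category count.
#'
#' @param ds a `meth_dataset`
#' @param ann probe annotation `data.frame` as returned by
#'   [read_probe_manifest()]; every probe of `ds` must have a row
#' @param flags_to_drop character vector drawn from `low_detection`,
#'   `sex_chromosome`, `snp_overlap`, `cross_reactive`, `manufacturer_flagged`
#' @return list with `dataset`, `removed_probes`, `counts_by_flag`,
#'   `counts_by_chrom`
#' @export
filter_probes <- function(ds, ann,
                          flags_to_drop = c("low_detection", "sex_chromosome",
                                            "snp_overlap", "cross_reactive",
                                            "manufacturer_flagged")) {
  stopifnot(inherits(ds, "meth_dataset"), is.data.frame(ann))
  missing <- setdiff(ds$probe_ids, ann$probe_id)
  if (length(missing)) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  }
  ann <- ann[match(ds$probe_ids, ann$probe_id), ]
  flags <- probe_flag_list(ann)
  hit <- vapply(flags, function(f) length(intersect(f, flags_to_drop)) > 0L, logical(1))
  by_flag <- vapply(flags_to_drop,
                    function(fl) sum(vapply(flags, function(f) fl %in% f, logical(1))),
                    integer(1))
  removed <- ds$probe_ids[hit]
  by_chrom <- if (length(removed)) table(ann$chrom[hit]) else table(character(0))
  list(dataset = subset_dataset(ds, probes = ds$probe_ids[!hit]),
       removed_probes = removed,
       counts_by_flag = by_flag,
       counts_by_chrom = by_chrom)
}

probe_flag_list <- function(ann) {
  qc <- if ("qc_flags" %in% names(ann)) as.character(ann$qc_flags) else
    rep("", nrow(ann))
  qc[is.na(qc)] <- ""
  strsplit(qc, ";", fixed = TRUE)
}

#' Drop probes with any missing value
#'
#' Per-probe least squares needs complete columns; probes with any `NA` across
#' the retained samples are removed before modelling.
#'
#' @param ds a `meth_dataset`
#' @return list with `dataset` and `removed_probes`
#' @export
drop_incomplete_probes <- function(ds) {
  stopifnot(inherits(ds, "meth_dataset"))
  bad <- colSums(is.na(ds$m)) > 0L
  list(dataset = subset_dataset(ds, probes = ds$probe_ids[!bad]),
       removed_probes = ds$probe_ids[bad])
}

#' Read a probe annotation manifest
#'
#' Expects delimited text with columns `probe_id`, `chrom`, `pos`,
#' `island_relation`, `gene`, `in_region`, `epicv2`, `epicv1`, `m450k`,
#' `m27k`, `qc_flags` (semicolon-joined, possibly empty). Coordinates are
#' 1-based inclusive.
#'
#' @param path file path; default is the packaged C9orf72 locus manifest
#'   (23 EPICv2 probes in the gene and its 1-kb flanks)
#' @return a `data.frame`, one row per probe
#' @export
read_probe_manifest <- function(path = system.file("extdata",
                                                   "c9orf72_locus_manifest.tsv",
                                                   package = "c9methpred")) {
  ann <- utils::read.delim(path, sep = infer_sep(path), header = TRUE,
                           check.names = FALSE,
                           colClasses = c(qc_flags = "character"))
  req <- c("probe_id", "chrom", "pos", "island_relation", "gene", "in_region",
           "epicv2", "epicv1", "m450k", "m27k", "qc_flags")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (any(ann$pos <= 0)) stop("probe positions must be positive (1-based)")
  bad <- setdiff(unique(ann$island_relation),
                 c("island", "shore", "shelf", "open_sea"))
  if (length(bad)) stop("invalid island_relation values: ", paste(bad, collapse = ", "))
  flags <- probe_flag_list(ann)
  sexflag <- vapply(flags, function(f) "sex_chromosome" %in% f, logical(1))
  if (any(sexflag & !ann$chrom %in% c("chrX", "chrY")))
    stop("sex_chromosome-flagged probes must lie on chrX or chrY")
  ann
}

#' Read a sample covariate table
#'
#' Delimited text keyed by `sample_id`, with the covariate columns described
#' in [meth_dataset()] and optionally a `carrier` column.
#'
#' @param path file path
#' @return a `data.frame` with row names set to `sample_id`
#' @export
read_covariates <- function(path) {
  cov <- utils::read.delim(path, sep = infer_sep(path), header = TRUE,
                           check.names = FALSE)
  if (!"sample_id" %in% names(cov)) stop("covariate table needs a sample_id column")
  dup <- unique(cov$sample_id[duplicated(cov$sample_id)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  rownames(cov) <- cov$sample_id
  cov
}

#' Attach covariates (and carrier labels) read separately from the matrix
#'
#' @param ds a `meth_dataset`
#' @param cov data.frame from [read_covariates()]; must cover every sample
#' @return a `meth_dataset`
#' @export
attach_covariates <- function(ds, cov) {
  stopifnot(inherits(ds, "meth_dataset"))
  missing <- setdiff(ds$sample_ids, rownames(cov))
  if (length(missing))
    stop("samples missing from covariate table: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  cov <- cov[ds$sample_ids, , drop = FALSE]
  carrier <- if ("carrier" %in% names(cov)) cov$carrier else ds$carrier
  keep <- setdiff(names(cov), c("sample_id", "carrier"))
  meth_dataset(ds$m, covariates = cov[, keep, drop = FALSE], carrier = carrier)
}
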