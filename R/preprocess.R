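#' Imputation parameters for downshifted-normal draws
#'
#' @param shift downshift of the imputation mean, in multiples of the
#'   per-sample SD of observed log2 intensities (default 1.8).
#' @param width SD of the imputation distribution as a fraction of the
#'   per-sample SD (default 0.3).
#' @param seed RNG seed for the imputation draws.
#' @export
impute_params <- function(shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(shift >= 0, width > 0, width <= 1)
  list(shift = shift, width = width, seed = as.integer(seed))
}

#' Remove samples with insufficient proteome depth
#'
#' Drops samples quantifying fewer than `min_count` proteins; proteins are
#' untouched.
#'
#' @param x a [protein_matrix].
#' @param min_count minimal number of quantified proteins per retained
#'   sample (default 200).
#' @export
filter_min_proteins <- function(x, min_count = 200L) {
  stopifnot(inherits(x, "protein_matrix"))
  n_quant <- colSums(!is.na(x$values))
  keep <- n_quant >= min_count
  if (!any(keep)) stop("all samples removed by the proteome-depth filter")
  protein_matrix(x$values[, keep, drop = FALSE], scale = x$scale)
}

#' Remove proteins with too many missing values
#'
#' Keeps proteins quantified in at least `min_frac` of all retained samples
#' (the valid-value filter); the boundary fraction is kept.
#'
#' @param x a [protein_matrix].
#' @param min_frac minimal present fraction across samples (default 0.6).
#' @export
filter_valid_values <- function(x, min_frac = 0.6) {
  stopifnot(inherits(x, "protein_matrix"))
  frac <- rowMeans(!is.na(x$values))
  keep <- frac >= min_frac
  if (!any(keep)) stop("all proteins removed by the valid-value filter")
  protein_matrix(x$values[keep, , drop = FALSE], scale = x$scale)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample, the mean `m` and SD `d` of the observed log2 intensities are
#' computed; each missing cell is replaced by an independent draw from
#' `Normal(m - shift * d, (width * d)^2)`. This places imputed values in the
#' low-abundance tail, the standard model for abundance-dependent (MNAR)
#' dropout in DIA proteomics. Observed cells are untouched and the result is
#' complete. Moments always come from the observed values only.
#'
#' @param x a log2-scale [protein_matrix].
#' @param params an [impute_params()].
#' @return complete [protein_matrix], deterministic given `params$seed`.
#' @export
impute_downshifted <- function(x, params = impute_params()) {
  stopifnot(inherits(x, "protein_matrix"))
  if (x$scale != "log2") stop("imputation operates on log2-scale matrices")
  v <- x$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 2L))
    stop("sample(s) with fewer than 2 observed values (SD undefined): ",
         paste(colnames(v)[n_obs < 2L], collapse = ", "))
  if (!anyNA(v)) return(x)
  set.seed(params$seed)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    m <- mean(v[!miss, j])
    d <- stats::sd(v[!miss, j])
    v[miss, j] <- stats::rnorm(sum(miss), m - params$shift * d,
                               params$width * d)
  }
  protein_matrix(v, scale = "log2")
}

#' Filter proteins on QC-replicate coefficient of variation
#'
#' The CV per protein is SD/mean of the linear-scale intensities across the
#' QC replicate columns (missing QC cells ignored). Proteins exceeding
#' `max_cv`, or with fewer than 2 observed QC values, are removed; the QC
#' columns themselves are dropped from the returned matrix.
#'
#' @param x a [protein_matrix] containing the QC columns (any scale).
#' @param qc_sample_ids the QC replicate column names.
#' @param max_cv maximal tolerated CV (default 0.30).
#' @return the filtered matrix without the QC columns; attribute
#'   `qc_excluded` lists proteins removed for having <2 observed QC values.
#' @export
qc_cv_filter <- function(x, qc_sample_ids, max_cv = 0.30) {
  stopifnot(inherits(x, "protein_matrix"))
  if (!all(qc_sample_ids %in% sample_ids(x)))
    stop("QC sample id(s) not in matrix: ",
         paste(setdiff(qc_sample_ids, sample_ids(x)), collapse = ", "))
  if (length(qc_sample_ids) < 2L) stop("need at least 2 QC columns")
  qc <- x$values[, qc_sample_ids, drop = FALSE]
  if (x$scale == "log2") qc <- 2^qc  # CV is defined on linear intensities
  n_obs <- rowSums(!is.na(qc))
  cv <- apply(qc, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(NA_real_)
    stats::sd(r) / mean(r)
  })
  unmeasurable <- n_obs < 2L
  keep <- !unmeasurable & cv <= max_cv
  if (!any(keep)) stop("all proteins removed by the QC CV filter")
  rest <- setdiff(sample_ids(x), qc_sample_ids)
  out <- protein_matrix(x$values[keep, rest, drop = FALSE], scale = x$scale)
  attr(out, "qc_excluded") <- protein_ids(x)[unmeasurable]
  attr(out, "qc_cv") <- cv
  out
}

#' Full preprocessing pipeline
#'
#' Fixed order: proteome-depth filter, valid-value filter, log2 transform,
#' QC CV filter (when QC replicates are supplied), downshifted-normal
#' imputation. Returns a complete log2 matrix ready for the differential
#' and machine-learning stages.
#'
#' @param x linear-scale [protein_matrix] of cohort samples.
#' @param qc optional linear-scale [protein_matrix] of QC replicates on the
#'   same protein set.
#' @param min_proteins,min_valid_frac,max_qc_cv filter thresholds.
#' @param impute an [impute_params()].
#' @param verbose log in/out counts per step.
#' @return imputed log2 [protein_matrix]; attribute `log` records per-step
#'   dimensions.
#' @export
preprocess_pipeline <- function(x, qc = NULL, min_proteins = 200L,
                                min_valid_frac = 0.6, max_qc_cv = 0.30,
                                impute = impute_params(), verbose = FALSE) {
  steps <- list(c(input = paste(dim(x), collapse = "x")))
  x <- filter_min_proteins(x, min_proteins)
  x <- filter_valid_values(x, min_valid_frac)
  x <- log2_transform(x)
  if (!is.null(qc)) {
    common <- intersect(protein_ids(x), protein_ids(qc))
    merged <- protein_matrix(
      cbind(x$values[common, , drop = FALSE],
            log2(qc$values[common, sample_ids(qc), drop = FALSE])),
      scale = "log2")
    x <- qc_cv_filter(merged, sample_ids(qc), max_qc_cv)
  }
  out <- impute_downshifted(x, impute)
  attr(out, "log") <- sprintf("retained %d proteins x %d samples",
                              nrow(out$values), ncol(out$values))
  if (verbose) message(attr(out, "log"))
  out
}
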