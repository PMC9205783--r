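#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and map back to input
#' order. `NA` entries are passed through and excluded from `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  qs <- rev(cummin(rev(ps * m / seq_len(m))))
  qs <- pmin(qs, 1)
  qi <- numeric(m)
  qi[ord] <- qs
  q[ok] <- qi
  q
}

# factor name -> metadata score column
.factor_field <- c(fibrosis = "kleiner_f", inflammation = "activity_i",
                   steatosis = "steatosis_s")

# default covariate sets: common clinical covariates plus the "vice versa"
# histology adjustment (steatosis when testing fibrosis/inflammation,
# fibrosis when testing steatosis)
#' Default ANCOVA covariate set for a histology factor
#' @param factor `"fibrosis"`, `"inflammation"` or `"steatosis"`.
#' @export
default_covariates <- function(factor) {
  extra <- switch(factor, fibrosis = "steatosis_s",
                  inflammation = "steatosis_s", steatosis = "kleiner_f",
                  stop("unknown factor: ", factor))
  c("age", "bmi", "sex", "abstinent", extra)
}

# build the model frame: samples with factor score + all covariates present
.diff_frame <- function(matrix, meta, factor, covariates) {
  field <- .factor_field[[factor]]
  if (is.null(field)) stop("unknown factor: ", factor)
  keep_s <- intersect(sample_ids(matrix), meta$sample_id)
  meta <- meta[match(keep_s, meta$sample_id), , drop = FALSE]
  have <- !is.na(meta[[field]])
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv)
    have <- have & !is.na(meta[[cv]])
  }
  list(samples = keep_s[have], meta = meta[have, , drop = FALSE], field = field)
}

# covariates as numeric design columns (sex/abstinent as 0/1 indicators)
.covariate_design <- function(meta, covariates) {
  cols <- lapply(covariates, function(cv) {
    v <- meta[[cv]]
    if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1
    else if (is.logical(v)) as.numeric(v)
    else as.numeric(v)
  })
  if (!length(cols)) return(matrix(numeric(0), nrow(meta), 0))
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Covariate-adjusted differential abundance (ANCOVA)
#'
#' Per protein, ordinary least squares of log2 intensity on the histology
#' factor encoded categorically (one indicator per stage above baseline)
#' plus covariates; the partial F-test compares this full model against the
#' covariates-only reduced model. Stage levels with fewer than 2 samples are
#' merged into the adjacent lower level (with a warning). Benjamini-Hochberg
#' q-values are computed over all proteins tested; a protein is flagged
#' significant at q < 0.05.
#'
#' @param matrix imputed log2 [protein_matrix].
#' @param meta sample metadata.
#' @param factor `"fibrosis"`, `"inflammation"` or `"steatosis"`.
#' @param covariates covariate names (default [default_covariates()]).
#' @return data frame: protein_id, factor, f_stat, p, q, direction
#'   (sign of top-vs-bottom stage median difference), significant, and one
#'   `median_<stage>` column per stage level.
#' @export
ancova_stagewise <- function(matrix, meta, factor,
                             covariates = default_covariates(factor)) {
  fr <- .diff_frame(matrix, meta, factor, covariates)
  if (length(fr$samples) < length(covariates) + 4L)
    stop("too few complete samples for ANCOVA")
  score <- fr$meta[[fr$field]]
  # merge sparse stage levels downward so every level has >= 2 samples
  lev <- sort(unique(score))
  counts <- table(factor(score, levels = lev))
  while (any(counts < 2L) && length(lev) > 1L) {
    i <- which(counts < 2L)[1L]
    tgt <- if (i > 1L) lev[i - 1L] else lev[2L]
    warning(sprintf("stage level %s has <2 samples; merged into %s",
                    lev[i], tgt))
    score[score == lev[i]] <- tgt
    lev <- sort(unique(score))
    counts <- table(factor(score, levels = lev))
  }
  stage_f <- factor(score, levels = lev)
  covs <- .covariate_design(fr$meta, covariates)
  X_red <- cbind(`(Intercept)` = 1, covs)
  X_full <- cbind(X_red, stats::model.matrix(~stage_f)[, -1L, drop = FALSE])
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    drop_cols <- colnames(X_full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("rank-deficient ANCOVA design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  qr_red <- qr(X_red)
  Y <- t(matrix$values[, fr$samples, drop = FALSE])  # samples x proteins
  if (anyNA(Y)) stop("ANCOVA requires an imputed (complete) matrix")
  rss_f <- colSums(qr.resid(qr_full, Y)^2)
  rss_r <- colSums(qr.resid(qr_red, Y)^2)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- nrow(Y) - ncol(X_full)
  f_stat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  q <- bh_adjust(p)
  med <- vapply(lev, function(s)
    apply(Y[score == s, , drop = FALSE], 2L, stats::median),
    numeric(ncol(Y)))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1L)
  colnames(med) <- paste0("median_", lev)
  direction <- sign(med[, ncol(med)] - med[, 1L])
  out <- data.frame(protein_id = protein_ids(matrix), factor = factor,
                    f_stat = f_stat, p = p, q = q, direction = direction,
                    significant = q < 0.05, stringsAsFactors = FALSE,
                    row.names = NULL)
  cbind(out, med)
}

#' Spearman partial correlation of proteins against a histology score
#'
#' Intensities, the score and numeric covariates are rank-transformed
#' (average ranks for ties); both ranked intensity and ranked score are
#' regressed on the ranked covariate block (with intercept) and `r` is the
#' Pearson correlation of the residuals. The p-value uses the t distribution
#' with `n - 2 - k` degrees of freedom. A protein is flagged significant iff
#' q < 0.05 and `|r| >= 0.3`.
#'
#' @param matrix log2 [protein_matrix]; missing cells are dropped per
#'   protein (pairwise complete).
#' @param meta sample metadata.
#' @param factor histology factor (or give `score_name` a metadata column).
#' @param covariates covariate names; empty for a plain Spearman correlation.
#' @param score_name metadata column to correlate against; defaults to the
#'   factor's score field.
#' @return data frame: protein_id, target, r, p, q, n_used, significant.
#' @export
spearman_partial_scores <- function(matrix, meta, factor = "fibrosis",
                                    covariates = default_covariates(factor),
                                    score_name = NULL) {
  if (is.null(score_name)) score_name <- .factor_field[[factor]]
  keep_s <- intersect(sample_ids(matrix), meta$sample_id)
  meta <- meta[match(keep_s, meta$sample_id), , drop = FALSE]
  have <- !is.na(meta[[score_name]])
  for (cv in covariates) have <- have & !is.na(meta[[cv]])
  samples <- keep_s[have]
  meta <- meta[have, , drop = FALSE]
  k <- length(covariates)
  V <- matrix$values[, samples, drop = FALSE]
  score <- meta[[score_name]]
  covs <- .covariate_design(meta, covariates)
  n_prot <- nrow(V)
  r <- p <- rep(NA_real_, n_prot)
  n_used <- integer(n_prot)
  complete_cov <- cbind(1, apply(covs, 2L, rank))
  if (k == 0L) complete_cov <- matrix(1, length(samples), 1L)
  for (i in seq_len(n_prot)) {
    obs <- !is.na(V[i, ])
    n <- sum(obs)
    n_used[i] <- n
    if (n < k + 3L) {
      warning("protein ", protein_ids(matrix)[i],
              " skipped: only ", n, " usable samples")
      next
    }
    if (all(obs)) {
      Z <- complete_cov
      y1 <- rank(V[i, ]); y2 <- rank(score)
    } else {
      Z <- cbind(1, apply(covs[obs, , drop = FALSE], 2L, rank))
      if (k == 0L) Z <- matrix(1, n, 1L)
      y1 <- rank(V[i, obs]); y2 <- rank(score[obs])
    }
    qz <- qr(Z)
    e1 <- qr.resid(qz, y1); e2 <- qr.resid(qz, y2)
    if (stats::sd(e1) == 0 || stats::sd(e2) == 0) next
    ri <- stats::cor(e1, e2)
    df <- n - 2L - k
    tt <- ri * sqrt(df / max(1 - ri^2, .Machine$double.eps))
    r[i] <- ri
    p[i] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  q <- bh_adjust(p)
  data.frame(protein_id = protein_ids(matrix), target = score_name,
             r = r, p = p, q = q, n_used = n_used,
             significant = !is.na(q) & q < 0.05 & abs(r) >= 0.3,
             stringsAsFactors = FALSE, row.names = NULL)
}
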