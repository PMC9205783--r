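#' Clinical comparator specification
#'
#' A comparator test is evaluated at a fixed, clinically recommended cutoff;
#' `direction` says which side of the cutoff is called a case (a value equal
#' to the cutoff is always a case).
#'
#' @param name test name (e.g. `TE`, `ELF`, `FIB4`, `APRI`, `CAP`).
#' @param cutoff decision threshold on the test's own scale.
#' @param direction `"higher_is_case"` or `"lower_is_case"`.
#' @export
comparator_spec <- function(name, cutoff,
                            direction = c("higher_is_case", "lower_is_case")) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  list(name = name, cutoff = cutoff, direction = direction)
}

#' Evaluate a comparator test at its clinical cutoff
#'
#' Computes the binary call per sample and the standard classification
#' metrics on the subset with an available test value.
#'
#' @param values test values (missing allowed).
#' @param spec a [comparator_spec()].
#' @param y true labels aligned with `values`.
#' @return named vector of metrics plus `n_used`.
#' @export
comparator_metrics <- function(values, spec, y) {
  ok <- !is.na(values) & !is.na(.as01(y))
  if (!any(ok)) stop("comparator ", spec$name, " has no available values")
  v <- values[ok]
  calls <- if (spec$direction == "higher_is_case") v >= spec$cutoff
           else v <= spec$cutoff
  score <- if (spec$direction == "higher_is_case") v else -v
  m <- classification_metrics(.as01(y)[ok], as.integer(calls), score)
  c(m, n_used = sum(ok))
}

#' Binary comparator calls at the clinical cutoff
#'
#' @inheritParams comparator_metrics
#' @return integer vector of 0/1 calls (NA where the value is missing).
#' @export
comparator_calls <- function(values, spec) {
  calls <- if (spec$direction == "higher_is_case") values >= spec$cutoff
           else values <= spec$cutoff
  as.integer(calls)
}

#' DeLong's test for two correlated ROC curves
#'
#' AUCs via the Mann-Whitney statistic with tie half-credit; the variance
#' and covariance of the paired AUCs come from DeLong's placement-value
#' (structural-components) estimator with midranks, so tied predictions are
#' handled. Identical predictors give z = 0, p = 1 rather than an error.
#'
#' @param p1,p2 predicted scores from the two models on the same samples.
#' @param y binary truth.
#' @return list: auc1, auc2, z, p (two-sided), se_diff.
#' @export
delong_test <- function(p1, p2, y) {
  y <- .as01(y)
  if (length(p1) != length(y) || length(p2) != length(y))
    stop("p1, p2 and y must be aligned")
  ok <- !is.na(p1) & !is.na(p2) & !is.na(y)
  p1 <- p1[ok]; p2 <- p2[ok]; y <- y[ok]
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  placements <- function(p) {
    x <- p[y == 1]; yy <- p[y == 0]
    r_all <- rank(c(x, yy))
    v10 <- (r_all[seq_len(m)] - rank(x)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(yy)) / m
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- placements(p1); b <- placements(p2)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0 || !is.finite(var_diff)) {
    z <- 0; pval <- 1; se <- 0
  } else {
    se <- sqrt(var_diff)
    z <- (a$auc - b$auc) / se
    pval <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  list(auc1 = a$auc, auc2 = b$auc, z = z, p = pval, se_diff = se)
}

#' DeLong variance of a single AUC
#'
#' @param p predicted scores; @param y binary truth.
#' @export
delong_auc_variance <- function(p, y) {
  y <- .as01(y)
  m <- sum(y == 1); n <- sum(y == 0)
  x <- p[y == 1]; yy <- p[y == 0]
  r_all <- rank(c(x, yy))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(yy)) / m
  stats::var(v10) / m + stats::var(v01) / n
}

#' Categorical net reclassification improvement
#'
#' Class-based NRI of a new binary rule against a baseline rule:
#' `NRI_e = P(up|event) - P(down|event)`,
#' `NRI_ne = P(down|nonevent) - P(up|nonevent)`, `NRI = NRI_e + NRI_ne`,
#' where `up` means baseline-negative reclassified new-positive and `down`
#' the reverse. With no events (or no nonevents) the corresponding component
#' and the total are reported missing.
#'
#' @param new_calls,base_calls binary calls (0/1) of the new and baseline
#'   rules.
#' @param y event indicator.
#' @return list: counts per group, nri_event, nri_nonevent, nri_total.
#' @export
nri <- function(new_calls, base_calls, y) {
  y <- .as01(y); new_calls <- .as01(new_calls); base_calls <- .as01(base_calls)
  ok <- !is.na(y) & !is.na(new_calls) & !is.na(base_calls)
  y <- y[ok]; new_calls <- new_calls[ok]; base_calls <- base_calls[ok]
  up <- base_calls == 0 & new_calls == 1
  down <- base_calls == 1 & new_calls == 0
  comp <- function(sel) {
    n <- sum(sel)
    if (n == 0) return(c(up = 0L, down = 0L, total = 0L, nri = NA_real_))
    c(up = sum(up & sel), down = sum(down & sel), total = n,
      nri = (sum(up & sel) - sum(down & sel)) / n)
  }
  ev <- comp(y == 1); ne <- comp(y == 0)
  nri_e <- unname(ev["nri"])
  nri_ne <- -unname(ne["nri"])  # nonevents benefit from down-classification
  list(events = ev[c("up", "down", "total")],
       nonevents = ne[c("up", "down", "total")],
       nri_event = nri_e, nri_nonevent = nri_ne,
       nri_total = if (is.na(nri_e) || is.na(nri_ne)) NA_real_
                   else nri_e + nri_ne)
}

#' Rule-out accuracy in a presumed disease-free population
#'
#' Fraction of samples a frozen panel model classifies negative (probability
#' below the cutoff), with an exact binomial 95% confidence interval.
#'
#' @param model a `panel_model`.
#' @param X_population samples x proteins matrix of the population.
#' @return list: fraction, n, ci (length-2).
#' @export
rule_out_accuracy <- function(model, X_population) {
  if (!nrow(X_population)) stop("empty population")
  p <- predict(model, X_population)
  neg <- sum(p < model$cutoff)
  ci <- stats::binom.test(neg, length(p))$conf.int
  list(fraction = neg / length(p), n = length(p), ci = as.numeric(ci))
}
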