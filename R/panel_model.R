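#' Missingness-pattern strata
#'
#' Each labeled sample is keyed by the tuple of present/absent flags over the
#' considered clinical variables; cross-validation splits are stratified on
#' this key (jointly with the class label) so that every fold carries the
#' same mixture of data-availability patterns. Patterns with fewer members
#' than the fold count are pooled into a `rare` stratum.
#'
#' @param meta sample metadata.
#' @param considered_vars metadata columns (comparator tests etc.) whose
#'   availability defines the pattern; empty means a single stratum.
#' @param folds fold count used for the rare-pattern pooling rule.
#' @return named character vector: sample_id -> pattern key.
#' @export
missingness_strata <- function(meta, considered_vars, folds = 5L) {
  if (!length(considered_vars)) {
    warning("no considered variables; all samples form one stratum")
    return(stats::setNames(rep("all", nrow(meta)), meta$sample_id))
  }
  missing_cols <- setdiff(considered_vars, names(meta))
  if (length(missing_cols))
    stop("considered variable(s) not in metadata: ",
         paste(missing_cols, collapse = ", "))
  flags <- sapply(considered_vars, function(v) as.integer(!is.na(meta[[v]])))
  key <- apply(flags, 1L, paste, collapse = "")
  tab <- table(key)
  key[key %in% names(tab)[tab < folds]] <- "rare"
  stats::setNames(key, meta$sample_id)
}

#' Repeated stratified k-fold cross-validation splits
#'
#' Within each repeat, samples are partitioned into `folds` test folds
#' stratified jointly on (class label x missingness stratum): members of
#' each cell are shuffled and dealt round-robin, with the fold cursor
#' carried across cells of the same class so per-fold class counts differ by
#' at most one. Each sample appears in exactly one test fold per repeat.
#'
#' @param labels factor/character class labels (no NA).
#' @param strata stratum key per sample (same order as `labels`); NULL for a
#'   single stratum.
#' @param folds,repeats fold and repeat counts (defaults 5 x 10 = 50 splits).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list of `folds * repeats` elements, each
#'   `list(train, test, repeat_idx, fold)` of integer indices.
#' @export
repeated_cv_splits <- function(labels, strata = NULL, folds = 5L,
                               repeats = 10L, seed = 1L) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must be complete; drop unlabeled samples first")
  if (is.null(strata)) strata <- rep("all", length(labels))
  cls_tab <- table(labels)
  if (any(cls_tab < folds))
    stop("class '", names(cls_tab)[which.min(cls_tab)],
         "' has fewer members than folds")
  set.seed(seed)
  splits <- vector("list", folds * repeats)
  idx <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(labels))
    for (cl in names(cls_tab)) {
      cursor <- sample.int(folds, 1L) - 1L
      for (st in unique(strata[labels == cl])) {
        cell <- which(labels == cl & strata == st)
        cell <- cell[sample.int(length(cell))]
        fold_of[cell] <- (cursor + seq_along(cell) - 1L) %% folds + 1L
        cursor <- (cursor + length(cell)) %% folds
      }
    }
    for (f in seq_len(folds)) {
      idx <- idx + 1L
      test <- which(fold_of == f)
      splits[[idx]] <- list(train = which(fold_of != f), test = test,
                            repeat_idx = r, fold = f)
    }
  }
  splits
}

#' Minimum redundancy - maximum relevance feature ranking
#'
#' Greedy forward selection: relevance of a feature is its one-way ANOVA F
#' statistic against the binary label; the first pick maximizes relevance,
#' and each subsequent pick maximizes
#' `F(f) / max(mean |Pearson r(f, s)| over selected s, eps)` with
#' `eps = 0.001`. Constant features have zero relevance. Ties break by
#' feature-id lexicographic order.
#'
#' @param X numeric matrix, samples x features, complete, with column names.
#' @param y binary labels (factor/logical/0-1), both classes present.
#' @param k_max number of features to rank (default 50).
#' @return character vector of feature ids in selection order.
#' @export
mrmr_rank <- function(X, y, k_max = 50L) {
  if (anyNA(X)) stop("mRMR requires a complete feature matrix")
  y <- .as01(y)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  feats <- colnames(X)
  if (is.null(feats)) stop("X needs column names")
  n <- nrow(X)
  n1 <- sum(y == 1); n0 <- n - n1
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  mg <- colMeans(X)
  ssb <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ssw <- colSums((X - matrix(ifelse(y == 1, 1, 0)) %*% t(m1)
                  - matrix(ifelse(y == 0, 1, 0)) %*% t(m0))^2)
  relevance <- ifelse(ssw <= 0, 0, (ssb / 1) / (ssw / (n - 2)))
  names(relevance) <- feats
  k_max <- min(k_max, ncol(X))
  ord0 <- order(-relevance, feats)
  selected <- feats[ord0[1L]]
  remaining <- setdiff(feats, selected)
  red_sum <- rep(0, length(feats))  # running sum of |r| vs selected
  names(red_sum) <- feats
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sds <- sqrt(colSums(Xc^2))
  while (length(selected) < k_max) {
    s_last <- selected[length(selected)]
    cr <- as.vector(crossprod(Xc[, s_last], Xc)) / (sds[s_last] * sds)
    cr[!is.finite(cr)] <- 0
    red_sum <- red_sum + abs(cr)
    mean_red <- pmax(red_sum[remaining] / length(selected), 0.001)
    score <- relevance[remaining] / mean_red
    pick <- remaining[order(-score, remaining)[1L]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

.as01 <- function(y) {
  if (is.factor(y)) {
    if (all(levels(y) %in% c("control", "case"))) as.integer(y == "case")
    else as.integer(y) - 1L
  } else if (is.logical(y)) as.integer(y)
  else if (is.character(y)) as.integer(y == "case")
  else as.integer(y)
}

#' Fit an L2-penalized logistic biomarker panel model
#'
#' Binary logistic regression maximizing the L2-penalized log-likelihood
#' (penalty `1/(2 * l2_strength) * ||beta||^2`, intercept unpenalized) by
#' Newton iterations, converged when the gradient norm drops below 1e-6.
#' Features are standardized internally on the training data and the scaler
#' is stored with the model, so prediction applies the same transform.
#'
#' @param X numeric matrix, samples x panel features, complete, with column
#'   names.
#' @param y binary labels (`case`/`control` factor, logical or 0/1).
#' @param l2_strength inverse regularization strength C (default 1.0);
#'   larger means weaker penalty.
#' @param cutoff classification probability cutoff (default 0.5; a
#'   probability equal to the cutoff is called a case).
#' @param endpoint optional endpoint name stored with the model.
#' @param fingerprint optional training provenance string (seed/split id).
#' @return object of class `panel_model`.
#' @export
fit_logistic <- function(X, y, l2_strength = 1.0, cutoff = 0.5,
                         endpoint = NA_character_, fingerprint = NA_character_) {
  if (anyNA(X)) stop("logistic fit requires a complete feature matrix")
  if (is.null(colnames(X))) stop("X needs column names")
  stopifnot(cutoff > 0, cutoff < 1)
  y01 <- .as01(y)
  if (length(unique(y01)) != 2L) stop("both classes must be present to fit")
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd) * sqrt((nrow(X) - 1) / nrow(X))  # population SD
  scl[scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2L, center), 2L, scl, "/"))
  p_dim <- ncol(Z)
  lambda <- 1 / l2_strength
  pen <- c(0, rep(lambda, p_dim - 1L))  # intercept unpenalized
  beta <- numeric(p_dim)
  converged <- FALSE
  for (it in seq_len(10000L)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Z, mu - y01)) + pen * beta
    if (sqrt(sum(grad^2)) < 1e-6) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * w, Z) + diag(pen, p_dim)
    step <- solve(H, grad)
    # damped Newton: halve until the penalized deviance does not increase
    obj <- function(b) {
      e <- drop(Z %*% b)
      sum(log1p(exp(e)) - y01 * e) + sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    t_step <- 1
    while (obj(beta - t_step * step) > f0 + 1e-12 && t_step > 1e-8)
      t_step <- t_step / 2
    beta <- beta - t_step * step
  }
  if (!converged)
    stop(sprintf("logistic fit failed to converge (gradient norm %.3g after 10000 iterations)",
                 sqrt(sum(grad^2))))
  structure(list(endpoint = endpoint, panel = colnames(X),
                 intercept = beta[1L],
                 coefficients = stats::setNames(beta[-1L], colnames(X)),
                 center = center, scale = scl, cutoff = cutoff,
                 l2_strength = l2_strength, n_train = nrow(X),
                 iterations = it, fingerprint = fingerprint),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d-protein panel%s (L2 C=%g, cutoff %.2f, n=%d)\n",
              length(x$panel),
              if (!is.na(x$endpoint)) paste0(" for ", x$endpoint) else "",
              x$l2_strength, x$cutoff, x$n_train))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.panel_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.panel_model <- function(object, ...) {
  cf <- sort(abs(object$coefficients), decreasing = TRUE)
  cat(sprintf("L2-penalized logistic panel model (%d proteins, trained on %d samples)\n",
              length(object$panel), object$n_train))
  if (!is.na(object$endpoint)) cat("endpoint:", object$endpoint, "\n")
  cat("standardized coefficients (|beta| order):\n")
  print(round(object$coefficients[names(cf)], 4))
  cat(sprintf("intercept %.4f, cutoff %.2f\n", object$intercept, object$cutoff))
  invisible(object)
}

#' Predict panel-model risk probabilities
#'
#' @param object a `panel_model`.
#' @param newdata samples x proteins matrix covering every panel protein.
#' @param type `"response"` (probability), `"link"` (log-odds) or
#'   `"class"` (`case`/`control` at the model cutoff; probability equal to
#'   the cutoff is a case).
#' @param ... unused.
#' @export
predict.panel_model <- function(object, newdata,
                                type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  missing_p <- setdiff(object$panel, colnames(newdata))
  if (length(missing_p))
    stop("panel protein(s) absent from newdata: ",
         paste(missing_p, collapse = ", "))
  X <- newdata[, object$panel, drop = FALSE]
  if (anyNA(X)) stop("newdata contains missing values for panel proteins")
  Z <- sweep(sweep(X, 2L, object$center[object$panel]), 2L,
             object$scale[object$panel], "/")
  eta <- drop(Z %*% object$coefficients) + object$intercept
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = factor(ifelse(stats::plogis(eta) >= object$cutoff,
                               "case", "control"),
                        levels = c("control", "case")))
}

#' @rdname predict.panel_model
#' @param model a `panel_model`.
#' @param X samples x proteins matrix.
#' @export
classify <- function(model, X) predict(model, X, type = "class")

#' Binary classification metrics
#'
#' Precision, recall, F1, balanced accuracy (mean of sensitivity and
#' specificity) and ROC-AUC via the Mann-Whitney relation with half credit
#' for probability ties. With a single-class truth vector the AUC is
#' reported missing and the other metrics are computed where defined.
#'
#' @param y true labels.
#' @param y_hat predicted labels (defaults to `p >= 0.5`).
#' @param p predicted case probabilities (needed for `roc_auc`).
#' @return named numeric vector.
#' @export
classification_metrics <- function(y, y_hat = NULL, p = NULL) {
  y <- .as01(y)
  if (is.null(y_hat)) {
    if (is.null(p)) stop("provide y_hat or p")
    y_hat <- as.integer(p >= 0.5)
  } else y_hat <- .as01(y_hat)
  tp <- sum(y == 1 & y_hat == 1); fp <- sum(y == 0 & y_hat == 1)
  fn <- sum(y == 1 & y_hat == 0); tn <- sum(y == 0 & y_hat == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (precision + recall > 0 && !is.na(recall))
    2 * precision * recall / (precision + recall) else 0
  sens <- recall
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- mean(c(sens, spec))
  auc <- if (!is.null(p) && length(unique(y)) == 2L) roc_auc(p, y) else NA_real_
  c(precision = precision, recall = recall, f1 = f1,
    balanced_accuracy = bal, roc_auc = auc)
}

#' ROC-AUC by the Mann-Whitney relation
#'
#' Probability that a random case outranks a random control, with half
#' credit for score ties.
#'
#' @param p scores or probabilities.
#' @param y binary truth.
#' @export
roc_auc <- function(p, y) {
  y <- .as01(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)  # average ranks give tie half-credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated performance across panel sizes
#'
#' For every split of a missingness-stratified repeated CV and every panel
#' size k, fits the logistic model on the training fold using the top-k
#' features of that fold's own mRMR ranking (no leakage into the test fold)
#' and evaluates on the test fold. `legacy_global_ranking = TRUE` instead
#' ranks once on the full data before splitting — the leakage-prone protocol
#' kept for comparability, off by default.
#'
#' @param X samples x proteins matrix (complete, column names).
#' @param y binary labels.
#' @param strata stratum key per sample (see [missingness_strata()]).
#' @param k_max largest panel size (truncated to the feature count).
#' @param folds,repeats CV geometry.
#' @param seed RNG seed.
#' @param l2_strength logistic penalty (see [fit_logistic()]).
#' @param legacy_global_ranking rank features once on all data.
#' @return list with `records` (one row per split x k: repeat_idx, fold, k,
#'   metrics) and `by_k` (per-k mean/SD of F1 and ROC-AUC).
#' @export
evaluate_panel_sizes <- function(X, y, strata = NULL, k_max = 50L, folds = 5L,
                                 repeats = 10L, seed = 1L, l2_strength = 1.0,
                                 legacy_global_ranking = FALSE) {
  if (k_max > ncol(X)) {
    warning("k_max exceeds available features; truncated to ", ncol(X))
    k_max <- ncol(X)
  }
  splits <- repeated_cv_splits(y, strata, folds, repeats, seed)
  global_rank <- if (legacy_global_ranking) mrmr_rank(X, y, k_max) else NULL
  rec <- list()
  for (sp in splits) {
    ranking <- if (legacy_global_ranking) global_rank
               else mrmr_rank(X[sp$train, , drop = FALSE],
                              .as01(y)[sp$train], k_max)
    for (k in seq_len(k_max)) {
      feats <- ranking[seq_len(k)]
      fit <- fit_logistic(X[sp$train, feats, drop = FALSE],
                          .as01(y)[sp$train], l2_strength)
      p <- predict(fit, X[sp$test, , drop = FALSE])
      m <- classification_metrics(.as01(y)[sp$test],
                                  as.integer(p >= fit$cutoff), p)
      rec[[length(rec) + 1L]] <- c(repeat_idx = sp$repeat_idx,
                                   fold = sp$fold, k = k, m)
    }
  }
  records <- as.data.frame(do.call(rbind, rec))
  by_k <- do.call(rbind, lapply(split(records, records$k), function(d)
    data.frame(k = d$k[1L], mean_f1 = mean(d$f1), sd_f1 = stats::sd(d$f1),
               mean_auc = mean(d$roc_auc, na.rm = TRUE),
               sd_auc = stats::sd(d$roc_auc, na.rm = TRUE))))
  list(records = records, by_k = by_k[order(by_k$k), ])
}

#' Panel-size rule: maximal F1 with the minimal panel
#'
#' @param curve per-k mean F1 (vector indexed by k, or the `by_k` table of
#'   [evaluate_panel_sizes()]).
#' @return the smallest k attaining the maximal mean F1.
#' @export
select_panel_size <- function(curve) {
  if (is.data.frame(curve)) {
    f1 <- curve$mean_f1[order(curve$k)]
  } else f1 <- as.numeric(curve)
  if (!length(f1)) stop("empty panel-size curve")
  which.max(f1)  # which.max returns the first (smallest k) maximum
}

#' Aggregate a cross-validation record table
#'
#' @param records per-split metric rows (from [evaluate_panel_sizes()] or
#'   [cv_panel()]).
#' @return data frame with mean, SD and normal-approximation 95% CI per
#'   metric.
#' @export
cv_report <- function(records) {
  metrics <- intersect(c("precision", "recall", "f1", "balanced_accuracy",
                         "roc_auc"), names(records))
  out <- lapply(metrics, function(mm) {
    v <- records[[mm]]
    v <- v[!is.na(v)]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(metric = mm, mean = mean(v), sd = stats::sd(v),
               ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
               n_splits = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-validate a fixed-size panel
#'
#' Repeated stratified CV at one panel size k: within each training fold,
#' mRMR picks the top-k features and the logistic model is fitted and then
#' scored on the held-out fold.
#'
#' @inheritParams evaluate_panel_sizes
#' @param k panel size.
#' @return list with `records` and the aggregate [cv_report()].
#' @export
cv_panel <- function(X, y, k, strata = NULL, folds = 5L, repeats = 10L,
                     seed = 1L, l2_strength = 1.0) {
  splits <- repeated_cv_splits(y, strata, folds, repeats, seed)
  rec <- lapply(splits, function(sp) {
    ranking <- mrmr_rank(X[sp$train, , drop = FALSE], .as01(y)[sp$train], k)
    fit <- fit_logistic(X[sp$train, ranking, drop = FALSE], .as01(y)[sp$train],
                        l2_strength)
    p <- predict(fit, X[sp$test, , drop = FALSE])
    c(repeat_idx = sp$repeat_idx, fold = sp$fold, k = k,
      classification_metrics(.as01(y)[sp$test], as.integer(p >= fit$cutoff), p))
  })
  records <- as.data.frame(do.call(rbind, rec))
  list(records = records, report = cv_report(records))
}

#' Final stratified train-test fit
#'
#' One stratified 80/20 split; mRMR ranking and the logistic fit use only
#' the 80% training part, metrics come from the held-out 20%. The returned
#' model is the frozen panel model used for benchmarking, rule-out and
#' prognostic evaluation.
#'
#' @inheritParams evaluate_panel_sizes
#' @param k_star selected panel size.
#' @param endpoint endpoint name stored with the model.
#' @return list: `model` (a `panel_model`), `metrics` (held-out),
#'   `test_idx`, `train_idx`, `test_probabilities`.
#' @export
final_fit <- function(X, y, k_star, strata = NULL, seed = 1L,
                      l2_strength = 1.0, endpoint = NA_character_) {
  sp <- repeated_cv_splits(y, strata, folds = 5L, repeats = 1L,
                           seed = seed)[[1L]]
  ranking <- mrmr_rank(X[sp$train, , drop = FALSE], .as01(y)[sp$train], k_star)
  model <- fit_logistic(X[sp$train, ranking, drop = FALSE], .as01(y)[sp$train],
                        l2_strength, endpoint = endpoint,
                        fingerprint = sprintf("seed=%d;final_split", seed))
  p <- predict(model, X[sp$test, , drop = FALSE])
  metrics <- classification_metrics(.as01(y)[sp$test],
                                    as.integer(p >= model$cutoff), p)
  list(model = model, metrics = metrics, test_idx = sp$test,
       train_idx = sp$train, test_probabilities = p)
}

#' Serialize / restore a panel model as JSON
#'
#' @param model a `panel_model`.
#' @param path JSON file path.
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @rdname write_panel_model
#' @export
read_panel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "center", "scale"))
    obj[[f]] <- stats::setNames(as.numeric(obj[[f]]), obj$panel)
  structure(obj, class = "panel_model")
}
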