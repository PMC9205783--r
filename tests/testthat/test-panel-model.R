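test_that("missingness strata key samples by availability and pool rare patterns", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:12),
                     TE = c(rep(1, 10), NA, NA),
                     CAP = c(rep(1, 5), rep(NA, 5), 1, 1))
  st <- missingness_strata(meta, c("TE", "CAP"), folds = 5)
  expect_equal(unname(st[1]), unname(st[2]))        # identical availability
  expect_equal(length(st), 12)
  expect_equal(unname(st[11]), "rare")              # 2 members < 5 folds
  expect_equal(unname(st[12]), "rare")
  # all-present data collapse to one stratum
  st2 <- missingness_strata(meta[1:5, ], "TE", folds = 2)
  expect_equal(unname(unique(st2)), "1")
  expect_warning(missingness_strata(meta, character(0)), "one stratum")
  expect_error(missingness_strata(meta, "ELF"), "ELF")
})

test_that("repeated CV splits partition each repeat and balance classes within one sample", {
  set.seed(2)
  labels <- factor(sample(c("case", "control"), 83, TRUE, prob = c(0.55, 0.45)),
                   levels = c("control", "case"))
  strata <- sample(c("a", "b", "c"), 83, TRUE)
  splits <- repeated_cv_splits(labels, strata, folds = 5, repeats = 10, seed = 4)
  expect_length(splits, 50)
  for (r in 1:10) {
    reps <- Filter(function(s) s$repeat_idx == r, splits)
    tests <- lapply(reps, `[[`, "test")
    expect_setequal(unlist(tests), seq_along(labels))     # union = all
    expect_equal(sum(lengths(tests)), length(labels))      # disjoint
    for (s in reps)
      expect_setequal(c(s$train, s$test), seq_along(labels))
  }
  # per-fold class counts within +-1 of equal share
  for (cl in c("case", "control")) {
    per_fold <- sapply(Filter(function(s) s$repeat_idx == 1, splits),
                       function(s) sum(labels[s$test] == cl))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_identical(repeated_cv_splits(labels, strata, seed = 4)[[1]],
                   splits[[1]])
  expect_error(repeated_cv_splits(factor(c("case", rep("control", 20)),
                                         levels = c("control", "case")),
                                  NULL, folds = 5),
               "fewer members than folds")
})

test_that("mRMR picks the top-F feature first and penalizes redundant copies", {
  toy <- toy_classification(n = 60, n_feat = 5, shift = 2, seed = 3)
  expect_equal(mrmr_rank(toy$X, toy$y, 1), "f01")
  # duplicate of the winner is not picked second while informative
  # alternatives exist
  X2 <- cbind(toy$X, f01copy = toy$X[, "f01"])
  X2[, "f02"] <- X2[, "f02"] + 0.8 * toy$y   # second informative feature
  rk <- mrmr_rank(X2, toy$y, 3)
  expect_equal(rk[1], "f01")
  expect_false(rk[2] == "f01copy")
  # constant features are never chosen before non-constant ones
  X3 <- cbind(toy$X, konst = rep(1, 60))
  rk3 <- mrmr_rank(X3, toy$y, 6)
  expect_equal(rk3[6], "konst")
})

test_that("mRMR matches brute-force greedy evaluation on five features", {
  for (s in 1:5) {
    toy <- toy_classification(n = 30, n_feat = 5, shift = 1, seed = s)
    toy$X[, 2] <- toy$X[, 2] + 0.5 * toy$y
    toy$X[, 3] <- 0.7 * toy$X[, 1] + 0.3 * rnorm(30)
    expect_identical(mrmr_rank(toy$X, toy$y, 5), brute_mrmr(toy$X, toy$y, 5))
  }
})

test_that("penalized logistic fit matches an independent optimizer on the same objective", {
  toy <- toy_classification(n = 30, n_feat = 3, shift = 1.5, seed = 6)
  fit <- fit_logistic(toy$X, toy$y, l2_strength = 1.0)
  # oracle: generic BFGS on the penalized deviance over standardized features
  Z <- scale(toy$X, scale = apply(toy$X, 2, sd) * sqrt(29 / 30))
  obj <- function(b) {
    eta <- b[1] + Z %*% b[-1]
    sum(log1p(exp(eta)) - toy$y * eta) + 0.5 * sum(b[-1]^2)
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - opt$par)), 1e-4)
})

test_that("null labels shrink coefficients to zero and the intercept to the base-rate log-odds", {
  set.seed(7)
  n <- 4000
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, 1, 1, 0), n / 4)  # base rate 0.75, independent of X
  fit <- fit_logistic(X, y, l2_strength = 1.0)
  expect_lt(max(abs(fit$coefficients)), 0.05)
  expect_lt(abs(fit$intercept - log(0.75 / 0.25)), 0.1)
})

test_that("perfectly separated data converge to finite coefficients under the penalty", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), 6, 1, dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(X, y)
  expect_true(all(is.finite(coef(fit))))
  expect_gt(fit$coefficients[["f"]], 0)
})

test_that("risk prediction is a logistic of the standardized panel with >= cutoff calls", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_logistic(X, rep(c(0, 1), 10))
  # hand-built model: zero coefficients, intercept log(1/3) -> p = 0.25
  fit$coefficients[] <- 0
  fit$intercept <- log(1 / 3)
  expect_equal(unname(predict(fit, X)), rep(0.25, 20))
  expect_true(all(classify(fit, X) == "control"))
  # linear predictor exactly 0 -> probability 0.5 -> case at the 0.5 cutoff
  fit$intercept <- 0
  expect_true(all(classify(fit, X) == "case"))
  expect_error(predict(fit, X[, "a", drop = FALSE]), "absent.*b")
  # monotonicity: raising a positively weighted protein never lowers risk
  set.seed(9)
  for (i in 1:5) {
    toy <- toy_classification(40, 3, 1.5, seed = 10 + i)
    m <- fit_logistic(toy$X, toy$y)
    w <- which(m$coefficients > 0)
    if (!length(w)) next
    X2 <- toy$X
    X2[, w[1]] <- X2[, w[1]] + 1
    expect_true(all(predict(m, X2) >= predict(m, toy$X) - 1e-12))
  }
})

test_that("classification metrics match their definitions and the pair-counting AUC", {
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  p <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.1, 0.6, 0.6)
  m <- classification_metrics(y, as.integer(p >= 0.5), p)
  expect_equal(unname(m["roc_auc"]), brute_auc(p, y))
  tp <- 3; fp <- 2; fn <- 1; tn <- 2
  expect_equal(unname(m["precision"]), tp / (tp + fp))
  expect_equal(unname(m["recall"]), tp / (tp + fn))
  expect_equal(unname(m["balanced_accuracy"]),
               (tp / (tp + fn) + tn / (tn + fp)) / 2)
  # perfect predictions
  mp <- classification_metrics(c(0, 1), c(0, 1), c(0.1, 0.9))
  expect_equal(unname(mp), rep(1, 5))
  # constant scores: AUC 0.5 by tie half-credit
  mc <- classification_metrics(c(0, 1, 0, 1), p = rep(0.7, 4))
  expect_equal(unname(mc["roc_auc"]), 0.5)
  # single-class truth: AUC missing
  m1 <- classification_metrics(c(1, 1), c(1, 0), c(0.9, 0.2))
  expect_true(is.na(m1["roc_auc"]))
})

test_that("panel-size curve bookkeeping and the minimal-panel rule behave", {
  toy <- toy_classification(n = 50, n_feat = 6, shift = 2.5, seed = 20)
  ev <- evaluate_panel_sizes(toy$X, toy$y, strata = NULL, k_max = 3,
                             folds = 5, repeats = 2, seed = 3)
  expect_equal(nrow(ev$records), 3 * 5 * 2)
  expect_equal(as.vector(table(ev$records$k)), rep(10, 3))
  ev2 <- evaluate_panel_sizes(toy$X, toy$y, strata = NULL, k_max = 3,
                              folds = 5, repeats = 2, seed = 3)
  expect_identical(ev$records, ev2$records)      # deterministic by seed
  expect_warning(
    evaluate_panel_sizes(toy$X, toy$y, k_max = 99, folds = 2, repeats = 1),
    "truncated")
  # selection rule: ties -> smallest k; monotone increase -> k_max; flat -> 1
  expect_equal(select_panel_size(c(0.7, 0.9, 0.9)), 2)
  expect_equal(select_panel_size(c(0.5, 0.6, 0.7)), 3)
  expect_equal(select_panel_size(rep(0.8, 4)), 1)
})

test_that("one informative feature saturates the F1 curve at k = 1", {
  toy <- toy_classification(n = 80, n_feat = 8, shift = 3, seed = 21)
  ev <- evaluate_panel_sizes(toy$X, toy$y, k_max = 4, folds = 5, repeats = 2,
                             seed = 5)
  f1 <- ev$by_k$mean_f1
  expect_true(all(f1[2:4] <= f1[1] + 0.05))
})

test_that("final fit holds out a disjoint test set and freezes the model", {
  toy <- toy_classification(n = 100, n_feat = 10, shift = 2, seed = 22)
  fin <- final_fit(toy$X, toy$y, k_star = 3, seed = 7, endpoint = "F2")
  expect_length(intersect(fin$train_idx, fin$test_idx), 0)
  expect_equal(length(fin$test_idx) + length(fin$train_idx), 100)
  p1 <- predict(fin$model, toy$X)
  p2 <- predict(fin$model, toy$X)
  expect_identical(p1, p2)
  expect_s3_class(fin$model, "panel_model")
  expect_equal(length(fin$model$panel), 3)
})

test_that("panel models serialize to JSON and back without losing predictions", {
  toy <- toy_classification(n = 60, n_feat = 4, shift = 2, seed = 23)
  m <- fit_logistic(toy$X, toy$y, endpoint = "F2")
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_model(m, path)
  m2 <- read_panel_model(path)
  expect_equal(predict(m2, toy$X), predict(m, toy$X), tolerance = 1e-12)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
})

test_that("cross-validated aggregates stay within the per-split range", {
  toy <- toy_classification(n = 90, n_feat = 6, shift = 1.5, seed = 24)
  cv <- cv_panel(toy$X, toy$y, k = 2, folds = 5, repeats = 2, seed = 9)
  rep_auc <- cv$report[cv$report$metric == "roc_auc", ]
  expect_gte(rep_auc$mean, min(cv$records$roc_auc))
  expect_lte(rep_auc$mean, max(cv$records$roc_auc))
  se <- rep_auc$sd / sqrt(rep_auc$n_splits)
  expect_equal(rep_auc$ci_hi - rep_auc$mean, 1.96 * se, tolerance = 1e-12)
})
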