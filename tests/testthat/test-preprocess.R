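test_that("log2 transform is exact, guards double application, keeps the mask", {
  x <- protein_matrix(matrix(c(8, 1, NA, 2), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))),
                      scale = "linear")
  y <- log2_transform(x)
  expect_equal(y$values["a", "s1"], 3)
  expect_equal(y$values["b", "s1"], 0)
  expect_error(log2_transform(y), "already log2")
  r <- random_matrix(10, 10, miss = 0.3, seed = 3)
  expect_identical(is.na(log2_transform(r)$values), is.na(r$values))
})

test_that("proteome-depth filter removes samples below the threshold, boundary inclusive", {
  set.seed(1)
  v <- matrix(2^runif(300 * 3, 10, 20), 300, 3,
              dimnames = list(sprintf("p%03d", 1:300), c("keep", "edge", "drop")))
  v[201:300, "edge"] <- NA   # exactly 200 present: retained (>= semantics)
  v[200:300, "drop"] <- NA   # 199 present: removed
  f <- filter_min_proteins(protein_matrix(v, "linear"), 200)
  expect_setequal(sample_ids(f), c("keep", "edge"))
  expect_error(filter_min_proteins(protein_matrix(v, "linear"), 1000), "all samples")
})

test_that("valid-value filter keeps proteins at or above the fraction", {
  v <- matrix(1, 3, 5, dimnames = list(c("keep60", "keep100", "drop40"),
                                       sprintf("s%d", 1:5)))
  v["keep60", 1:2] <- NA   # 3/5 = 60% present
  v["drop40", 1:3] <- NA   # 2/5 = 40% present
  f <- filter_valid_values(protein_matrix(v, "linear"), 0.6)
  expect_setequal(protein_ids(f), c("keep60", "keep100"))
})

test_that("filters agree with a brute-force recount on a random mask", {
  x <- random_matrix(50, 20, miss = 0.35, seed = 17)
  keep_p <- rowSums(!is.na(x$values)) / 20 >= 0.6
  expect_identical(protein_ids(filter_valid_values(x, 0.6)),
                   protein_ids(x)[keep_p])
  keep_s <- colSums(!is.na(x$values)) >= 30
  expect_identical(sample_ids(filter_min_proteins(x, 30)),
                   sample_ids(x)[keep_s])
})

test_that("downshifted imputation matches its stated moments", {
  # one sample observing {10, 12}: m = 11, d = sqrt(2)
  n_miss <- 10000
  v <- matrix(NA_real_, n_miss + 2, 1,
              dimnames = list(sprintf("p%05d", 1:(n_miss + 2)), "s1"))
  v[1:2, 1] <- c(10, 12)
  imp <- impute_downshifted(protein_matrix(v, "log2"), impute_params(seed = 31))
  drawn <- imp$values[-(1:2), 1]
  mu <- 11 - 1.8 * sqrt(2)
  sdv <- 0.3 * sqrt(2)
  expect_lt(abs(mean(drawn) - mu), 3 * sdv / sqrt(n_miss))
  expect_lt(abs(sd(drawn) - sdv), 3 * sdv / sqrt(2 * n_miss))
  # observed cells untouched, result complete
  expect_equal(imp$values[1:2, 1], c(10, 12), ignore_attr = TRUE)
  expect_false(anyNA(imp$values))
})

test_that("imputation is identity on complete data and deterministic by seed", {
  x <- random_matrix(20, 5, miss = 0, seed = 2, scale = "log2")
  expect_identical(impute_downshifted(x)$values, x$values)
  y <- random_matrix(20, 8, miss = 0.3, seed = 4, scale = "log2")
  i1 <- impute_downshifted(y, impute_params(seed = 9))
  i2 <- impute_downshifted(y, impute_params(seed = 9))
  expect_identical(i1$values, i2$values)
  # imputed values sit below the per-sample observed mean (1.8 SD downshift,
  # 0.3 SD spread: the whole distribution lies under the mean)
  for (j in seq_len(ncol(y$values))) {
    obs_mean <- mean(y$values[, j], na.rm = TRUE)
    expect_true(all(i1$values[is.na(y$values[, j]), j] < obs_mean))
  }
  # a sample with fewer than two observations cannot be imputed
  v <- matrix(c(1, NA, NA), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_error(impute_downshifted(protein_matrix(v, "log2")), "fewer than 2")
})

test_that("QC CV filter removes irreproducible proteins on the linear scale", {
  v <- matrix(c(5, 5, 5,     # CV 0 -> kept
                1, 3, 2,     # CV = sd/mean = 1/2 > 0.3 -> removed
                4, 4.1, 3.9),# small CV -> kept
              3, 3, byrow = TRUE,
              dimnames = list(c("stable", "noisy", "ok"),
                              c("QC1", "QC2", "QC3")))
  cohort <- matrix(1, 3, 2, dimnames = list(rownames(v), c("s1", "s2")))
  x <- protein_matrix(cbind(cohort, v), "linear")
  f <- qc_cv_filter(x, c("QC1", "QC2", "QC3"), 0.30)
  expect_setequal(protein_ids(f), c("stable", "ok"))
  expect_setequal(sample_ids(f), c("s1", "s2"))
  # hand check of the {1, 3} two-replicate case: CV = sqrt(2)/2
  v2 <- matrix(c(1, 3), 1, 2, dimnames = list("p", c("QC1", "QC2")))
  x2 <- protein_matrix(cbind(matrix(1, 1, 1, dimnames = list("p", "s1")), v2),
                       "linear")
  expect_error(qc_cv_filter(x2, c("QC1", "QC2"), 0.30), "all proteins")
})

test_that("QC CV survivor set equals a brute-force recount on random data", {
  set.seed(8)
  qc <- matrix(2^rnorm(40 * 6, 15, 0.35), 40, 6,
               dimnames = list(sprintf("p%02d", 1:40), sprintf("QC%d", 1:6)))
  qc[sample(length(qc), 30)] <- NA
  cohort <- matrix(1, 40, 3,
                   dimnames = list(rownames(qc), sprintf("s%d", 1:3)))
  x <- protein_matrix(cbind(cohort, qc), "linear")
  f <- qc_cv_filter(x, colnames(qc), 0.30)
  manual <- sapply(seq_len(40), function(i) {
    r <- qc[i, !is.na(qc[i, ])]
    length(r) >= 2 && sd(r) / mean(r) <= 0.30
  })
  expect_setequal(protein_ids(f), rownames(qc)[manual])
  # proteins with <2 observed QC values are reported, not silently kept
  under <- rownames(qc)[rowSums(!is.na(qc)) < 2]
  expect_setequal(attr(f, "qc_excluded"), under)
})

test_that("pipeline yields a complete matrix and logs retained dimensions", {
  sim <- generate_cohort(cohort_config(seed = 12))
  cfg <- cohort_config(seed = 12)
  plasma <- apply_mnar_dropout(sim$plasma, cfg$mnar_midpoint,
                               cfg$mnar_steepness, seed = 1)
  out <- preprocess_pipeline(delog2_transform(plasma),
                             generate_qc_replicates(cfg),
                             impute = impute_params(seed = 2))
  expect_false(anyNA(out$values))
  expect_identical(out$scale, "log2")
  expect_match(attr(out, "log"), "retained")
})
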