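test_that("BH step-up matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  # permutation equivariance
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # monotone nondecreasing in p-rank, q >= p
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# shared small cohort for the ANCOVA / partial-correlation checks
.toy_cohort <- function(n = 100, seed = 1) {
  set.seed(seed)
  meta <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    age = rnorm(n, 55, 8), bmi = rnorm(n, 27, 4),
    sex = sample(c("male", "female"), n, TRUE),
    abstinent = sample(c(TRUE, FALSE), n, TRUE),
    kleiner_f = sample(0:4, n, TRUE), steatosis_s = sample(0:3, n, TRUE),
    stringsAsFactors = FALSE)
  meta
}

test_that("ANCOVA attributes covariate-driven signal to the covariate, not the stage", {
  meta <- .toy_cohort(150, seed = 2)
  v <- matrix(0.5 * meta$age, 1, 150,
              dimnames = list("ageprot", meta$sample_id))
  x <- protein_matrix(v + rnorm(150, 0, 1e-6), "log2")
  d <- ancova_stagewise(x, meta, "fibrosis",
                        covariates = c("age", "bmi", "sex", "abstinent"))
  expect_gt(d$p, 0.2)

  # pure stage signal is detected overwhelmingly
  v2 <- matrix(meta$kleiner_f + rnorm(150, 0, 0.01), 1, 150,
               dimnames = list("stageprot", meta$sample_id))
  d2 <- ancova_stagewise(protein_matrix(v2, "log2"), meta, "fibrosis",
                         covariates = c("age", "bmi"))
  expect_lt(d2$p, 1e-6)
  expect_equal(d2$direction, 1)
})

test_that("ANCOVA F and p match an explicit normal-equations fit on a fixed toy set", {
  set.seed(7)
  n <- 15
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     age = rnorm(n, 50, 10), bmi = rnorm(n, 26, 3),
                     kleiner_f = rep(0:2, each = 5))
  y <- rnorm(n) + 0.8 * meta$kleiner_f
  x <- protein_matrix(matrix(y, 1, n, dimnames = list("p1", meta$sample_id)),
                      "log2")
  d <- ancova_stagewise(x, meta, "fibrosis", covariates = c("age", "bmi"))
  # oracle: normal equations solved explicitly for full and reduced designs
  Xr <- cbind(1, meta$age, meta$bmi)
  Xf <- cbind(Xr, meta$kleiner_f == 1, meta$kleiner_f == 2)
  bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  rss_f <- sum((y - Xf %*% bf)^2)
  rss_r <- sum((y - Xr %*% br)^2)
  f_oracle <- ((rss_r - rss_f) / 2) / (rss_f / (n - 5))
  expect_equal(d$f_stat, f_oracle, tolerance = 1e-10)
  expect_equal(d$p, pf(f_oracle, 2, n - 5, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANCOVA merges sparse stage levels and rejects collinear designs", {
  meta <- .toy_cohort(60, seed = 3)
  meta$kleiner_f[meta$kleiner_f == 4] <- 3
  meta$kleiner_f[1] <- 4  # a single F4 sample
  x <- random_matrix(5, 60, miss = 0, seed = 4, scale = "log2")
  colnames(x$values) <- meta$sample_id
  expect_warning(
    d <- ancova_stagewise(x, meta, "fibrosis", covariates = c("age")),
    "merged")
  expect_equal(nrow(d), 5)
  meta$age2 <- meta$age  # exact duplicate covariate
  expect_error(
    suppressWarnings(
      ancova_stagewise(x, meta, "fibrosis", covariates = c("age", "age2"))),
    "collinear")
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  meta <- .toy_cohort(40, seed = 9)
  x <- random_matrix(6, 40, miss = 0, seed = 10, scale = "log2")
  colnames(x$values) <- meta$sample_id
  res <- spearman_partial_scores(x, meta, "fibrosis", covariates = character(0))
  for (i in 1:6) {
    ct <- suppressWarnings(
      cor.test(x$values[i, ], meta$kleiner_f, method = "spearman"))
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
  }
})

test_that("partial Spearman is invariant to monotone transforms and exact on rank-identical data", {
  meta <- .toy_cohort(50, seed = 11)
  # intensity strictly increasing in the score: r = 1
  v <- matrix(exp(meta$kleiner_f), 1, 50,
              dimnames = list("mono", meta$sample_id))
  res <- spearman_partial_scores(protein_matrix(v, "log2"), meta, "fibrosis",
                                 covariates = character(0))
  expect_equal(res$r, 1)
  # monotone transform leaves the partial r unchanged
  x <- random_matrix(4, 50, miss = 0, seed = 12, scale = "log2")
  colnames(x$values) <- meta$sample_id
  r1 <- spearman_partial_scores(x, meta, "fibrosis",
                                covariates = c("age", "bmi"))$r
  x2 <- protein_matrix(exp(x$values / 4), "log2")
  r2 <- spearman_partial_scores(x2, meta, "fibrosis",
                                covariates = c("age", "bmi"))$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("partial Spearman matches brute-force residualization on a fixed example", {
  set.seed(13)
  n <- 12
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     age = rnorm(n, 50, 5), kleiner_f = sample(0:4, n, TRUE))
  v <- rnorm(n) + 0.5 * meta$kleiner_f
  x <- protein_matrix(matrix(v, 1, n, dimnames = list("p", meta$sample_id)),
                      "log2")
  res <- spearman_partial_scores(x, meta, "fibrosis", covariates = "age")
  # oracle: residualize average ranks on ranked covariate by explicit lm
  rv <- rank(v); rs <- rank(meta$kleiner_f); ra <- rank(meta$age)
  e1 <- resid(lm(rv ~ ra)); e2 <- resid(lm(rs ~ ra))
  r_oracle <- cor(e1, e2)
  t_oracle <- r_oracle * sqrt((n - 3) / (1 - r_oracle^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(t_oracle), n - 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$n_used, n)
})
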