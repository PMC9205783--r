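# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementations they check.

# random protein matrix with a missingness mask
random_matrix <- function(n_prot = 20, n_samp = 10, miss = 0.2, seed = 42,
                          scale = "linear") {
  set.seed(seed)
  v <- matrix(2^runif(n_prot * n_samp, 10, 25), n_prot, n_samp,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              sprintf("S%03d", seq_len(n_samp))))
  v[runif(length(v)) < miss] <- NA
  if (scale == "log2") v <- log2(v)
  protein_matrix(v, scale = scale)
}

# AUC by exhaustive case-control pair counting with tie half-credit
brute_auc <- function(p, y) {
  cases <- p[y == 1]; controls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Harrell's C by exhaustive pair enumeration
brute_harrell <- function(risk, time, event) {
  conc <- ties <- comp <- 0
  n <- length(risk)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      e <- if (event[i]) i else j
    } else {
      e <- if (time[i] < time[j]) i else j
      if (!event[e]) next
    }
    o <- setdiff(c(i, j), e)
    comp <- comp + 1
    if (risk[e] > risk[o]) conc <- conc + 1
    else if (risk[e] == risk[o]) ties <- ties + 1
  }
  if (comp == 0) return(NA_real_)
  (conc + 0.5 * ties) / comp
}

# greedy mRMR by direct evaluation of the criterion (F / mean |cor|)
brute_mrmr <- function(X, y, k) {
  fstat <- sapply(colnames(X), function(f) {
    a <- X[y == 1, f]; b <- X[y == 0, f]
    if (var(c(a, b)) == 0) return(0)
    summary(aov(X[, f] ~ factor(y)))[[1]][["F value"]][1]
  })
  sel <- character(0)
  remaining <- colnames(X)
  for (step in seq_len(k)) {
    score <- sapply(remaining, function(f) {
      if (!length(sel)) return(fstat[f])
      red <- mean(sapply(sel, function(s) {
        r <- suppressWarnings(cor(X[, f], X[, s]))
        if (is.na(r)) 0 else abs(r)
      }))
      fstat[f] / max(red, 0.001)
    })
    pick <- remaining[order(-score, remaining)[1]]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  sel
}

# jackknife variance of the Mann-Whitney AUC
jackknife_auc_var <- function(p, y) {
  n <- length(p)
  theta <- sapply(seq_len(n), function(i) brute_auc(p[-i], y[-i]))
  (n - 1) / n * sum((theta - mean(theta))^2)
}

# small labeled feature matrix with one informative feature block
toy_classification <- function(n = 40, n_feat = 5, shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("f%02d", 1:n_feat)))
  X[, 1] <- X[, 1] + shift * y
  list(X = X, y = y)
}
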