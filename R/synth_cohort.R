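#' Synthetic ALD cohort configuration
#'
#' Defaults emulate the biopsied subset of a derivation cohort of patients
#' with alcohol-related liver disease: 360 biopsied patients with fibrosis
#' stage counts 36/124/106/27/67 (F0-F4), NAS inflammation/steatosis scores
#' available for 352 of them with marginal counts 72/91/82/53/31/23
#' (activity 0-5) and 156/85/72/39 (steatosis 0-3), 76% male, 42% abstinent.
#' Histology scores share a latent Gaussian copula (Spearman 0.6 between
#' fibrosis and inflammation, 0.3 between fibrosis and steatosis). Planted
#' marker proteins respond log-additively to one histology axis.
#'
#' @param n_patients cohort size; patients beyond the biopsied subset carry
#'   no histology scores.
#' @param stage_distribution counts per fibrosis stage F0-F4; their sum is
#'   the biopsied subset size.
#' @param n_nas_scored how many biopsied patients carry inflammation and
#'   steatosis scores (the remainder have missing NAS scores).
#' @param activity_distribution,steatosis_distribution marginal counts of the
#'   activity (0-5) and steatosis (0-3) scores among the NAS-scored subset.
#' @param n_proteins number of plasma proteins simulated.
#' @param n_markers planted stage-responsive proteins per lesion axis
#'   (fibrosis, inflammation, steatosis).
#' @param effect_slope log2 units per stage step for planted markers
#'   (random sign per marker).
#' @param noise_sd residual SD in log2 units.
#' @param copula_fi,copula_fs latent Spearman rank correlations
#'   fibrosis-inflammation and fibrosis-steatosis.
#' @param mnar_midpoint,mnar_steepness dropout logistic: a log2 intensity at
#'   50% dropout and the slope (1/log2 units) of the dropout curve.
#' @param liver_pair_fraction fraction of patients with a paired liver matrix.
#' @param qc_replicates number of quality-control replicate injections.
#' @param qc_cv target workflow coefficient of variation of the QC replicates.
#' @param hazard_base baseline liver-related-event hazard (events/month at F0).
#' @param hazard_log_hr_per_stage log hazard ratio per fibrosis stage.
#' @param censor_months administrative censoring horizon.
#' @param cohort_label cohort tag written into the metadata.
#' @param seed master seed; all randomness fans out from it through named
#'   substreams.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 360L,
                          stage_distribution = c(36L, 124L, 106L, 27L, 67L),
                          n_nas_scored = 352L,
                          activity_distribution = c(72L, 91L, 82L, 53L, 31L, 23L),
                          steatosis_distribution = c(156L, 85L, 72L, 39L),
                          n_proteins = 500L,
                          n_markers = 9L,
                          effect_slope = 0.5,
                          noise_sd = 0.5,
                          copula_fi = 0.6,
                          copula_fs = 0.3,
                          mnar_midpoint = 15,
                          mnar_steepness = 0.8,
                          liver_pair_fraction = 0.22,
                          qc_replicates = 13L,
                          qc_cv = 0.19,
                          hazard_base = 0.001,
                          hazard_log_hr_per_stage = 0.65,
                          censor_months = 72,
                          cohort_label = "derivation",
                          seed = 1L) {
  cfg <- as.list(environment())
  if (any(stage_distribution < 0) || sum(stage_distribution) == 0)
    stop("stage_distribution must be nonnegative with positive sum")
  if (n_patients < sum(stage_distribution))
    stop("n_patients smaller than the biopsied subset implied by stage_distribution")
  if (n_nas_scored > sum(stage_distribution))
    stop("n_nas_scored cannot exceed the biopsied subset")
  if (sum(activity_distribution) != n_nas_scored ||
      sum(steatosis_distribution) != n_nas_scored)
    stop("activity/steatosis distributions must sum to n_nas_scored")
  stopifnot(noise_sd >= 0, effect_slope >= 0 || TRUE,
            liver_pair_fraction >= 0, liver_pair_fraction <= 1,
            hazard_base >= 0, censor_months >= 0)
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic substream seed from (master seed, stream name); < 2^31
.substream <- function(seed, name) {
  s <- abs(as.numeric(seed)) %% 2147483647
  for (c in utf8ToInt(name)) s <- (s * 31 + c) %% 2147483647
  as.integer(s)
}

# exact-marginal ordinal assignment: rank latent z, cut at cumulative counts
.assign_by_rank <- function(z, counts) {
  stopifnot(length(z) == sum(counts))
  grade <- rep(seq_along(counts) - 1L, counts)
  out <- integer(length(z))
  out[order(z)] <- grade
  out
}

#' Generate a synthetic ALD cohort with ground truth
#'
#' Produces complete (pre-dropout) log2 plasma and liver matrices, sample
#' metadata with histology, covariates, comparator tests and right-censored
#' outcomes, and a ground-truth record of the planted markers. Abundance-
#' dependent missingness is applied separately with [apply_mnar_dropout()].
#'
#' Protein baselines are drawn uniformly over a 12-log2-unit dynamic range;
#' a planted marker for one lesion axis adds `slope * score` (slope of
#' random sign and magnitude `effect_slope`) to its baseline, plus
#' independent Gaussian noise. Paired liver profiles share the planted
#' slopes with matched sign so liver-plasma marker correlation is positive.
#' Comparator tests are noisy monotone transforms of the relevant histology
#' score with per-patient availability drawn from a small set of
#' missingness patterns.
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `plasma`, `liver` ([protein_matrix], log2),
#'   `meta` (data frame), `pairing` (liver to plasma sample-id map) and
#'   `truth` (planted markers, true slopes, true scores, true hazards).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  n_biopsy <- sum(cfg$stage_distribution)
  ids <- sprintf("P%04d", seq_len(n))

  ## -- histology via latent Gaussian copula ------------------------------
  set.seed(.substream(cfg$seed, "histology"))
  r_fi <- 2 * sin(pi * cfg$copula_fi / 6)   # Spearman -> Pearson on latents
  r_fs <- 2 * sin(pi * cfg$copula_fs / 6)
  zf <- stats::rnorm(n)
  zi <- r_fi * zf + sqrt(1 - r_fi^2) * stats::rnorm(n)
  zs <- r_fs * zf + sqrt(1 - r_fs^2) * stats::rnorm(n)
  biopsied <- sort(sample.int(n, n_biopsy))
  true_f <- rep(NA_integer_, n)
  true_f[biopsied] <- .assign_by_rank(zf[biopsied], cfg$stage_distribution)
  nas_scored <- sort(sample(biopsied, cfg$n_nas_scored))
  true_a <- rep(NA_integer_, n)
  true_a[nas_scored] <- .assign_by_rank(zi[nas_scored], cfg$activity_distribution)
  true_s <- rep(NA_integer_, n)
  true_s[nas_scored] <- .assign_by_rank(zs[nas_scored], cfg$steatosis_distribution)
  # effect scores for everyone (unscored patients still have latent biology)
  eff_f <- .assign_by_rank(zf, .scale_counts(cfg$stage_distribution, n))
  eff_a <- .assign_by_rank(zi, .scale_counts(cfg$activity_distribution, n))
  eff_s <- .assign_by_rank(zs, .scale_counts(cfg$steatosis_distribution, n))
  eff_f[biopsied] <- true_f[biopsied]
  eff_a[nas_scored] <- true_a[nas_scored]
  eff_s[nas_scored] <- true_s[nas_scored]
  ballooning <- pmin(2L, as.integer(round(0.4 * true_a)))
  lobular <- true_a - ballooning

  ## -- covariates --------------------------------------------------------
  set.seed(.substream(cfg$seed, "covariates"))
  age <- round(pmin(90, pmax(20, stats::rnorm(n, 57, 9.6))))
  bmi <- round(stats::rlnorm(n, log(27.4), 0.18), 1)
  sex <- ifelse(stats::runif(n) < 0.76, "male", "female")
  abstinent <- stats::runif(n) < 0.42

  ## -- plasma proteome (complete, log2) ----------------------------------
  set.seed(.substream(cfg$seed, "proteome"))
  prot <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
  baseline <- stats::runif(cfg$n_proteins, 14, 26)
  axes <- c("fibrosis", "inflammation", "steatosis")
  marker_idx <- matrix(sample.int(cfg$n_proteins, 3L * cfg$n_markers),
                       nrow = 3L, dimnames = list(axes, NULL))
  slopes <- stats::setNames(numeric(cfg$n_proteins), prot)
  axis_of <- stats::setNames(rep(NA_character_, cfg$n_proteins), prot)
  sign_draw <- sample(c(-1, 1), 3L * cfg$n_markers, replace = TRUE)
  slopes[as.vector(t(marker_idx))] <- 0  # placeholder, filled next
  k <- 0L
  for (ax in axes) for (j in marker_idx[ax, ]) {
    k <- k + 1L
    slopes[j] <- sign_draw[k] * cfg$effect_slope
    axis_of[j] <- ax
  }
  score_mat <- rbind(fibrosis = eff_f, inflammation = eff_a, steatosis = eff_s)
  signal <- matrix(0, cfg$n_proteins, n)
  for (ax in axes) {
    rows <- marker_idx[ax, ]
    signal[rows, ] <- signal[rows, ] +
      outer(slopes[rows], score_mat[ax, ])
  }
  plasma_vals <- baseline + signal +
    matrix(stats::rnorm(cfg$n_proteins * n, 0, cfg$noise_sd), cfg$n_proteins, n)
  dimnames(plasma_vals) <- list(prot, ids)
  plasma <- protein_matrix(plasma_vals, scale = "log2")

  ## -- paired liver proteome --------------------------------------------
  set.seed(.substream(cfg$seed, "liver"))
  n_liver <- round(cfg$liver_pair_fraction * n)
  liver_idx <- sort(sample.int(n, n_liver))
  liver_baseline <- stats::runif(cfg$n_proteins, 14, 26)
  liver_vals <- liver_baseline + signal[, liver_idx, drop = FALSE] +
    matrix(stats::rnorm(cfg$n_proteins * n_liver, 0, cfg$noise_sd),
           cfg$n_proteins, n_liver)
  liver_ids <- paste0("L", ids[liver_idx])
  dimnames(liver_vals) <- list(prot, liver_ids)
  liver <- protein_matrix(liver_vals, scale = "log2")
  pairing <- data.frame(liver_sample_id = liver_ids,
                        plasma_sample_id = ids[liver_idx],
                        stringsAsFactors = FALSE)

  ## -- clinical comparator tests ----------------------------------------
  set.seed(.substream(cfg$seed, "comparators"))
  comp <- data.frame(
    TE   = exp(log(4.5) + 0.30 * eff_f + stats::rnorm(n, 0, 0.35)),
    FIB4 = exp(log(1.0) + 0.35 * eff_f + stats::rnorm(n, 0, 0.45)),
    APRI = exp(log(0.4) + 0.30 * eff_f + stats::rnorm(n, 0, 0.50)),
    ALT  = exp(log(25)  + 0.25 * eff_a + stats::rnorm(n, 0, 0.40)),
    CAP  = 230 + 25 * eff_s + stats::rnorm(n, 0, 30)
  )
  # availability patterns: which comparators were actually measured
  patterns <- list(all = character(0), no_te = "TE", no_cap = "CAP",
                   no_te_cap = c("TE", "CAP"), no_indices = c("FIB4", "APRI"))
  p_pattern <- c(0.55, 0.15, 0.15, 0.10, 0.05)
  pat <- sample(seq_along(patterns), n, replace = TRUE, prob = p_pattern)
  for (i in seq_len(n))
    comp[i, patterns[[pat[i]]]] <- NA_real_
  comp <- round(comp, 2)

  meta <- data.frame(
    sample_id = ids, cohort = cfg$cohort_label,
    age = age, bmi = bmi, sex = sex, abstinent = abstinent,
    kleiner_f = true_f, lobular = lobular, ballooning = ballooning,
    steatosis_s = true_s, stringsAsFactors = FALSE)
  meta <- derive_activity_score(meta)
  meta <- cbind(meta, comp)

  ## -- outcomes ----------------------------------------------------------
  meta_out <- generate_outcomes(
    meta, stage = eff_f,
    hazard_base = cfg$hazard_base,
    hazard_log_hr_per_stage = cfg$hazard_log_hr_per_stage,
    censor_months = cfg$censor_months,
    seed = .substream(cfg$seed, "outcomes"))
  validate_sample_meta(meta_out)

  truth <- list(
    markers = lapply(axes, function(ax) prot[marker_idx[ax, ]]),
    slopes = slopes,
    true_scores = data.frame(sample_id = ids, fibrosis = eff_f,
                             inflammation = eff_a, steatosis = eff_s),
    hazard = cfg$hazard_base * exp(cfg$hazard_log_hr_per_stage * eff_f))
  names(truth$markers) <- axes

  list(plasma = plasma, liver = liver, meta = meta_out,
       pairing = pairing, truth = truth)
}

# rescale an exact count vector to a different total (for latent effect scores)
.scale_counts <- function(counts, total) {
  sc <- floor(counts / sum(counts) * total)
  rem <- total - sum(sc)
  if (rem > 0) {
    frac <- counts / sum(counts) * total - sc
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sc[add] <- sc[add] + 1L
  }
  sc
}

#' Abundance-dependent (MNAR) dropout
#'
#' Removes each present cell independently with probability
#' `plogis(-steepness * (x - midpoint))`: low-abundance values drop out
#' preferentially, the mechanism that motivates downshifted-normal
#' imputation.
#'
#' @param x a log2-scale [protein_matrix].
#' @param midpoint log2 intensity at which dropout probability is 50%.
#' @param steepness logistic slope (1 / log2 units); 0 means uniform 50%.
#' @param seed RNG seed.
#' @return the matrix with cells set missing.
#' @export
apply_mnar_dropout <- function(x, midpoint, steepness, seed = 1L) {
  stopifnot(inherits(x, "protein_matrix"))
  if (x$scale != "log2") stop("MNAR dropout operates on log2-scale matrices")
  set.seed(seed)
  v <- x$values
  p_drop <- stats::plogis(-steepness * (v - midpoint))
  drop <- !is.na(v) & stats::runif(length(v)) < p_drop
  v[drop] <- NA_real_
  protein_matrix(v, scale = "log2")
}

#' Simulate right-censored outcomes
#'
#' Liver-related-event times are exponential with per-patient rate
#' `hazard_base * exp(hazard_log_hr_per_stage * stage)`; all-cause mortality
#' is generated analogously with an attenuated stage coefficient (half) and
#' a lower base rate. Observed times are administratively censored at
#' `censor_months`; a liver-related event is only observed if it precedes
#' both death and censoring, so `lre_time_months <= followup_months`.
#'
#' @param meta sample metadata (uses `kleiner_f` unless `stage` is given).
#' @param hazard_base events per month at stage 0.
#' @param hazard_log_hr_per_stage log hazard-ratio per fibrosis stage.
#' @param censor_months administrative censoring horizon.
#' @param seed RNG seed.
#' @param stage optional complete stage vector overriding `meta$kleiner_f`.
#' @return `meta` with `followup_months`, `death`, `lre_time_months`,
#'   `lre_event` columns filled.
#' @export
generate_outcomes <- function(meta, hazard_base, hazard_log_hr_per_stage,
                              censor_months, seed = 1L, stage = NULL) {
  if (is.null(stage)) stage <- meta$kleiner_f
  if (is.null(stage) || any(is.na(stage)))
    stop("fibrosis stage required for every patient to simulate outcomes")
  if (hazard_base < 0) stop("negative hazard rate")
  n <- nrow(meta)
  set.seed(seed)
  rate_lre <- hazard_base * exp(hazard_log_hr_per_stage * stage)
  rate_death <- 0.7 * hazard_base * exp(0.5 * hazard_log_hr_per_stage * stage)
  t_lre <- if (hazard_base > 0) stats::rexp(n, rate_lre) else rep(Inf, n)
  t_death <- if (hazard_base > 0) stats::rexp(n, rate_death) else rep(Inf, n)
  fu <- pmin(t_death, censor_months)
  meta$followup_months <- round(fu, 2)
  meta$death <- t_death <= censor_months
  meta$lre_event <- t_lre <= fu
  meta$lre_time_months <- round(pmin(t_lre, fu), 2)
  meta
}

#' Simulate quality-control replicate injections
#'
#' QC replicates share one fixed protein profile (the cohort's protein
#' baselines on the linear scale) with multiplicative lognormal noise tuned
#' to a target coefficient of variation.
#'
#' @param cfg a [cohort_config()]; uses `n_proteins`, `qc_replicates`, `qc_cv`.
#' @param seed RNG seed (defaults to the config's `qc` substream).
#' @return linear-scale [protein_matrix] of QC columns `QC01`, `QC02`, ...
#' @export
generate_qc_replicates <- function(cfg = cohort_config(), seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(.substream(cfg$seed, "proteome"))  # same baselines as the cohort
  prot <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
  baseline <- stats::runif(cfg$n_proteins, 14, 26)
  if (is.null(seed)) seed <- .substream(cfg$seed, "qc")
  set.seed(seed)
  sdlog <- sqrt(log(1 + cfg$qc_cv^2))  # lognormal CV -> sdlog
  m <- cfg$qc_replicates
  vals <- 2^baseline * matrix(exp(stats::rnorm(cfg$n_proteins * m, 0, sdlog)),
                              cfg$n_proteins, m)
  dimnames(vals) <- list(prot, sprintf("QC%02d", seq_len(m)))
  protein_matrix(vals, scale = "linear")
}
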