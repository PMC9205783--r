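#' Load a pipeline run configuration
#'
#' A YAML or JSON document with any of the blocks `cohort` (arguments to
#' [cohort_config()]), `preprocess` (`min_proteins`, `min_valid_frac`,
#' `max_qc_cv`, `impute_shift`, `impute_width`), `ml` (`k_max`, `folds`,
#' `repeats`, `l2_strength`, `endpoints`, `considered_vars`), `comparators`
#' (list of name/cutoff/direction), `prognosis` (`horizons`), plus `seed`
#' and `outdir`. Missing blocks fall back to package defaults.
#'
#' @param path config file; NULL for all defaults.
#' @param overrides named list merged over the file contents.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
  }
  base <- list(
    seed = 1L, outdir = "ald_run",
    cohort = list(), qc = TRUE,
    preprocess = list(min_proteins = 200L, min_valid_frac = 0.6,
                      max_qc_cv = 0.30, impute_shift = 1.8, impute_width = 0.3),
    ml = list(k_max = 10L, folds = 5L, repeats = 10L, l2_strength = 1.0,
              endpoints = c("F2", "F3", "I2", "S1"),
              considered_vars = c("TE", "FIB4", "APRI", "ALT", "CAP")),
    comparators = list(
      list(name = "TE", cutoff = 9.6, direction = "higher_is_case",
           endpoint = "F2"),
      list(name = "FIB4", cutoff = 1.45, direction = "higher_is_case",
           endpoint = "F2"),
      list(name = "APRI", cutoff = 0.5, direction = "higher_is_case",
           endpoint = "F2"),
      list(name = "ALT", cutoff = 40, direction = "higher_is_case",
           endpoint = "I2"),
      list(name = "CAP", cutoff = 248, direction = "higher_is_case",
           endpoint = "S1")),
    prognosis = list(horizons = c(36, 60)))
  cfg <- utils::modifyList(base, cfg)
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

.provenance <- function(outdir, stage, inputs, params, seed) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(stage = stage, inputs = sums, params = params, seed = seed,
              package_version = as.character(utils::packageVersion("aldpanel")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(obj, file.path(outdir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort from the config's `cohort` block, applies
#' MNAR dropout to the plasma and liver matrices, and writes
#' `plasma.tsv`, `liver.tsv`, `meta.tsv`, `pairing.tsv`, `qc.tsv`,
#' `events.tsv` and `truth_markers.tsv` to the output directory.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
cmd_simulate <- function(config = run_config()) {
  outdir <- config$outdir
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    message("created output directory ", outdir)
  }
  cfg <- do.call(cohort_config, utils::modifyList(list(seed = config$seed),
                                                  as.list(config$cohort)))
  sim <- generate_cohort(cfg)
  plasma <- apply_mnar_dropout(sim$plasma, cfg$mnar_midpoint,
                               cfg$mnar_steepness,
                               seed = .substream(cfg$seed, "dropout_plasma"))
  liver <- apply_mnar_dropout(sim$liver, cfg$mnar_midpoint,
                              cfg$mnar_steepness,
                              seed = .substream(cfg$seed, "dropout_liver"))
  write_protein_matrix(delog2_transform(plasma), file.path(outdir, "plasma.tsv"))
  write_protein_matrix(delog2_transform(liver), file.path(outdir, "liver.tsv"))
  write_protein_matrix(generate_qc_replicates(cfg), file.path(outdir, "qc.tsv"))
  write_sample_meta(sim$meta, file.path(outdir, "meta.tsv"))
  utils::write.table(sim$pairing, file.path(outdir, "pairing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # event table: one named qualifying outcome per simulated LRE
  set.seed(.substream(cfg$seed, "event_names"))
  ev <- sim$meta[sim$meta$lre_event %in% TRUE, , drop = FALSE]
  events <- data.frame(
    sample_id = ev$sample_id,
    event_name = sample(lre_event_types, nrow(ev), replace = TRUE),
    time_months = ev$lre_time_months, stringsAsFactors = FALSE)
  utils::write.table(events, file.path(outdir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tm <- do.call(rbind, lapply(names(sim$truth$markers), function(ax)
    data.frame(protein_id = sim$truth$markers[[ax]], axis = ax,
               slope = unname(sim$truth$slopes[sim$truth$markers[[ax]]]),
               stringsAsFactors = FALSE)))
  utils::write.table(tm, file.path(outdir, "truth_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .provenance(outdir, "simulate", character(0), unclass(cfg), config$seed)
  invisible(outdir)
}

.need <- function(outdir, files, stage) {
  paths <- file.path(outdir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing input artifact(s): ",
         paste(missing, collapse = ", "),
         " -- run the producing stage first")
  paths
}

#' Run pipeline stages
#'
#' Executes the requested stages in their canonical order
#' (`preprocess`, `diff`, `integrate`, `train`, `benchmark`, `prognosis`)
#' against the artifacts in `config$outdir`, writing TSV results and a JSON
#' provenance block per stage. Each stage checks that the artifacts it needs
#' exist and fails naming the missing one otherwise.
#'
#' @param config a [run_config()].
#' @param stages subset of the stage names above.
#' @return named list of in-memory stage results, invisibly.
#' @export
cmd_run <- function(config = run_config(),
                    stages = c("preprocess", "diff", "integrate", "train",
                               "benchmark", "prognosis")) {
  order_all <- c("preprocess", "diff", "integrate", "train", "benchmark",
                 "prognosis")
  stages <- order_all[order_all %in% stages]
  if (!length(stages)) stop("no recognised stages requested")
  outdir <- config$outdir
  res <- list()
  pp <- config$preprocess
  seed <- config$seed

  if ("preprocess" %in% stages) {
    ins <- .need(outdir, c("plasma.tsv", "meta.tsv"), "preprocess")
    plasma <- read_protein_matrix(file.path(outdir, "plasma.tsv"))
    qc <- if (file.exists(file.path(outdir, "qc.tsv")))
      read_protein_matrix(file.path(outdir, "qc.tsv")) else NULL
    imp <- impute_params(pp$impute_shift, pp$impute_width,
                         seed = .substream(seed, "impute_plasma"))
    n0 <- nrow(plasma$values)
    proc <- preprocess_pipeline(plasma, qc, pp$min_proteins,
                                pp$min_valid_frac, pp$max_qc_cv, imp)
    message(sprintf("preprocess: %d -> %d proteins after filtering", n0,
                    nrow(proc$values)))
    write_protein_matrix(proc, file.path(outdir, "plasma_processed.tsv"))
    if (file.exists(file.path(outdir, "liver.tsv"))) {
      liver <- read_protein_matrix(file.path(outdir, "liver.tsv"))
      proc_l <- preprocess_pipeline(
        liver, NULL, min_proteins = 0L, min_valid_frac = pp$min_valid_frac,
        impute = impute_params(pp$impute_shift, pp$impute_width,
                               seed = .substream(seed, "impute_liver")))
      write_protein_matrix(proc_l, file.path(outdir, "liver_processed.tsv"))
    }
    .provenance(outdir, "preprocess", ins, pp, seed)
    res$preprocess <- proc
  }

  if ("diff" %in% stages) {
    ins <- .need(outdir, c("plasma_processed.tsv", "meta.tsv"), "diff")
    mat <- read_protein_matrix(file.path(outdir, "plasma_processed.tsv"))
    meta <- read_sample_meta(file.path(outdir, "meta.tsv"))
    diffs <- list()
    for (fac in c("fibrosis", "inflammation", "steatosis")) {
      d <- ancova_stagewise(mat, meta, fac)
      s <- spearman_partial_scores(mat, meta, fac)
      utils::write.table(d, file.path(outdir, paste0("diff_", fac, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(s, file.path(outdir, paste0("corr_", fac, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("diff[%s]: %d/%d proteins significant (ANCOVA q<0.05)",
                      fac, sum(d$significant), nrow(d)))
      diffs[[fac]] <- list(ancova = d, spearman = s)
    }
    .provenance(outdir, "diff", ins, list(), seed)
    res$diff <- diffs
  }

  if ("integrate" %in% stages) {
    ins <- .need(outdir, c("plasma_processed.tsv", "liver_processed.tsv",
                           "pairing.tsv", "meta.tsv"), "integrate")
    plasma <- read_protein_matrix(file.path(outdir, "plasma_processed.tsv"))
    liver <- read_protein_matrix(file.path(outdir, "liver_processed.tsv"))
    pairing <- utils::read.table(file.path(outdir, "pairing.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    pc <- pair_correlation(liver, plasma, pairing)
    utils::write.table(pc, file.path(outdir, "pair_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(abundance_map(liver, plasma),
                       file.path(outdir, "abundance_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .provenance(outdir, "integrate", ins, list(), seed)
    res$integrate <- pc
  }

  if ("train" %in% stages) {
    ins <- .need(outdir, c("plasma_processed.tsv", "meta.tsv"), "train")
    mat <- read_protein_matrix(file.path(outdir, "plasma_processed.tsv"))
    meta <- read_sample_meta(file.path(outdir, "meta.tsv"))
    ml <- config$ml
    X_all <- t(mat$values)
    models <- list()
    for (ep in ml$endpoints) {
      lab <- label_endpoint(meta, ep)
      keep <- !is.na(lab) & meta$sample_id %in% rownames(X_all)
      X <- X_all[meta$sample_id[keep], , drop = FALSE]
      y <- lab[keep]
      strata <- missingness_strata(meta[keep, , drop = FALSE],
                                   ml$considered_vars, ml$folds)
      ep_seed <- .substream(seed, paste0("train_", ep))
      curve <- evaluate_panel_sizes(X, y, strata, k_max = ml$k_max,
                                    folds = ml$folds, repeats = ml$repeats,
                                    seed = ep_seed,
                                    l2_strength = ml$l2_strength)
      k_star <- select_panel_size(curve$by_k)
      fin <- final_fit(X, y, k_star, strata, seed = ep_seed,
                       l2_strength = ml$l2_strength, endpoint = ep)
      message(sprintf("train[%s]: k*=%d, held-out AUC %.3f", ep, k_star,
                      fin$metrics[["roc_auc"]]))
      write_panel_model(fin$model, file.path(outdir, paste0("model_", ep, ".json")))
      utils::write.table(curve$by_k,
                         file.path(outdir, paste0("panel_curve_", ep, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = rownames(X)[fin$test_idx],
                   probability = fin$test_probabilities,
                   label = y[fin$test_idx]),
        file.path(outdir, paste0("final_test_", ep, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      models[[ep]] <- list(model = fin$model, k_star = k_star,
                           metrics = fin$metrics, curve = curve$by_k)
    }
    .provenance(outdir, "train", ins, ml, seed)
    res$train <- models
  }

  if ("benchmark" %in% stages) {
    ins <- .need(outdir, c("meta.tsv"), "benchmark")
    meta <- read_sample_meta(file.path(outdir, "meta.tsv"))
    rows <- list()
    for (cs in config$comparators) {
      ep <- cs$endpoint
      test_file <- file.path(outdir, paste0("final_test_", ep, ".tsv"))
      if (!file.exists(test_file))
        stop("stage 'benchmark' is missing input artifact(s): ",
             basename(test_file), " -- run the producing stage first")
      ft <- utils::read.table(test_file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      mm <- meta[match(ft$sample_id, meta$sample_id), , drop = FALSE]
      spec <- comparator_spec(cs$name, cs$cutoff, cs$direction)
      vals <- mm[[cs$name]]
      ok <- !is.na(vals)
      if (sum(ok) < 5L) next
      cm <- comparator_metrics(vals[ok], spec, ft$label[ok])
      dl <- delong_test(ft$probability[ok],
                        if (spec$direction == "higher_is_case") vals[ok]
                        else -vals[ok],
                        ft$label[ok])
      nr <- nri(as.integer(ft$probability[ok] >= 0.5),
                comparator_calls(vals[ok], spec),
                ft$label[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, comparator = cs$name, n_used = sum(ok),
        comparator_f1 = cm[["f1"]], comparator_auc = cm[["roc_auc"]],
        model_auc = dl$auc1, delong_z = dl$z, delong_p = dl$p,
        nri_total = nr$nri_total, stringsAsFactors = FALSE)
    }
    bench <- do.call(rbind, rows)
    utils::write.table(bench, file.path(outdir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .provenance(outdir, "benchmark", ins, list(), seed)
    res$benchmark <- bench
  }

  if ("prognosis" %in% stages) {
    ins <- .need(outdir, c("plasma_processed.tsv", "meta.tsv", "events.tsv"),
                 "prognosis")
    mat <- read_protein_matrix(file.path(outdir, "plasma_processed.tsv"))
    meta <- read_sample_meta(file.path(outdir, "meta.tsv"))
    events <- utils::read.table(file.path(outdir, "events.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
    records <- compose_lre(meta, events)
    rows <- list()
    for (ep in config$ml$endpoints) {
      mf <- file.path(outdir, paste0("model_", ep, ".json"))
      if (!file.exists(mf)) next
      model <- read_panel_model(mf)
      pe <- prognostic_eval(model, t(mat$values), records,
                            config$prognosis$horizons)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, c_index = pe$c_index,
        t(pe$horizon_auc), stringsAsFactors = FALSE)
    }
    prog <- do.call(rbind, rows)
    utils::write.table(prog, file.path(outdir, "prognosis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .provenance(outdir, "prognosis", ins, config$prognosis, seed)
    res$prognosis <- prog
  }
  invisible(res)
}
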