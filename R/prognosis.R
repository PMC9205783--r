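#' Default liver-related-event composite
#'
#' The ten qualifying clinical outcomes for the composite liver-related
#' event endpoint. The composite is configurable: pass any subset or
#' extension to [compose_lre()].
#' @export
lre_event_types <- c(
  "alcoholic_hepatitis", "varices_needing_treatment", "variceal_bleeding",
  "ascites", "spontaneous_bacterial_peritonitis", "hepatic_encephalopathy",
  "hcc", "hepatorenal_syndrome", "upper_gi_bleeding",
  "jaundice_liver_failure")

#' Compose the liver-related-event endpoint from an event table
#'
#' Per patient: time to the earliest qualifying event (event = TRUE), or the
#' censored follow-up time when no qualifying event occurred.
#'
#' @param meta sample metadata with `followup_months`.
#' @param event_table data frame (sample_id, event_name, time_months); may
#'   list several events per patient.
#' @param composite qualifying event names (default [lre_event_types]).
#' @return data frame: sample_id, time, event.
#' @export
compose_lre <- function(meta, event_table, composite = lre_event_types) {
  if (is.null(meta$followup_months)) stop("metadata lacks followup_months")
  ev <- event_table[event_table$event_name %in% composite, , drop = FALSE]
  fu <- stats::setNames(meta$followup_months, meta$sample_id)
  bad <- ev$time_months > fu[ev$sample_id] + 1e-9
  if (any(bad, na.rm = TRUE))
    stop("event time exceeds follow-up for sample(s): ",
         paste(unique(ev$sample_id[which(bad)]), collapse = ", "))
  first <- tapply(ev$time_months, ev$sample_id, min)
  time <- fu
  event <- rep(FALSE, nrow(meta))
  names(event) <- meta$sample_id
  hit <- names(first)[names(first) %in% meta$sample_id]
  time[hit] <- first[hit]
  event[hit] <- TRUE
  data.frame(sample_id = meta$sample_id, time = unname(time[meta$sample_id]),
             event = unname(event[meta$sample_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs -- pairs where the smaller observed time belongs
#' to an event; pairs with tied times are non-comparable unless exactly one
#' is an event -- the fraction in which the earlier-event patient carries the
#' higher risk, with half credit for tied risks.
#'
#' @param records data frame with columns `risk`, `time`, `event`.
#' @return the C-index, or NA (with warning) when no pair is comparable.
#' @export
harrells_c <- function(records) {
  risk <- records$risk; time <- records$time; event <- as.logical(records$event)
  n <- length(risk)
  conc <- ties <- comp <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (time[i] == time[j]) {
      if (sum(event[c(i, j)]) != 1L) next
      early <- if (event[i]) i else j
    } else {
      early <- if (time[i] < time[j]) i else j
      if (!event[early]) next
    }
    late <- if (early == i) j else i
    comp <- comp + 1
    if (risk[early] > risk[late]) conc <- conc + 1
    else if (risk[early] == risk[late]) ties <- ties + 1
  }
  if (comp == 0) {
    warning("no comparable pairs; C-index undefined")
    return(NA_real_)
  }
  (conc + 0.5 * ties) / comp
}

#' Fixed-horizon ROC-AUC for a survival risk score
#'
#' Cases are patients with an event at or before the horizon; controls are
#' patients observed event-free past the horizon; patients censored before
#' the horizon without an event are excluded. AUC via the Mann-Whitney
#' relation with tie half-credit.
#'
#' @param records data frame with `risk`, `time`, `event`.
#' @param horizon months.
#' @return AUC, or NA (with warning) if either group is empty.
#' @export
horizon_auc <- function(records, horizon) {
  stopifnot(horizon > 0)
  case <- records$event & records$time <= horizon
  control <- records$time > horizon
  keep <- case | control
  if (!any(case) || !any(control)) {
    warning("no cases or no controls at horizon ", horizon, " months")
    return(NA_real_)
  }
  roc_auc(records$risk[keep], as.integer(case[keep]))
}

#' Prognostic evaluation of a frozen diagnostic panel model
#'
#' Scores patients with the diagnostic model's probability (no refitting on
#' outcomes) and reports Harrell's C plus fixed-horizon AUCs.
#'
#' @param model a `panel_model`.
#' @param X samples x proteins matrix (rownames = sample ids).
#' @param records survival records (`sample_id`, `time`, `event`), e.g. from
#'   [compose_lre()].
#' @param horizons months (default 36 and 60).
#' @return list: `c_index`, `horizon_auc` (named by horizon), `records`.
#' @export
prognostic_eval <- function(model, X, records, horizons = c(36, 60)) {
  common <- intersect(rownames(X), records$sample_id)
  if (!length(common)) stop("no overlap between matrix and survival records")
  rec <- records[match(common, records$sample_id), , drop = FALSE]
  rec$risk <- predict(model, X[common, , drop = FALSE])
  aucs <- vapply(horizons, function(h) horizon_auc(rec, h), numeric(1))
  names(aucs) <- paste0("auc_", horizons, "m")
  list(c_index = harrells_c(rec), horizon_auc = aucs, records = rec)
}
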