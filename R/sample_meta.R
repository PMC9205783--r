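#' Sample metadata table
#'
#' Per-sample clinical metadata are kept in an ordinary data frame with one
#' row per sample. Recognised columns:
#' \describe{
#'   \item{sample_id}{unique identifier}
#'   \item{cohort}{`derivation`, `healthy` or `validation`}
#'   \item{age, bmi}{years, kg/m2}
#'   \item{sex}{`male`/`female`}
#'   \item{abstinent}{logical, abstinent from alcohol at inclusion}
#'   \item{kleiner_f}{Kleiner fibrosis stage 0-4 or NA}
#'   \item{lobular}{lobular inflammation 0-3 or NA}
#'   \item{ballooning}{hepatocyte ballooning 0-2 or NA}
#'   \item{steatosis_s}{steatosis grade 0-3 or NA}
#'   \item{activity_i}{inflammatory activity 0-5 (lobular + ballooning), derived}
#'   \item{followup_months, death}{follow-up and all-cause mortality}
#'   \item{lre_time_months, lre_event}{liver-related event time / indicator}
#' }
#' Clinical comparator tests (elastography, blood indices, ...) are extra
#' numeric columns named by test.
#'
#' @param meta a data frame as above.
#' @return the validated data frame (invisibly classed as-is).
#' @export
validate_sample_meta <- function(meta) {
  if (!is.data.frame(meta)) stop("metadata must be a data frame")
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  .check_ordinal(meta, "kleiner_f", 0, 4)
  .check_ordinal(meta, "lobular", 0, 3)
  .check_ordinal(meta, "ballooning", 0, 2)
  .check_ordinal(meta, "steatosis_s", 0, 3)
  .check_ordinal(meta, "activity_i", 0, 5)
  if (all(c("lre_time_months", "followup_months") %in% names(meta))) {
    both <- !is.na(meta$lre_time_months) & !is.na(meta$followup_months)
    if (any(meta$lre_time_months[both] > meta$followup_months[both] + 1e-9))
      stop("lre_time_months exceeds followup_months for some samples")
  }
  invisible(meta)
}

.check_ordinal <- function(meta, field, lo, hi) {
  if (!field %in% names(meta)) return(invisible(NULL))
  v <- meta[[field]]
  bad <- !is.na(v) & (v < lo | v > hi | v != round(v))
  if (any(bad))
    stop(sprintf("%s out of ordinal range %d-%d for sample(s) %s",
                 field, lo, hi,
                 paste(utils::head(meta$sample_id[bad], 3L), collapse = ", ")))
  invisible(NULL)
}

#' Derive the inflammatory activity score
#'
#' The activity score I (0-5) is the sum of lobular inflammation (0-3) and
#' hepatocyte ballooning (0-2); it is missing whenever either component is.
#'
#' @param meta sample metadata data frame with `lobular` and `ballooning`.
#' @return `meta` with `activity_i` filled in.
#' @export
derive_activity_score <- function(meta) {
  .check_ordinal(meta, "lobular", 0, 3)
  .check_ordinal(meta, "ballooning", 0, 2)
  meta$activity_i <- ifelse(!is.na(meta$lobular) & !is.na(meta$ballooning),
                            meta$lobular + meta$ballooning, NA_real_)
  meta
}

# binary histology endpoints: which score and the minimal grade counted a case
.endpoints <- list(
  F2 = list(score_field = "kleiner_f",   threshold = 2L),
  F3 = list(score_field = "kleiner_f",   threshold = 3L),
  I2 = list(score_field = "activity_i",  threshold = 2L),
  S1 = list(score_field = "steatosis_s", threshold = 1L)
)

#' Binary classification endpoints
#'
#' The four histology endpoints: significant fibrosis (`F2`, Kleiner >= 2),
#' advanced fibrosis (`F3`, Kleiner >= 3), mild inflammatory activity (`I2`,
#' activity >= 2) and any steatosis (`S1`, steatosis >= 1).
#'
#' @param name endpoint name.
#' @return list with `name`, `score_field`, `threshold`.
#' @export
endpoint <- function(name = c("F2", "F3", "I2", "S1")) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.endpoints))
    stop("unknown endpoint: ", paste(name, collapse = ","),
         " (expected one of F2, F3, I2, S1)")
  c(list(name = name), .endpoints[[name]])
}

#' Label samples for a binary endpoint
#'
#' @param meta sample metadata.
#' @param ep endpoint name or an [endpoint()] object.
#' @return factor with levels `control`, `case`; `NA` where the relevant
#'   histology score is missing (unlabeled).
#' @export
label_endpoint <- function(meta, ep) {
  if (is.character(ep)) ep <- endpoint(ep)
  score <- meta[[ep$score_field]]
  if (is.null(score)) stop("metadata lacks column ", ep$score_field)
  factor(ifelse(is.na(score), NA_character_,
                ifelse(score >= ep$threshold, "case", "control")),
         levels = c("control", "case"))
}

#' Read / write sample metadata
#'
#' One delimited row per sample; delimiter by extension as for matrices.
#' @param path file path.
#' @export
read_sample_meta <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = .na_tokens, quote = "\"")
  for (f in c("abstinent", "death", "lre_event"))
    if (f %in% names(meta)) meta[[f]] <- as.logical(meta[[f]])
  validate_sample_meta(meta)
  meta
}

#' @rdname read_sample_meta
#' @param meta metadata data frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' Read a protein annotation table
#'
#' Two-column TSV `protein_id <tab> category` with categories from
#' `liver_specific`, `secreted`, `other` (tissue-specificity and secretome
#' classes in the style of the Human Protein Atlas).
#'
#' @param path file path.
#' @return named character vector: category per protein id.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs protein_id and category")
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(dup))
    stop("protein annotated more than once: ", paste(dup, collapse = ", "))
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}
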