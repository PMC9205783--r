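#' Paired liver-plasma protein correlation
#'
#' For each protein quantified in both matrices, Pearson correlation of the
#' paired log2 values across patients (pairs with either value missing are
#' dropped). P-values from the t distribution, Benjamini-Hochberg q over the
#' common-protein set; significant iff q < 0.05 and |r| > 0.3. Proteins with
#' fewer than 3 complete pairs are reported with missing `r`.
#'
#' @param liver,plasma log2 [protein_matrix] objects.
#' @param pairing data frame with columns `liver_sample_id`,
#'   `plasma_sample_id` mapping one-to-one.
#' @return data frame: protein_id, r, p, q, n_pairs, significant.
#' @export
pair_correlation <- function(liver, plasma, pairing) {
  stopifnot(inherits(liver, "protein_matrix"), inherits(plasma, "protein_matrix"))
  if (anyDuplicated(pairing$liver_sample_id) ||
      anyDuplicated(pairing$plasma_sample_id))
    stop("pairing must map liver to plasma samples one-to-one")
  pairing <- pairing[pairing$liver_sample_id %in% sample_ids(liver) &
                     pairing$plasma_sample_id %in% sample_ids(plasma), ,
                     drop = FALSE]
  if (!nrow(pairing)) stop("no usable liver-plasma pairs")
  common <- intersect(protein_ids(liver), protein_ids(plasma))
  L <- liver$values[common, pairing$liver_sample_id, drop = FALSE]
  P <- plasma$values[common, pairing$plasma_sample_id, drop = FALSE]
  n_prot <- length(common)
  r <- p <- rep(NA_real_, n_prot)
  n_pairs <- integer(n_prot)
  for (i in seq_len(n_prot)) {
    ok <- !is.na(L[i, ]) & !is.na(P[i, ])
    n <- sum(ok)
    n_pairs[i] <- n
    if (n < 3L) next
    ri <- stats::cor(L[i, ok], P[i, ok])
    if (is.na(ri)) next
    tt <- ri * sqrt((n - 2) / max(1 - ri^2, .Machine$double.eps))
    r[i] <- ri
    p[i] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  q <- bh_adjust(p)
  data.frame(protein_id = common, r = r, p = p, q = q, n_pairs = n_pairs,
             significant = !is.na(q) & q < 0.05 & abs(r) > 0.3,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Co-dysregulated proteins across liver and plasma
#'
#' Intersection of the significant (q < 0.05) sets of two differential
#' screens computed for the same histology factor, annotated `concordant`
#' when the direction of change agrees between compartments and
#' `discordant` otherwise.
#'
#' @param diff_liver,diff_plasma results of [ancova_stagewise()] on the
#'   liver and plasma matrices for the same factor.
#' @return data frame: protein_id, direction_liver, direction_plasma,
#'   concordance.
#' @export
codysregulated <- function(diff_liver, diff_plasma) {
  if (!identical(unique(diff_liver$factor), unique(diff_plasma$factor)))
    stop("differential results computed for different factors")
  sig_l <- diff_liver[diff_liver$significant, c("protein_id", "direction")]
  sig_p <- diff_plasma[diff_plasma$significant, c("protein_id", "direction")]
  ids <- intersect(sig_l$protein_id, sig_p$protein_id)
  dl <- sig_l$direction[match(ids, sig_l$protein_id)]
  dp <- sig_p$direction[match(ids, sig_p$protein_id)]
  data.frame(protein_id = ids, direction_liver = dl, direction_plasma = dp,
             concordance = ifelse(dl == dp, "concordant", "discordant"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Up/down fractions of significant proteins per annotation category
#'
#' Among the significant proteins of a differential screen, tallies the
#' fraction changing up and down within each annotation category
#' (liver-specific, secreted, other); proteins absent from the annotation
#' table fall into `other`. With no significant proteins in a category the
#' fractions are reported missing.
#'
#' @param diff result of [ancova_stagewise()].
#' @param annotations named character vector from [read_annotation_table()].
#' @return data frame: category, n_significant, frac_up, frac_down.
#' @export
annotation_fractions <- function(diff, annotations) {
  sig <- diff[diff$significant & !is.na(diff$direction), , drop = FALSE]
  cat_of <- function(id) {
    a <- unname(annotations[id])
    ifelse(is.na(a), "other", a)
  }
  cats <- c("liver_specific", "secreted", "other")
  out <- lapply(cats, function(cc) {
    sub <- sig[cat_of(sig$protein_id) == cc, , drop = FALSE]
    n <- nrow(sub)
    data.frame(category = cc, n_significant = n,
               frac_up = if (n) mean(sub$direction > 0) else NA_real_,
               frac_down = if (n) mean(sub$direction < 0) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Median abundance map across compartments
#'
#' Per-protein median log2 intensity in liver and plasma, the tabular
#' reduction of the usual liver/plasma abundance scatter.
#'
#' @param liver,plasma log2 [protein_matrix] objects.
#' @return data frame: protein_id, median_liver, median_plasma.
#' @export
abundance_map <- function(liver, plasma) {
  common <- intersect(protein_ids(liver), protein_ids(plasma))
  data.frame(
    protein_id = common,
    median_liver = apply(liver$values[common, , drop = FALSE], 1L,
                         stats::median, na.rm = TRUE),
    median_plasma = apply(plasma$values[common, , drop = FALSE], 1L,
                          stats::median, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
}
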