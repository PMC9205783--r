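#' Protein quantification matrix
#'
#' A `protein_matrix` holds protein-level MS intensities as a numeric matrix
#' with proteins in rows and samples in columns, together with a scale flag.
#' Missing quantifications are explicit `NA` cells; on the linear scale every
#' present value must be strictly positive (MS intensities cannot be zero or
#' negative), while the log2 scale admits any finite value.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimnames must be set, unique and non-empty.
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `protein_matrix`: a list with elements
#'   `values` (the matrix) and `scale`.
#' @export
protein_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry protein (row) and sample (column) names")
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stop("duplicate protein id(s): ", paste(dup_p, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present; missing cells must be NA")
  if (scale == "linear" && any(values <= 0, na.rm = TRUE))
    stop("linear-scale intensities must be strictly positive")
  structure(list(values = values, scale = scale), class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  v <- x$values
  miss <- mean(is.na(v))
  cat(sprintf("protein_matrix: %d proteins x %d samples (%s scale, %.1f%% missing)\n",
              nrow(v), ncol(v), x$scale, 100 * miss))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' Protein and sample identifiers
#' @param x a `protein_matrix`.
#' @return character vector of identifiers in matrix order.
#' @export
protein_ids <- function(x) rownames(x$values)

#' @rdname protein_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# tokens treated as missing on read (common search-engine export dialects)
.na_tokens <- c("", "NA", "NaN", "Filtered")

#' Read a protein matrix from delimited text
#'
#' Reads a TSV or CSV file (delimiter chosen by extension, `.csv` means comma)
#' with one header line of identifiers. Empty cells and the tokens `NA`,
#' `NaN` and `Filtered` are read as missing. A header comment line
#' `#scale=log2` (or a first header field `log2`) marks an already
#' log-transformed matrix; otherwise intensities are taken as linear.
#'
#' @param path file to read.
#' @param orientation `"proteins_in_rows"` (default) or `"samples_in_rows"`.
#' @return a [protein_matrix].
#' @export
read_protein_matrix <- function(path, orientation = c("proteins_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  scale <- "linear"
  skip <- 0L
  if (grepl("^#\\s*scale\\s*=\\s*log2", first)) {
    scale <- "log2"
    skip <- 1L
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, skip = skip,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifier(s) in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                 dimnames = list(ids, colnames(raw)))
  is_na <- raw %in% .na_tokens | is.na(raw)
  dim(is_na) <- dim(raw)
  num <- suppressWarnings(as.numeric(raw))
  bad <- !is_na & is.na(num)
  dim(num) <- dim(raw)
  dim(bad) <- dim(raw)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                 ids[idx[1L]], colnames(raw)[idx[2L]], raw[idx[1L], idx[2L]]))
  }
  vals[!is_na] <- num[!is_na]
  if (orientation == "samples_in_rows") vals <- t(vals)
  if (scale == "linear" && any(vals <= 0, na.rm = TRUE)) {
    idx <- which(vals <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive linear intensity at row '%s', column '%s'",
                 rownames(vals)[idx[1L]], colnames(vals)[idx[2L]]))
  }
  protein_matrix(vals, scale = scale)
}

#' Write a protein matrix as TSV
#'
#' Proteins in rows, samples in columns, missing cells written empty, values
#' at full precision (round-trips bit-for-bit through
#' [read_protein_matrix()]). A log2 matrix is marked with a leading
#' `#scale=log2` comment line.
#'
#' @param x a [protein_matrix].
#' @param path output file.
#' @export
write_protein_matrix <- function(x, path) {
  stopifnot(inherits(x, "protein_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  if (x$scale == "log2") writeLines("#scale=log2", con)
  v <- x$values
  writeLines(paste(c("protein_id", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1L, function(row) {
    cells <- ifelse(is.na(row), "", format(row, digits = 17, trim = TRUE,
                                           scientific = FALSE))
    paste(cells, collapse = "\t")
  })
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(NULL)
}

#' Interconvert linear and log2 intensity scales
#'
#' @param x a [protein_matrix].
#' @return the matrix on the other scale; the missingness mask is unchanged.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "protein_matrix"))
  if (x$scale == "log2")
    stop("matrix is already log2 scale (double-transform guard)")
  protein_matrix(log2(x$values), scale = "log2")
}

#' @rdname log2_transform
#' @export
delog2_transform <- function(x) {
  stopifnot(inherits(x, "protein_matrix"))
  if (x$scale == "linear") stop("matrix is already linear scale")
  protein_matrix(2^x$values, scale = "linear")
}
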