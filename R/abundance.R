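#' Construct an abundance matrix
#'
#' The central data container: a numeric features x samples matrix with
#' unique feature and sample identifiers and an explicit data-scale tag.
#' All model fitting in this package operates on `relative`, `log` or
#' `presence` data; `raw` marks freshly read tables that have not yet been
#' normalized.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param scale One of `"raw"`, `"relative"`, `"log"`, `"presence"`.
#'   `relative` requires every column to sum to 1 (tolerance 1e-6) with
#'   non-negative entries; `presence` requires entries in \{0, 1\}.
#' @return An object of class `btr_abundance` with fields `values` and
#'   `scale`.
#' @export
abundance_matrix <- function(values, scale = c("raw", "relative", "log", "presence")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    btr_validation_error("'values' must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    btr_validation_error("abundance matrix needs rownames (features) and colnames (samples)")
  if (anyNA(values))
    btr_validation_error("abundance matrix contains missing values")
  if (anyDuplicated(rownames(values)))
    btr_validation_error(sprintf("duplicated feature id(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  if (anyDuplicated(colnames(values)))
    btr_validation_error(sprintf("duplicated sample id(s): %s",
      paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")))
  if (scale == "relative") {
    if (any(values < 0))
      btr_validation_error("relative-scale matrix has negative entries")
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-6))
      btr_validation_error("relative-scale matrix has column sums different from 1")
  }
  if (scale == "presence" && !all(values %in% c(0, 1)))
    btr_validation_error("presence-scale matrix must contain only 0/1 entries")
  structure(list(values = values, scale = scale), class = "btr_abundance")
}

#' @method print btr_abundance
#' @export
print.btr_abundance <- function(x, ...) {
  cat(sprintf("<btr_abundance> %d features x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname abundance_matrix
#' @param m A `btr_abundance` object.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname abundance_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

n_features <- function(m) nrow(m$values)
n_samples  <- function(m) ncol(m$values)

# internal constructor that skips the closure check: feature-subset views of
# relative data keep their parent scale (scores stay relative to the original
# sample total), even though their columns no longer sum to 1
new_abundance <- function(values, scale) {
  structure(list(values = values, scale = scale), class = "btr_abundance")
}

subset_samples <- function(m, idx) {
  new_abundance(m$values[, idx, drop = FALSE], scale = m$scale)
}

subset_features <- function(m, keep) {
  new_abundance(m$values[keep, , drop = FALSE], scale = m$scale)
}

#' Read a delimited abundance table
#'
#' Reads a TSV/CSV table with one header row of sample ids and one identifier
#' column. By metagenomic convention features are in rows; set
#' `features_in_rows = FALSE` for samples-in-rows tables.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, default tab.
#' @param features_in_rows Orientation flag, default `TRUE`.
#' @return A `btr_abundance` with `scale = "raw"`.
#' @export
read_abundance_table <- function(path, delimiter = "\t", features_in_rows = TRUE) {
  if (!file.exists(path)) btr_validation_error(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = delimiter, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) btr_parse_error("table needs an identifier column plus at least one data column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    btr_validation_error(sprintf("duplicated identifier(s) in first column: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  cols <- colnames(raw)[-1]
  num <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw), dimnames = list(ids, cols))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    btr_parse_error(sprintf("non-numeric value at row '%s', column '%s'",
                            ids[bad[1]], cols[bad[2]]))
  }
  if (!features_in_rows) num <- t(num)
  abundance_matrix(num, scale = "raw")
}

#' Write an abundance table as TSV
#'
#' Values are formatted with `%.10g`, so repeated writes of the same matrix
#' are byte-identical.
#'
#' @param m A `btr_abundance`.
#' @param path Output file path.
#' @export
write_abundance_table <- function(m, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", sample_ids(m)), collapse = "\t"), con)
  rows <- vapply(seq_len(n_features(m)), function(i) {
    paste(c(feature_ids(m)[i], sprintf("%.10g", m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Normalize a table to relative abundances
#'
#' Closes each sample (column) to sum 1, the compositional scale on which
#' ratio models are scale-invariant.
#'
#' @param m A `btr_abundance` with non-negative entries.
#' @return A `btr_abundance` with `scale = "relative"`.
#' @export
normalize_relative <- function(m) {
  if (any(m$values < 0)) btr_domain_error("negative entries cannot be normalized to relative abundances")
  cs <- colSums(m$values)
  if (any(cs == 0))
    btr_degenerate_error(sprintf("all-zero sample(s): %s",
      paste(sample_ids(m)[cs == 0], collapse = ", ")))
  abundance_matrix(sweep(m$values, 2, cs, "/"), scale = "relative")
}

#' Transform abundances to presence/absence
#'
#' Any strictly positive entry becomes 1. Idempotent; all-zero features are
#' retained (filtering is a separate step).
#'
#' @param m A `btr_abundance` with non-negative entries.
#' @return A `btr_abundance` with `scale = "presence"`.
#' @export
to_presence <- function(m) {
  if (any(m$values < 0)) btr_domain_error("presence transform requires non-negative entries")
  abundance_matrix((m$values > 0) * 1, scale = "presence")
}

#' Log-transform abundances
#'
#' Entry-wise `log(x + pseudocount)`. The default pseudocount 1e-6 is on the
#' order of the smallest nonzero relative abundances in shotgun profiles.
#' Ternary models fitted on the result are the TerLog configuration.
#'
#' @param m A `btr_abundance` on raw or relative scale.
#' @param pseudocount Positive offset added before taking logs.
#' @return A `btr_abundance` with `scale = "log"`.
#' @export
log_transform <- function(m, pseudocount = 1e-6) {
  if (!m$scale %in% c("raw", "relative"))
    btr_domain_error("log transform applies to raw or relative data")
  if (pseudocount <= 0 && any(m$values == 0))
    btr_domain_error("pseudocount must be > 0 when zeros are present")
  abundance_matrix(log(m$values + pseudocount), scale = "log")
}

#' Filter low-variability features at the SD elbow
#'
#' Computes each feature's standard deviation, sorts the SDs, and places the
#' cutoff at the point of maximum discrete (central) second difference of the
#' sorted-SD curve -- the elbow of the SD distribution. Features with SD at or
#' below the elbow value are removed; SD = 0 features are always removed.
#' A flat curve (maximum second difference 0) triggers no elbow filtering.
#' Ties in the maximum second difference resolve to the smallest SD value, so
#' the filter is conservative.
#'
#' @param m A `btr_abundance` with at least 3 features.
#' @return A list with elements `matrix` (the filtered `btr_abundance`) and
#'   `removed` (character vector of removed feature ids).
#' @export
filter_low_sd <- function(m) {
  p <- n_features(m)
  if (p < 3) btr_validation_error("SD filtering needs at least 3 features")
  sds <- apply(m$values, 1, stats::sd)
  if (all(sds == 0)) btr_degenerate_error("no informative features: all features are constant")
  ord <- order(sds)
  s <- sds[ord]
  # central second differences on the sorted curve (rank index as abscissa)
  d2 <- s[-(1:2)] - 2 * s[-c(1, length(s))] + s[-((length(s) - 1):length(s))]
  cutoff <- -Inf
  if (max(d2) > 1e-12 * max(s)) {
    elbow <- which.max(d2) + 1L            # index into the sorted curve
    cutoff <- s[elbow]
  }
  remove <- sds <= cutoff | sds == 0
  if (all(remove)) {
    # elbow at the top of the curve would discard everything; fall back to
    # dropping only constant features
    remove <- sds == 0
  }
  list(matrix = subset_features(m, !remove),
       removed = feature_ids(m)[remove])
}
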