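#' Construct a sample target
#'
#' Wraps the variable to predict: a 2-level class label (classification) or a
#' real-valued outcome (regression), aligned to the samples of an abundance
#' matrix.
#'
#' @param values Class labels (character/factor, exactly 2 levels) or a
#'   numeric vector.
#' @param sample_ids Sample identifiers aligned with `values`.
#' @param kind `"binary_class"`, `"continuous"`, or `"auto"` (numeric with
#'   more than 2 distinct values is treated as continuous).
#' @param positive_class For binary targets, the label mapped to the
#'   score-high side of the decision rule. Defaults to the lexicographically
#'   larger label; the comparison direction is learned during threshold
#'   fitting, so this is a labeling convention, not an assumption.
#' @return An object of class `btr_target`.
#' @export
sample_target <- function(values, sample_ids,
                          kind = c("auto", "binary_class", "continuous"),
                          positive_class = NULL) {
  kind <- match.arg(kind)
  if (length(values) != length(sample_ids))
    btr_validation_error("'values' and 'sample_ids' lengths differ")
  if (anyDuplicated(sample_ids))
    btr_validation_error("duplicated sample ids in target")
  if (anyNA(values)) btr_validation_error("target contains missing values")
  if (is.factor(values)) values <- as.character(values)
  if (kind == "auto") {
    kind <- if (is.numeric(values) && length(unique(values)) > 2) "continuous" else "binary_class"
  }
  if (kind == "binary_class") {
    values <- as.character(values)
    lev <- sort(unique(values))
    if (length(lev) != 2)
      btr_validation_error(sprintf("binary target needs exactly 2 distinct labels, found %d", length(lev)))
    if (is.null(positive_class)) positive_class <- lev[2]
    if (!positive_class %in% lev)
      btr_validation_error(sprintf("positive_class '%s' is not an observed label", positive_class))
  } else {
    if (!is.numeric(values)) btr_validation_error("continuous target must be numeric")
    positive_class <- NULL
  }
  names(values) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), kind = kind,
                 values = values, positive_class = positive_class),
            class = "btr_target")
}

#' @method print btr_target
#' @export
print.btr_target <- function(x, ...) {
  if (x$kind == "binary_class") {
    tab <- table(x$values)
    cat(sprintf("<btr_target> binary_class, n = %d (%s), positive_class = %s\n",
                length(x$values),
                paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
                x$positive_class))
  } else {
    cat(sprintf("<btr_target> continuous, n = %d, range [%.3g, %.3g]\n",
                length(x$values), min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Read a sample metadata table with a target column
#'
#' Expects a delimited file with columns `sample_id` and `target` (or names
#' given by `id_col` / `target_col`).
#'
#' @param path Path to the metadata file.
#' @param delimiter Field separator, default tab.
#' @param id_col,target_col Column names holding sample ids and the target.
#' @inheritParams sample_target
#' @return A `btr_target`.
#' @export
read_sample_target <- function(path, delimiter = "\t",
                               id_col = "sample_id", target_col = "target",
                               kind = "auto", positive_class = NULL) {
  if (!file.exists(path)) btr_validation_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (cl in c(id_col, target_col)) {
    if (!cl %in% colnames(df))
      btr_config_error(sprintf("metadata file lacks column '%s'", cl))
  }
  sample_target(df[[target_col]], df[[id_col]], kind = kind,
                positive_class = positive_class)
}

subset_target <- function(y, idx) {
  v <- y$values[idx]
  structure(list(sample_ids = y$sample_ids[idx], kind = y$kind, values = v,
                 positive_class = y$positive_class), class = "btr_target")
}

# logical vector: TRUE = positive class
positive_mask <- function(y) {
  if (y$kind != "binary_class") btr_validation_error("binary_class target required")
  y$values == y$positive_class
}

# align a target to the sample order of an abundance matrix
align_target <- function(y, m) {
  idx <- match(sample_ids(m), y$sample_ids)
  if (anyNA(idx))
    btr_validation_error("target is missing samples present in the abundance matrix")
  subset_target(y, idx)
}
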