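#' Signed feature incidence table of an FBM
#'
#' One row per FBM model, one column per feature appearing in at least one
#' model; entries are the model coefficients (+1/-1; for ratio models +1
#' marks the numerator and -1 the denominator side) and 0 for features a
#' model does not use.
#'
#' @param fbm A `btr_fbm`.
#' @return A numeric matrix (models x features).
#' @export
model_feature_table <- function(fbm) {
  if (!inherits(fbm, "btr_fbm") || length(fbm$models) == 0)
    btr_validation_error("non-empty FBM required")
  features <- sort(unique(unlist(lapply(fbm$models, `[[`, "features"))))
  tab <- matrix(0, nrow = length(fbm$models), ncol = length(features),
                dimnames = list(sprintf("model_%03d", seq_along(fbm$models)),
                                features))
  for (i in seq_along(fbm$models)) {
    mod <- fbm$models[[i]]
    tab[i, mod$features] <- mod$coefficients
  }
  tab
}

#' Prevalence and class-wise statistics of features
#'
#' For each feature: prevalence (fraction of samples with abundance > 0)
#' overall and per class, the two-sided Mann-Whitney p-value of the
#' abundance shift between classes, and the enrichment direction (class
#' with the greater mean rank).
#'
#' @param m A `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param features Feature names (default: all features of `m`).
#' @return Data frame with columns `feature`, `prevalence`,
#'   `prevalence_positive`, `prevalence_negative`, `p_value`, `direction`.
#' @export
feature_class_stats <- function(m, y, features = feature_ids(m)) {
  y <- align_target(y, m)
  missing <- setdiff(features, feature_ids(m))
  if (length(missing))
    btr_validation_error(sprintf("feature(s) absent from matrix: %s",
                                 paste(missing, collapse = ", ")))
  pos <- positive_mask(y)
  sub <- subset_features(m, match(features, feature_ids(m)))
  rk <- mann_whitney_rank(sub, y)
  rk <- rk[match(features, rk$feature), ]
  x <- sub$values
  data.frame(feature = features,
             prevalence = rowMeans(x > 0),
             prevalence_positive = rowMeans(x[, pos, drop = FALSE] > 0),
             prevalence_negative = rowMeans(x[, !pos, drop = FALSE] > 0),
             p_value = rk$p_value,
             direction = rk$direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# phi coefficient of two binary vectors
phi_coef <- function(a, b) {
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  den <- sqrt(as.numeric(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

#' Feature co-occurrence network over the FBM
#'
#' Measures, for every pair of features used by the FBM, the phi coefficient
#' of their co-presence across FBM models: positive weights mark features
#' that appear in models together (complementarity), negative weights mark
#' features that replace one another (redundancy). Only the `top_fraction`
#' strongest edges by absolute weight are retained (ties broken by the name
#' pair), so growing `top_fraction` only ever adds edges. Features present
#' in every model or in none (constant incidence columns) carry no
#' association information and are excluded with a warning.
#'
#' @param fbm A `btr_fbm` with at least 2 models and 2 features.
#' @param top_fraction Fraction of candidate edges to keep (default 0.05).
#' @return Data frame with columns `source`, `target`, `weight`, `sign`.
#' @export
cooccurrence_network <- function(fbm, top_fraction = 0.05) {
  tab <- model_feature_table(fbm) != 0
  if (nrow(tab) < 2 || ncol(tab) < 2)
    btr_validation_error("co-occurrence needs >= 2 models and >= 2 features")
  const <- colSums(tab) %in% c(0L, nrow(tab))
  if (any(const)) {
    warning(sprintf("excluding constant incidence column(s): %s",
                    paste(colnames(tab)[const], collapse = ", ")))
    tab <- tab[, !const, drop = FALSE]
  }
  feats <- colnames(tab)
  if (length(feats) < 2) btr_validation_error("fewer than 2 informative features")
  pairs <- utils::combn(feats, 2)
  w <- vapply(seq_len(ncol(pairs)), function(i)
    phi_coef(tab[, pairs[1, i]], tab[, pairs[2, i]]), numeric(1))
  edges <- data.frame(source = pairs[1, ], target = pairs[2, ], weight = w,
                      sign = ifelse(w >= 0, "co_presence", "mutual_exclusion"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$weight), edges$source, edges$target), ,
                 drop = FALSE]
  n_keep <- max(1L, floor(top_fraction * nrow(edges) + 1e-9))
  edges <- edges[seq_len(min(n_keep, nrow(edges))), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Data correlation versus model co-presence for feature pairs
#'
#' For each feature pair of the FBM incidence table, returns the Pearson
#' correlation of the two features' abundances across samples together with
#' the phi coefficient of their co-presence across FBM models. Redundant
#' (inter-replaceable) features show up as highly correlated in the data but
#' mutually exclusive in the models. No thresholding is applied.
#'
#' @param m A `btr_abundance` containing all FBM features.
#' @param fbm A `btr_fbm`.
#' @param pairs Optional 2-column character matrix or data frame of feature
#'   pairs (defaults to all pairs of the incidence table).
#' @return Data frame with columns `feature_a`, `feature_b`,
#'   `data_correlation`, `model_correlation`.
#' @export
data_vs_model_correlation <- function(m, fbm, pairs = NULL) {
  tab <- model_feature_table(fbm) != 0
  feats <- colnames(tab)
  if (is.null(pairs)) {
    if (length(feats) < 2) btr_validation_error("fewer than 2 FBM features")
    pairs <- t(utils::combn(feats, 2))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  for (f in unique(as.vector(pairs))) {
    if (!f %in% feature_ids(m))
      btr_validation_error(sprintf("feature '%s' absent from the data", f))
    if (!f %in% feats)
      btr_validation_error(sprintf("feature '%s' absent from the FBM", f))
  }
  data.frame(
    feature_a = pairs[, 1], feature_b = pairs[, 2],
    data_correlation = vapply(seq_len(nrow(pairs)), function(i)
      stats::cor(m$values[pairs[i, 1], ], m$values[pairs[i, 2], ]), numeric(1)),
    model_correlation = vapply(seq_len(nrow(pairs)), function(i)
      phi_coef(tab[, pairs[i, 1]], tab[, pairs[i, 2]]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Write network edge and node tables as TSV
#'
#' @param edges Edge data frame from [cooccurrence_network()].
#' @param path Output path.
#' @export
write_edges_tsv <- function(edges, path) {
  df <- edges
  df$weight <- sprintf("%.10g", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
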