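#' Exhaustively enumerate BTR models up to a size limit
#'
#' Enumerates every feature subset of size `k_min..k_max` and every
#' admissible sign/side assignment in canonical form (the first selected
#' feature carries a positive coefficient: a ternary rule and its global
#' sign flip, or a ratio and its numerator/denominator swap, describe the
#' same decision family once the threshold and direction are refitted), fits
#' all thresholds and returns the complete ranked population. Intended as a
#' ground-truth oracle for small problems; a guard bound refuses runs whose
#' model count would be excessive.
#'
#' @param m A `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param language Model language.
#' @param k_max Maximum model size.
#' @param k_min Minimum model size (default 1).
#' @param metric Fitness metric (default `"accuracy"`).
#' @param guard Maximum number of models that will be evaluated
#'   (default 2e6).
#' @return A `btr_population` containing every canonical model.
#' @export
exhaustive_search <- function(m, y, language, k_max, k_min = 1L,
                              metric = "accuracy", guard = 2e6) {
  language <- match.arg(language, c("bin", "ter", "ratio", "terlog"))
  m <- prepare_search_data(m, language)
  y <- align_target(y, m)
  p <- n_features(m)
  if (k_max > p) btr_config_error("k_max exceeds the number of features")
  total <- exhaustive_count(p, k_min, k_max, language)
  if (total > guard)
    btr_config_error(sprintf(
      "exhaustive enumeration would evaluate %.0f models (guard bound %.0f)",
      total, guard))
  ypos <- positive_mask(y)
  X <- m$values
  models <- vector("list", total)
  pos <- 0L
  for (k in k_min:k_max) {
    combos <- utils::combn(p, k)
    signs <- canonical_signs(k, language)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      for (si in seq_len(ncol(signs))) {
        pos <- pos + 1L
        models[[pos]] <- eval_ind(X, ypos, idx, signs[, si], language, metric)
      }
    }
  }
  models <- lapply(models, ind_to_model, language = language,
                   feat_names = feature_ids(m), data_scale = m$scale,
                   class_map = class_map_of(y), metric = metric,
                   n = length(ypos))
  new_population(models, language, m$scale, 0L,
                 data.frame(k = integer(), generation = integer(),
                            best_fitness = numeric()))
}

# canonical sign patterns: first coefficient fixed at +1
canonical_signs <- function(k, language) {
  if (language == "bin") return(matrix(1, nrow = k, ncol = 1))
  if (k == 1L) return(matrix(1, nrow = 1, ncol = 1))
  rest <- as.matrix(expand.grid(rep(list(c(1, -1)), k - 1L)))
  rbind(rep(1, 2^(k - 1L)), t(rest))
}

# closed-form count of canonical models
exhaustive_count <- function(p, k_min, k_max, language) {
  ks <- k_min:k_max
  per_k <- if (language == "bin") rep(1, length(ks)) else 2^(ks - 1)
  sum(choose(p, ks) * per_k)
}
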