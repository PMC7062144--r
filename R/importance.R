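#' Permutation feature importance (mean decrease accuracy) over the FBM
#'
#' For every cross-validation fold, and for every feature appearing in at
#' least one model of that fold's family of best models, the feature's
#' values are permuted across the fold's held-out samples (other features
#' intact), every FBM model's held-out error (1 - accuracy) is recomputed,
#' and the error increase is averaged over all FBM models (models not using
#' the feature contribute an exactly zero difference) and over
#' `n_permutations` permutation draws. The mean decrease accuracy of a
#' feature is the mean of these per-fold values, reported with the standard
#' error of the mean across folds. Features absent from every FBM model
#' have MDA exactly 0 and are omitted from the table. Deterministic given
#' `seed`.
#'
#' @param fbm_per_fold List of `btr_fbm`, one per fold.
#' @param held_out_per_fold List (same length) of `list(m =, y =)` with each
#'   fold's held-out abundance matrix and binary target.
#' @param n_permutations Permutation draws per fold (default 10).
#' @param seed Integer seed.
#' @return A data frame of class `btr_importance` with columns `feature`,
#'   `mda`, `sem`, `direction` (+1 = enriched in the positive class, from
#'   Mann-Whitney mean ranks over the pooled held-out data), sorted by
#'   decreasing MDA.
#' @export
compute_mda <- function(fbm_per_fold, held_out_per_fold, n_permutations = 10,
                        seed = 42) {
  if (length(fbm_per_fold) == 0) btr_validation_error("empty FBM list")
  if (length(fbm_per_fold) != length(held_out_per_fold))
    btr_validation_error("one held-out set per FBM is required")
  if (any(vapply(fbm_per_fold, function(f) length(f$models) == 0, logical(1))))
    btr_validation_error("empty FBM")
  if (n_permutations < 1) btr_config_error("n_permutations must be >= 1")
  set.seed(seed)

  features <- sort(unique(unlist(lapply(fbm_per_fold, function(f)
    unlist(lapply(f$models, `[[`, "features"))))))
  n_folds <- length(fbm_per_fold)
  per_fold <- matrix(NA_real_, nrow = length(features), ncol = n_folds,
                     dimnames = list(features, NULL))

  for (f in seq_len(n_folds)) {
    fbm <- fbm_per_fold[[f]]
    m_te <- held_out_per_fold[[f]]$m
    y_te <- align_target(held_out_per_fold[[f]]$y, m_te)
    n_te <- n_samples(m_te)
    n_models <- length(fbm$models)
    err_before <- vapply(fbm$models, function(mod)
      1 - compute_metric(y_te, predict(mod, m_te), "accuracy"), numeric(1))
    acc <- matrix(0, nrow = length(features), ncol = 1)
    for (perm in seq_len(n_permutations)) {
      pidx <- sample.int(n_te)
      for (j in seq_along(features)) {
        feat <- features[j]
        using <- which(vapply(fbm$models, function(mod) feat %in% mod$features,
                              logical(1)))
        if (length(using) == 0) next
        m_perm <- m_te
        m_perm$values[feat, ] <- m_te$values[feat, pidx]
        diffs <- vapply(using, function(mi) {
          ea <- 1 - compute_metric(y_te, predict(fbm$models[[mi]], m_perm),
                                   "accuracy")
          ea - err_before[mi]
        }, numeric(1))
        # models not using the feature contribute exactly 0
        acc[j] <- acc[j] + sum(diffs) / n_models
      }
    }
    per_fold[, f] <- acc / n_permutations
  }

  mda <- rowMeans(per_fold)
  sem <- apply(per_fold, 1, stats::sd) / sqrt(n_folds)
  direction <- feature_direction(features, held_out_per_fold)
  out <- data.frame(feature = features, mda = unname(mda), sem = unname(sem),
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(-out$mda, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("btr_importance", "data.frame")
  out
}

# class-enrichment tag from the pooled held-out data (+1 = positive class)
feature_direction <- function(features, held_out_per_fold) {
  vals <- lapply(held_out_per_fold, function(h) {
    y <- align_target(h$y, h$m)
    list(x = h$m$values[features, , drop = FALSE], pos = positive_mask(y))
  })
  x <- do.call(cbind, lapply(vals, `[[`, "x"))
  pos <- unlist(lapply(vals, `[[`, "pos"))
  if (!any(pos) || all(pos)) return(rep(NA_integer_, length(features)))
  vapply(seq_along(features), function(j) {
    r <- rank(x[j, ])
    if (mean(r[pos]) >= mean(r[!pos])) 1L else -1L
  }, integer(1))
}

#' MDA from a cross-validated BTR run
#'
#' Convenience wrapper assembling the per-fold FBMs and held-out sets stored
#' by [cross_validate()] with a [learner_btr()] and calling [compute_mda()].
#'
#' @param cv A `btr_cv` produced with a BTR learner.
#' @param m,y The full data the CV was run on.
#' @inheritParams compute_mda
#' @return A `btr_importance` data frame.
#' @export
mda_from_cv <- function(cv, m, y, n_permutations = 10, seed = 42) {
  has_fbm <- vapply(cv$fits, function(f) !is.null(f$fbm), logical(1))
  if (!any(has_fbm))
    btr_validation_error("CV result stores no FBMs (was it run with learner_btr?)")
  fbms <- lapply(cv$fits[has_fbm], `[[`, "fbm")
  scale_needed <- fbms[[1]]$models[[1]]$data_scale
  m_use <- if (scale_needed == "log" && m$scale != "log") log_transform(m) else m
  held <- lapply(cv$fits[has_fbm], function(f)
    list(m = subset_samples(m_use, f$test_idx), y = y))
  compute_mda(fbms, held, n_permutations = n_permutations, seed = seed)
}

#' Write a feature-importance table as TSV
#'
#' @param imp A `btr_importance`.
#' @param path Output path.
#' @export
write_importance_tsv <- function(imp, path) {
  df <- data.frame(feature = imp$feature, mda = sprintf("%.10g", imp$mda),
                   sem = sprintf("%.10g", imp$sem), direction = imp$direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
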