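# Learner adapters share a minimal contract: list(name, fit(m, y) -> fitted,
# predict(fitted, m) -> list(labels, scores)) with class "btr_learner".
# Scores are oriented so that higher values favor the positive class. Only
# the adapter contract is part of this package; the comparator
# implementations come from glmnet, randomForest and e1071.

new_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "btr_learner")
}

# Mann-Whitney pre-selection used by the RF/SVM comparators
mw_top_features <- function(m, y, k_top) {
  rk <- mann_whitney_rank(m, y)
  rk$feature[seq_len(min(k_top, nrow(rk)))]
}

# shared guard: comparators work on relative abundances as well
prepare_comparator_data <- function(m) {
  if (m$scale == "raw") normalize_relative(m) else m
}

# Third-party learners cannot use zero-variance predictors (glmnet refuses
# them, tree learners cannot split): a training fold with no variable
# feature falls back to the majority-class rule.
zero_variance_fold <- function(m) {
  all(m$values == m$values[, 1])
}

majority_fit <- function(y) {
  tab <- table(y$values)
  list(fallback = names(tab)[which.max(tab)])
}

fallback_predict <- function(fitted, m) {
  list(labels = rep(fitted$fallback, n_samples(m)),
       scores = rep(0, n_samples(m)))
}

#' BTR learner adapter
#'
#' Wraps the full BTR pipeline -- optional SD-elbow feature filtering,
#' genetic search per model size, penalized best-model choice and FBM
#' extraction -- behind the fit/predict contract of [cross_validate()], so
#' every data-dependent step is re-learned inside each training fold.
#'
#' @param cfg A [search_config()].
#' @param lambda Model-size penalty for the final choice (default 0.01).
#' @param sd_filter Apply [filter_low_sd()] on the training fold (ignored
#'   when the fold has no informative features).
#' @param p_level FBM equivalence level.
#' @return A `btr_learner`.
#' @export
learner_btr <- function(cfg = search_config(), lambda = 0.01,
                        sd_filter = TRUE, p_level = 0.05) {
  new_learner(
    name = sprintf("btr_%s", cfg$language),
    fit = function(m, y) {
      if (m$scale == "raw") m <- normalize_relative(m)
      if (sd_filter && n_features(m) >= 3) {
        flt <- tryCatch(filter_low_sd(m), btr_degenerate_error = function(e) NULL)
        if (!is.null(flt) && n_features(flt$matrix) >= cfg$k_max) m <- flt$matrix
      }
      pop <- evolve(m, y, cfg)
      best <- penalized_select(pop, lambda)
      fbm <- extract_fbm(pop, n_train = n_samples(m), p_level = p_level)
      list(model = best, fbm = fbm, pop = pop)
    },
    predict = function(fitted, m) {
      if (m$scale == "raw") m <- normalize_relative(m)
      if (fitted$model$data_scale == "log" && m$scale != "log") m <- log_transform(m)
      list(labels = predict(fitted$model, m),
           scores = predict(fitted$model, m, type = "score"))
    })
}

#' Elastic-net comparator (glmnet, mixing alpha = 0.5)
#'
#' Logistic regression with elastic-net regularization. With `k_top` set,
#' the model is taken at the point of the regularization path where at most
#' `k_top` features have entered (the embedded feature-selection analogue of
#' the BTR sparsity constraint); otherwise the penalty is chosen by internal
#' cross-validation.
#'
#' @param k_top Optional sparsity budget along the regularization path.
#' @param alpha Elastic-net mixing parameter (0.5: between ridge and lasso).
#' @return A `btr_learner`.
#' @export
learner_enet <- function(k_top = NULL, alpha = 0.5) {
  new_learner(
    name = "enet",
    fit = function(m, y) {
      m <- prepare_comparator_data(m)
      if (zero_variance_fold(m)) return(majority_fit(y))
      ypos <- positive_mask(y)
      x <- t(m$values)
      fit <- glmnet::glmnet(x, factor(ypos), family = "binomial", alpha = alpha)
      s <- if (!is.null(k_top)) {
        df <- fit$df
        cand <- which(df <= k_top)
        fit$lambda[if (length(cand)) max(cand) else 1L]
      } else {
        cvfit <- glmnet::cv.glmnet(x, factor(ypos), family = "binomial",
                                   alpha = alpha, nfolds = 5)
        cvfit$lambda.min
      }
      list(fit = fit, s = s, positive = y$positive_class,
           negative = setdiff(sort(unique(y$values)), y$positive_class))
    },
    predict = function(fitted, m) {
      if (!is.null(fitted$fallback)) return(fallback_predict(fitted, m))
      m <- prepare_comparator_data(m)
      pr <- as.numeric(stats::predict(fitted$fit, t(m$values), s = fitted$s,
                                      type = "response"))
      list(labels = ifelse(pr > 0.5, fitted$positive, fitted$negative),
           scores = pr)
    })
}

#' Random-forest comparator (500 trees)
#'
#' Optionally pre-selects the `k_top` features most associated with the
#' class by Mann-Whitney ranking on the training fold (random forests have
#' no sparsity constraint of their own).
#'
#' @param k_top Optional number of pre-selected features.
#' @param ntree Number of trees (default 500).
#' @return A `btr_learner`.
#' @export
learner_rf <- function(k_top = NULL, ntree = 500) {
  new_learner(
    name = "rf",
    fit = function(m, y) {
      m <- prepare_comparator_data(m)
      if (zero_variance_fold(m)) return(majority_fit(y))
      feats <- if (is.null(k_top)) feature_ids(m) else mw_top_features(m, y, k_top)
      ypos <- positive_mask(y)
      fit <- randomForest::randomForest(
        x = t(m$values[feats, , drop = FALSE]),
        y = factor(ifelse(ypos, "pos", "neg"), levels = c("neg", "pos")),
        ntree = ntree)
      list(fit = fit, feats = feats, positive = y$positive_class,
           negative = setdiff(sort(unique(y$values)), y$positive_class))
    },
    predict = function(fitted, m) {
      if (!is.null(fitted$fallback)) return(fallback_predict(fitted, m))
      m <- prepare_comparator_data(m)
      x <- t(m$values[fitted$feats, , drop = FALSE])
      pr <- stats::predict(fitted$fit, x, type = "prob")[, "pos"]
      list(labels = ifelse(pr > 0.5, fitted$positive, fitted$negative),
           scores = as.numeric(pr))
    })
}

#' Linear-kernel SVM comparator (e1071)
#'
#' @inheritParams learner_rf
#' @param cost SVM cost parameter.
#' @return A `btr_learner`.
#' @export
learner_svm <- function(k_top = NULL, cost = 1) {
  new_learner(
    name = "svm_linear",
    fit = function(m, y) {
      m <- prepare_comparator_data(m)
      if (zero_variance_fold(m)) return(majority_fit(y))
      feats <- if (is.null(k_top)) feature_ids(m) else mw_top_features(m, y, k_top)
      ypos <- positive_mask(y)
      fit <- e1071::svm(x = t(m$values[feats, , drop = FALSE]),
                        y = factor(ifelse(ypos, "pos", "neg"), levels = c("neg", "pos")),
                        kernel = "linear", cost = cost, scale = FALSE)
      list(fit = fit, feats = feats, positive = y$positive_class,
           negative = setdiff(sort(unique(y$values)), y$positive_class))
    },
    predict = function(fitted, m) {
      if (!is.null(fitted$fallback)) return(fallback_predict(fitted, m))
      m <- prepare_comparator_data(m)
      x <- t(m$values[fitted$feats, , drop = FALSE])
      pred <- stats::predict(fitted$fit, x, decision.values = TRUE)
      dec <- attr(pred, "decision.values")
      d <- dec[, 1]
      if (startsWith(colnames(dec)[1], "neg/")) d <- -d  # orient toward "pos"
      list(labels = ifelse(as.character(pred) == "pos", fitted$positive,
                           fitted$negative),
           scores = unname(d))
    })
}

#' Majority-class baseline learner
#'
#' Always predicts the most frequent training label: the chance floor any
#' useful model must beat.
#'
#' @return A `btr_learner`.
#' @export
learner_majority <- function() {
  new_learner(
    name = "majority",
    fit = function(m, y) {
      tab <- table(y$values)
      list(label = names(tab)[which.max(tab)])
    },
    predict = function(fitted, m) {
      list(labels = rep(fitted$label, n_samples(m)),
           scores = rep(0, n_samples(m)))
    })
}
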