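#' Construct a BTR model
#'
#' A BTR model is a sparse linear decision rule whose coefficients are
#' restricted by its language: `bin` uses \{1\}, `ter` and `terlog` use
#' \{-1, 1\}, and `ratio` splits the selected features into a numerator side
#' (coefficient +1) and a denominator side (coefficient -1). The score of a
#' sample is the (signed) cumulated abundance of the selected features, or
#' the numerator/denominator quotient for ratio models; the decision compares
#' the score against the threshold (the intercept-equivalent cut for
#' bin/ter/terlog, the ratio factor theta for ratio models).
#'
#' @param language One of `"bin"`, `"ter"`, `"ratio"`, `"terlog"`.
#' @param features Character vector of selected feature names (model size k).
#' @param coefficients Numeric vector aligned with `features`; see above.
#' @param data_scale Scale of the data the model applies to
#'   (`"relative"`, `"log"`, or `"presence"`); `terlog` requires `"log"`.
#' @param threshold Decision cut (set by [fit_model_threshold()] if `NULL`).
#' @param direction `"score_greater"` or `"score_less"`: which side of the
#'   threshold maps to the positive class.
#' @param class_map List with entries `positive` and `negative` naming the
#'   observed labels.
#' @param fitness Optional list `(metric =, value =)` recorded at fit time.
#' @return An object of class `btr_model`.
#' @export
btr_model <- function(language, features, coefficients, data_scale,
                      threshold = NULL, direction = NULL, class_map = NULL,
                      fitness = NULL) {
  language <- match.arg(language, c("bin", "ter", "ratio", "terlog"))
  data_scale <- match.arg(data_scale, c("relative", "log", "presence", "raw"))
  features <- as.character(features)
  k <- length(features)
  if (k < 1) btr_validation_error("a model needs at least one feature (k >= 1)")
  if (length(coefficients) != k)
    btr_validation_error("coefficients must align one-to-one with features")
  if (anyDuplicated(features))
    btr_validation_error("duplicated features in model")
  ok <- switch(language,
    bin    = all(coefficients == 1),
    ter    = all(coefficients %in% c(-1, 1)),
    terlog = all(coefficients %in% c(-1, 1)),
    ratio  = all(coefficients %in% c(-1, 1)) && any(coefficients == 1))
  if (!ok) btr_validation_error(sprintf("coefficients invalid for language '%s'", language))
  if (language == "terlog" && data_scale != "log")
    btr_validation_error("terlog models require data_scale = 'log'")
  if (!is.null(direction))
    direction <- match.arg(direction, c("score_greater", "score_less"))
  structure(list(language = language, features = features,
                 coefficients = as.numeric(coefficients),
                 data_scale = data_scale, threshold = threshold,
                 direction = direction, class_map = class_map,
                 fitness = fitness),
            class = "btr_model")
}

#' @method print btr_model
#' @export
print.btr_model <- function(x, ...) {
  tag <- function(cf) if (x$language == "ratio") ifelse(cf > 0, "num", "den") else sprintf("%+d", cf)
  cat(sprintf("<btr_model> %s, k = %d, scale = %s\n", x$language,
              length(x$features), x$data_scale))
  cat(paste(sprintf("  %s [%s]", x$features, tag(x$coefficients)), collapse = "\n"), "\n")
  if (!is.null(x$threshold))
    cat(sprintf("  threshold = %.6g (%s -> %s)\n", x$threshold,
                x$direction %||% "?", x$class_map$positive %||% "?"))
  if (!is.null(x$fitness))
    cat(sprintf("  fitness: %s = %.4f\n", x$fitness$metric, x$fitness$value))
  invisible(x)
}

model_size <- function(model) length(model$features)

# identity of the decision structure, ignoring the threshold (dedup key)
model_key <- function(model) {
  o <- order(model$features)
  paste(model$language,
        paste(model$features[o], collapse = "|"),
        paste(model$coefficients[o], collapse = "|"), sep = "::")
}

# Core scoring on a plain matrix given row indices; the hot path shared by
# the GA.  `coef` follows the btr_model convention (+1 numerator / -1
# denominator for ratio).
score_idx <- function(X, idx, coef, language) {
  if (language == "ratio") {
    num <- coef > 0
    sn <- if (sum(num) == 1L) X[idx[num], ] else .colSums(X[idx[num], , drop = FALSE], sum(num), ncol(X))
    if (all(num)) {
      sd_ <- numeric(length(sn))
    } else {
      sd_ <- if (sum(!num) == 1L) X[idx[!num], ] else .colSums(X[idx[!num], , drop = FALSE], sum(!num), ncol(X))
    }
    sc <- sn / sd_
    z <- sd_ == 0
    if (any(z)) sc[z] <- ifelse(sn[z] > 0, Inf, 0)   # x/0 and 0/0 sentinels
    sc
  } else if (length(idx) == 1L) {
    X[idx, ] * coef
  } else {
    .colSums(X[idx, , drop = FALSE] * coef, length(idx), ncol(X))
  }
}

#' Score samples with a BTR model
#'
#' For `bin`/`ter`/`terlog` the score is the signed sum of the selected
#' features' values (the threshold is not part of the score). For `ratio` it
#' is the quotient of the numerator and denominator sums, with sentinels
#' `x/0 -> Inf` (for `x > 0`) and `0/0 -> 0` so that predictions remain
#' defined on presence-sparse data.
#'
#' @param model A `btr_model`.
#' @param m A `btr_abundance` whose scale matches `model$data_scale` and
#'   whose rownames contain all model features.
#' @return Named numeric vector, one score per sample.
#' @export
score_samples <- function(model, m) {
  if (!inherits(m, "btr_abundance")) btr_validation_error("'m' must be a btr_abundance")
  if (m$scale != model$data_scale)
    btr_validation_error(sprintf("model was fit on '%s' data but got '%s'",
                                 model$data_scale, m$scale))
  idx <- match(model$features, feature_ids(m))
  if (anyNA(idx))
    btr_validation_error(sprintf("feature(s) absent from matrix: %s",
      paste(model$features[is.na(idx)], collapse = ", ")))
  sc <- score_idx(m$values, idx, model$coefficients, model$language)
  names(sc) <- sample_ids(m)
  sc
}

#' Predict class labels with a fitted BTR model
#'
#' With `direction = "score_greater"` a sample is assigned the positive class
#' iff its score is strictly greater than the threshold (`score_less` is
#' symmetric); ties go to the non-positive class.
#'
#' @param object A fitted `btr_model` (threshold, direction and class map set).
#' @param m A `btr_abundance`.
#' @param type `"class"` for labels, `"score"` for direction-oriented scores
#'   (higher = more positive-class-like, usable for AUC).
#' @param ... Unused.
#' @return Named character vector of labels, or numeric scores.
#' @export
predict.btr_model <- function(object, m, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$threshold) || is.null(object$direction))
    btr_validation_error("model threshold/direction not fitted")
  sc <- score_samples(object, m)
  if (type == "score") {
    return(if (object$direction == "score_greater") sc else -sc)
  }
  if (is.null(object$class_map))
    btr_validation_error("model class_map not set")
  pos <- if (object$direction == "score_greater") sc > object$threshold else sc < object$threshold
  out <- ifelse(pos, object$class_map$positive, object$class_map$negative)
  names(out) <- names(sc)
  out
}

#' Fit the decision threshold of a BTR model on training data
#'
#' Runs [optimize_threshold()] on the model's training scores; for ratio
#' models the selected cut is the ratio factor theta. The class map and
#' training fitness are recorded on the returned model.
#'
#' @param model A `btr_model`.
#' @param m Training `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param metric Fitness metric to record (default `"accuracy"`).
#' @return The fitted `btr_model`.
#' @export
fit_model_threshold <- function(model, m, y, metric = "accuracy") {
  y <- align_target(y, m)
  sc <- score_samples(model, m)
  opt <- optimize_threshold(sc, y)
  model$threshold <- opt$threshold
  model$direction <- opt$direction
  neg <- setdiff(sort(unique(y$values)), y$positive_class)
  model$class_map <- list(positive = y$positive_class, negative = neg)
  val <- if (metric == "accuracy") {
    1 - opt$train_error / length(sc)
  } else {
    compute_metric(y$values,
                   if (metric == "auc") predict(model, m, type = "score")
                   else predict(model, m),
                   metric, positive_class = y$positive_class)
  }
  model$fitness <- list(metric = metric, value = val)
  model
}

#' Scale a model score into the range of a continuous target
#'
#' Ordinary least squares of the target on the model score, giving the
#' multiplication factor `alpha` and intercept `beta`, plus a goodness
#' metric: squared Pearson correlation (`r2`), Spearman rho
#' (`spearman_rho`), or the scaled standard error of regression (`ser`,
#' residual standard error divided by the target's standard deviation).
#'
#' @param scores Numeric model scores.
#' @param y Numeric targets (or a continuous `btr_target`).
#' @param metric One of `"r2"`, `"spearman_rho"`, `"ser"`.
#' @return A list of class `btr_regression` with `alpha`, `beta`, `metric`,
#'   `value`.
#' @export
fit_regression_scaling <- function(scores, y, metric = c("r2", "spearman_rho", "ser")) {
  metric <- match.arg(metric)
  if (inherits(y, "btr_target")) {
    if (y$kind != "continuous") btr_validation_error("continuous target required")
    y <- unname(y$values)
  }
  if (length(scores) != length(y)) btr_validation_error("scores and targets lengths differ")
  n <- length(y)
  if (n < 3) btr_validation_error("regression scaling needs n >= 3")
  if (stats::var(scores) == 0)
    btr_degenerate_error("constant scores: regression scaling is undefined")
  alpha <- stats::cov(scores, y) / stats::var(scores)
  beta <- mean(y) - alpha * mean(scores)
  resid <- y - (alpha * scores + beta)
  value <- switch(metric,
    r2 = stats::cor(scores, y)^2,
    spearman_rho = stats::cor(scores, y, method = "spearman"),
    ser = sqrt(sum(resid^2) / (n - 2)) / stats::sd(y))
  structure(list(alpha = alpha, beta = beta, metric = metric, value = value),
            class = "btr_regression")
}
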