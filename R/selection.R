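#' Select the best model under a model-size penalty
#'
#' Returns the model maximizing `fitness - lambda * k`. With the default
#' `lambda = 0.01` a model using one additional feature is preferred only if
#' it improves the (training) accuracy by more than 1%. Ties are broken by
#' smaller model size, then by the lexicographic order of the sorted feature
#' names, so the choice is deterministic and invariant under population
#' reordering.
#'
#' @param pop A `btr_population`.
#' @param lambda Penalty per selected feature (>= 0).
#' @return The selected `btr_model`.
#' @export
penalized_select <- function(pop, lambda = 0.01) {
  if (!inherits(pop, "btr_population") || length(pop$models) == 0)
    btr_validation_error("empty population")
  if (lambda < 0) btr_config_error("lambda must be >= 0")
  fit <- population_fitness(pop)
  k <- population_sizes(pop)
  key <- vapply(pop$models, function(mm) paste(sort(mm$features), collapse = "|"),
                character(1))
  # round away float noise so that an exactly-lambda-sized gain is a tie
  # (resolved toward the smaller model), per the strictly-greater rule
  pen <- round(fit - lambda * k, 10)
  pop$models[[order(-pen, k, key)[1L]]]
}

#' Extract the family of best models (FBM)
#'
#' Collects every model whose accuracy lies within a statistically
#' equivalent window of the best model's accuracy. The window assumes the
#' number of correct training classifications is binomial: with best
#' accuracy `a` over `n_train` samples, the one-sided normal approximation
#' gives `window = qnorm(1 - p_level) * sqrt(a * (1 - a) / n_train)`.
#' Setting `exact = TRUE` uses the exact binomial quantile instead
#' (`a - qbinom(p_level, n_train, a) / n_train`); the two differ negligibly
#' for `n_train >= 30`. Members are deduplicated by their decision structure
#' (feature set and signs, ignoring the threshold).
#'
#' @param pop A `btr_population` with a classification fitness metric.
#' @param n_train Number of training samples defining the window.
#' @param p_level One-sided equivalence level (default 0.05).
#' @param exact Use the exact binomial quantile instead of the normal
#'   approximation.
#' @return An object of class `btr_fbm` with fields `models`,
#'   `best_fitness`, `window`, `n_train`, `p_level`.
#' @export
extract_fbm <- function(pop, n_train, p_level = 0.05, exact = FALSE) {
  if (!inherits(pop, "btr_population") || length(pop$models) == 0)
    btr_validation_error("empty population")
  metric <- pop$models[[1]]$fitness$metric
  if (metric %in% c("r2", "spearman_rho", "ser"))
    btr_validation_error("FBM extraction is defined on classification accuracy-type fitness")
  if (n_train < 1) btr_validation_error("n_train must be >= 1")
  fit <- population_fitness(pop)
  a <- max(fit)
  window <- if (exact) {
    a - stats::qbinom(p_level, n_train, min(1, max(0, a))) / n_train
  } else {
    stats::qnorm(1 - p_level) * sqrt(a * (1 - a) / n_train)
  }
  keep <- which(fit >= a - window - 1e-12)
  keep <- keep[order(-fit[keep])]
  models <- pop$models[keep]
  dup <- duplicated(vapply(models, model_key, character(1)))
  models <- models[!dup]
  structure(list(models = models, best_fitness = a, window = window,
                 n_train = as.integer(n_train), p_level = p_level),
            class = "btr_fbm")
}

#' @method print btr_fbm
#' @export
print.btr_fbm <- function(x, ...) {
  cat(sprintf("<btr_fbm> %d models, best fitness %.4f, window %.4f (n_train = %d, P < %g)\n",
              length(x$models), x$best_fitness, x$window, x$n_train, x$p_level))
  cat(sprintf("  %d distinct features\n",
              length(unique(unlist(lapply(x$models, `[[`, "features"))))))
  invisible(x)
}
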