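#' Specification of a synthetic compositional dataset
#'
#' Describes a log-normal composition: per-feature log-scale means and SDs,
#' a detection-limit sparsity fraction, and optionally a planted BTR model
#' that generates the class labels. Log-normal draws closed to relative
#' abundances reproduce the heavy-tailed, zero-inflated profiles typical of
#' shotgun relative abundance tables while keeping per-feature dispersion
#' under direct control (unlike a Dirichlet composition).
#'
#' @param n_samples,p_features Dimensions of the generated table.
#' @param meanlog Per-feature log-scale means (length `p_features`,
#'   recycled); `NULL` draws them once from N(0, 1.5) under `seed`, giving a
#'   realistic spread of feature abundances over ~4 orders of magnitude.
#' @param sdlog Per-feature log-scale SD (default 1).
#' @param sparsity Fraction of entries zeroed at the detection limit
#'   (default 0.3).
#' @param planted Optional list describing the planted model:
#'   `language`, `features` (indices into `1:p_features`), `coefficients`,
#'   and optionally `threshold` (defaults to the median planted score, which
#'   yields balanced classes).
#' @param label_noise Probability of flipping each planted label
#'   (in \[0, 0.5)).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `btr_synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, p_features = 50L, meanlog = NULL,
                           sdlog = 1, sparsity = 0.3, planted = NULL,
                           label_noise = 0.05, seed = 42L) {
  if (n_samples < 2 || p_features < 2)
    btr_config_error("need n_samples >= 2 and p_features >= 2")
  if (sparsity < 0 || sparsity >= 1) btr_config_error("sparsity must be in [0, 1)")
  if (label_noise < 0 || label_noise >= 0.5)
    btr_config_error("label_noise must be in [0, 0.5)")
  if (!is.null(planted)) {
    if (!all(planted$features %in% seq_len(p_features)))
      btr_config_error("planted features must be indices in 1..p_features")
    if (length(planted$features) != length(planted$coefficients))
      btr_config_error("planted features/coefficients lengths differ")
  }
  structure(list(n_samples = as.integer(n_samples),
                 p_features = as.integer(p_features), meanlog = meanlog,
                 sdlog = sdlog, sparsity = sparsity, planted = planted,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "btr_synthetic_spec")
}

#' Generate a synthetic relative-abundance matrix
#'
#' Draws per-sample log-normal abundances, zeroes entries below the
#' `sparsity` quantile of the drawn values (a detection limit; each sample's
#' largest entry is always kept so no sample is empty), and closes every
#' sample to sum 1.
#'
#' @param spec A [synthetic_spec()].
#' @return A `btr_abundance` with `scale = "relative"`.
#' @export
generate_abundance <- function(spec) {
  stopifnot(inherits(spec, "btr_synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$p_features; n <- spec$n_samples
  meanlog <- spec$meanlog %||% stats::rnorm(p, 0, 1.5)
  meanlog <- rep_len(meanlog, p)
  X <- matrix(stats::rlnorm(p * n, meanlog, spec$sdlog), nrow = p,
              dimnames = list(sprintf("feat_%03d", seq_len(p)),
                              sprintf("sample_%03d", seq_len(n))))
  if (spec$sparsity > 0) {
    detect <- stats::quantile(X, spec$sparsity, names = FALSE)
    keep_max <- cbind(apply(X, 2, which.max), seq_len(n))
    below <- X < detect
    below[keep_max] <- FALSE
    X[below] <- 0
  }
  normalize_relative(abundance_matrix(X, "raw"))
}

planted_model_of <- function(spec, m) {
  pl <- spec$planted
  if (is.null(pl)) btr_config_error("spec has no planted model")
  btr_model(language = pl$language,
            features = feature_ids(m)[pl$features],
            coefficients = pl$coefficients, data_scale = m$scale)
}

#' Plant class labels from the spec's model
#'
#' Labels are the planted model's predictions ("pos" side = score above the
#' planted threshold), each flipped independently with probability
#' `label_noise`. A planted threshold that puts every sample on one side is
#' re-drawn at the median score, with a warning. Deterministic given the
#' spec seed (a distinct stream from the abundance draw).
#'
#' @param m The `btr_abundance` generated from `spec`.
#' @param spec A [synthetic_spec()] with a `planted` model.
#' @return A binary `btr_target` with labels `"neg"`/`"pos"`
#'   (`positive_class = "pos"`).
#' @export
plant_labels <- function(m, spec) {
  stopifnot(inherits(spec, "btr_synthetic_spec"))
  model <- planted_model_of(spec, m)
  sc <- score_samples(model, m)
  thr <- spec$planted$threshold %||% stats::median(sc)
  lab <- ifelse(sc > thr, "pos", "neg")
  if (length(unique(lab)) < 2) {
    warning("planted threshold is degenerate; re-drawing at the median score")
    thr <- stats::median(sc)
    lab <- ifelse(sc > thr, "pos", "neg")
    if (length(unique(lab)) < 2)  # ties at the median: force a split
      lab <- ifelse(rank(sc, ties.method = "first") > length(sc) / 2, "pos", "neg")
  }
  set.seed(spec$seed + 1L)
  flip <- stats::runif(length(lab)) < spec$label_noise
  lab[flip] <- ifelse(lab[flip] == "pos", "neg", "pos")
  sample_target(lab, sample_ids(m), kind = "binary_class", positive_class = "pos")
}

#' Generate a continuous target from the planted model score
#'
#' `y = alpha * score + beta + N(0, noise_sd)`: the recovery fixture for
#' [fit_regression_scaling()].
#'
#' @param m The `btr_abundance` generated from `spec`.
#' @param spec A [synthetic_spec()] with a `planted` model.
#' @param alpha,beta Scaling factor and intercept.
#' @param noise_sd Gaussian noise SD (0 gives an exactly linear target).
#' @return A continuous `btr_target`.
#' @export
generate_regression_target <- function(m, spec, alpha = 1, beta = 0,
                                       noise_sd = 0) {
  stopifnot(inherits(spec, "btr_synthetic_spec"))
  sc <- score_samples(planted_model_of(spec, m), m)
  set.seed(spec$seed + 2L)
  y <- alpha * sc + beta + stats::rnorm(length(sc), 0, noise_sd)
  sample_target(unname(y), sample_ids(m), kind = "continuous")
}
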