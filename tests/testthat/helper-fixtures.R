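# Shared fixtures and independent oracles, built in code at test time.

# random relative-abundance matrix
make_abundance <- function(p = 20, n = 40, seed = 1, scale = "relative") {
  set.seed(seed)
  X <- matrix(stats::rlnorm(p * n), p, n,
              dimnames = list(sprintf("f%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  m <- abundance_matrix(X, "raw")
  if (scale == "relative") normalize_relative(m) else m
}

make_binary_target <- function(n = 40, n_pos = NULL, seed = 2,
                               ids = sprintf("s%03d", seq_len(n))) {
  set.seed(seed)
  n_pos <- n_pos %||% (n %/% 2)
  lab <- sample(rep(c("neg", "pos"), c(n - n_pos, n_pos)))
  sample_target(lab, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# abundance matrix with a planted additive signal: the 'planted' features are
# multiplied by 'effect' in positive-class samples before closure
make_planted <- function(p = 20, n = 60, planted = 1:2, effect = 6, seed = 3) {
  set.seed(seed)
  X <- matrix(stats::rlnorm(p * n), p, n,
              dimnames = list(sprintf("f%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  pos <- seq_len(n) > n / 2
  X[planted, pos] <- X[planted, pos] * effect
  m <- normalize_relative(abundance_matrix(X, "raw"))
  y <- sample_target(ifelse(pos, "pos", "neg"), colnames(X))
  list(m = m, y = y)
}

# independent brute-force oracle for the threshold optimizer: enumerate every
# candidate cut and both directions with explicit predictions
brute_force_threshold <- function(scores, ypos) {
  s <- sort(unique(scores))
  sf <- s
  if (any(!is.finite(sf))) sf[!is.finite(sf)] <- max(c(sf[is.finite(sf)], 0)) + 2
  cuts <- if (length(sf) == 1) c(sf - 1, sf + 1) else
    c(sf[1] - 1, (sf[-1] + sf[-length(sf)]) / 2, sf[length(sf)] + 1)
  best <- Inf
  for (ct in cuts) {
    for (greater in c(TRUE, FALSE)) {
      pred <- if (greater) scores > ct else scores < ct
      best <- min(best, sum(pred != ypos))
    }
  }
  as.integer(best)
}

# fitted single-feature bin model on a named matrix (helper for MDA tests)
fit_bin_model <- function(m, y, feature) {
  mod <- btr_model("bin", feature, 1, m$scale)
  fit_model_threshold(mod, m, y)
}

penalized_value <- function(model, lambda = 0.01) {
  model$fitness$value - lambda * length(model$features)
}
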