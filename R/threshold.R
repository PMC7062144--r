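#' Optimal decision threshold by cumulative-error sweep
#'
#' Sorts the samples by score and evaluates every cut position -- the
#' midpoints between consecutive distinct scores plus below-minimum and
#' above-maximum sentinels -- for both comparison directions, counting
#' misclassifications with a single cumulative sweep. The returned cut
#' minimizes the training error and is guaranteed to match exhaustive
#' enumeration over all cuts and directions. Ties in error resolve to the
#' cut with the widest margin (midpoint of the widest qualifying score gap;
#' the sentinels count as infinitely wide), then to the smaller cut value,
#' then to `score_greater`, so the result is deterministic. When all scores
#' are identical the sentinel cut predicting the larger class is returned,
#' with error equal to the smaller class count.
#'
#' Non-finite scores (the `Inf` sentinel of ratio models) are supported: cut
#' candidates are generated on a finite surrogate axis while errors are
#' counted on the actual scores.
#'
#' @param scores Numeric scores, length >= 2.
#' @param y Binary labels: a `btr_target`, a logical vector (TRUE =
#'   positive), or a character/factor vector with `positive_class`.
#' @param positive_class Label treated as positive when `y` is not logical;
#'   defaults to the lexicographically larger label.
#' @return List with `threshold`, `direction`, `train_error` (integer
#'   misclassification count), and `accuracy`.
#' @export
optimize_threshold <- function(scores, y, positive_class = NULL) {
  ypos <- as_positive_mask(y, positive_class)
  n <- length(scores)
  if (length(ypos) != n) btr_validation_error("scores and labels lengths differ")
  if (n < 2) btr_validation_error("threshold optimization needs n >= 2")
  if (all(ypos) || !any(ypos))
    btr_validation_error("both classes must be present to optimize a threshold")
  sw <- threshold_sweep(scores, ypos)
  list(threshold = sw$cut, direction = sw$dir,
       train_error = as.integer(sw$err), accuracy = 1 - sw$err / n)
}

# lean computational core shared with the genetic search (no validation);
# implemented in C++ (src/threshold_sweep.cpp), this R version is retained
# as the readable reference of the same algorithm
threshold_sweep <- function(scores, ypos) {
  cpp_threshold_sweep(unname(scores), ypos)
}

threshold_sweep_r <- function(scores, ypos) {
  n <- length(scores)
  o <- sort.int(unname(scores), index.return = TRUE, method = "radix")
  s <- o$x
  yp <- ypos[o$ix]
  cp <- c(0, cumsum(yp))          # positives among the i lowest-scoring samples
  cn <- c(0, cumsum(!yp))
  npos <- cp[n + 1]
  nneg <- cn[n + 1]

  # finite surrogate axis for cut placement (errors use the real scores)
  sf <- s
  fin <- is.finite(sf)
  if (!all(fin)) {
    lo <- if (any(fin)) min(sf[fin]) else 0
    hi <- if (any(fin)) max(sf[fin]) else 0
    sf[sf == -Inf] <- lo - 2
    sf[sf == Inf] <- hi + 2
  }

  # boundary j in 1..n+1 separates the j-1 lowest scores from the rest;
  # boundaries inside a run of tied scores are not admissible cuts
  err_g <- cp + (nneg - cn)       # positive iff score > cut
  err_l <- cn + (npos - cp)       # positive iff score < cut
  vi <- which(c(TRUE, sf[-1] > sf[-n], TRUE))

  gap_at <- function(j) ifelse(j == 1L | j == n + 1L, Inf, sf[j] - sf[j - 1L])
  cut_at <- function(j) {
    ifelse(j == 1L, sf[1] - 1,
           ifelse(j == n + 1L, sf[n] + 1, (sf[j - 1L] + sf[pmin(j, n)]) / 2))
  }

  emin <- min(err_g[vi], err_l[vi])
  cand_g <- vi[err_g[vi] == emin]
  cand_l <- vi[err_l[vi] == emin]
  cand <- c(cand_g, cand_l)
  greater <- rep(c(TRUE, FALSE), c(length(cand_g), length(cand_l)))
  if (length(cand) > 1L) {
    # widest margin, then smallest cut, then score_greater
    g <- gap_at(cand)
    keep <- g == max(g)
    cand <- cand[keep]; greater <- greater[keep]
    if (length(cand) > 1L) {
      cv <- cut_at(cand)
      keep <- cv == min(cv)
      cand <- cand[keep]; greater <- greater[keep]
      if (length(cand) > 1L && any(greater)) {
        cand <- cand[greater][1L]; greater <- TRUE
      }
    }
  }
  j <- cand[1L]
  list(cut = cut_at(j), dir = if (greater[1L]) "score_greater" else "score_less",
       err = emin)
}

as_positive_mask <- function(y, positive_class = NULL) {
  if (inherits(y, "btr_target")) return(positive_mask(y))
  if (is.logical(y)) return(y)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) > 2) btr_validation_error("more than 2 classes in labels")
  if (is.null(positive_class)) positive_class <- lev[length(lev)]
  y == positive_class
}
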