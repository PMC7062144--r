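#' Configuration of the genetic model search
#'
#' Defaults are conventional genetic-algorithm settings: one island of 200
#' models per model size k, 100 generations, tournament selection of size 2,
#' elitism on the top 10%, per-feature mutation rate 0.2 and crossover rate
#' 0.8. `patience` optionally stops an island early after that many
#' generations without improvement of its best fitness (`Inf` = always run
#' the full budget).
#'
#' @param language Model language: `"bin"`, `"ter"`, `"ratio"`, `"terlog"`.
#' @param k_min,k_max Range of model sizes to search (one island per k).
#' @param population_size Models per island (>= 2).
#' @param generations Number of generations per island.
#' @param mutation_rate Per-selected-feature mutation probability.
#' @param crossover_rate Probability that a selected parent pair recombines.
#' @param elite_fraction Fraction of the population carried over unchanged.
#' @param seed Integer seed; the whole search is deterministic given it.
#' @param fitness_metric `"accuracy"` (default), `"auc"`, `"f1"`,
#'   `"precision"` or `"recall"`.
#' @param seeded_fraction Fraction of the initial population seeded from the
#'   top Mann-Whitney-ranked features (signs from class-wise enrichment);
#'   the rest is uniform random.
#' @param patience Early-stopping patience in generations (default `Inf`).
#' @param verbose Emit per-generation best-fitness messages.
#' @return A list of class `btr_search_config`.
#' @export
search_config <- function(language = "bin", k_min = 1L, k_max = 5L,
                          population_size = 200L, generations = 100L,
                          mutation_rate = 0.2, crossover_rate = 0.8,
                          elite_fraction = 0.1, seed = 42L,
                          fitness_metric = c("accuracy", "auc", "f1",
                                             "precision", "recall"),
                          seeded_fraction = 0.5, patience = Inf,
                          verbose = FALSE) {
  language <- match.arg(language, c("bin", "ter", "ratio", "terlog"))
  fitness_metric <- match.arg(fitness_metric)
  if (k_min < 1 || k_min > k_max) btr_config_error("need 1 <= k_min <= k_max")
  if (population_size < 2) btr_config_error("population_size must be >= 2")
  for (r in c(mutation_rate, crossover_rate, elite_fraction, seeded_fraction))
    if (r < 0 || r > 1) btr_config_error("rates/fractions must be in [0, 1]")
  structure(list(language = language, k_min = as.integer(k_min),
                 k_max = as.integer(k_max),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elite_fraction = elite_fraction, seed = as.integer(seed),
                 fitness_metric = fitness_metric,
                 seeded_fraction = seeded_fraction, patience = patience,
                 verbose = isTRUE(verbose)),
            class = "btr_search_config")
}

# ---- internal individual representation ------------------------------------
# an individual is list(idx, coef, cut, dir, err, fit); idx is sorted and the
# first selected feature carries a positive coefficient (canonical form), so a
# rule and its global sign flip are searched once.

canonicalize_ind <- function(idx, coef, language) {
  o <- order(idx)
  idx <- idx[o]; coef <- coef[o]
  if (language != "bin" && coef[1] < 0) coef <- -coef
  list(idx = idx, coef = coef)
}

fitness_from_sweep <- function(sc, sw, ypos, metric) {
  n <- length(sc)
  if (metric == "accuracy") return(1 - sw$err / n)
  if (metric == "auc") {
    oriented <- if (sw$dir == "score_greater") sc else -sc
    r <- rank(oriented)
    n1 <- sum(ypos); n0 <- n - n1
    return((sum(r[ypos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  pred <- if (sw$dir == "score_greater") sc > sw$cut else sc < sw$cut
  tp <- sum(pred & ypos); fp <- sum(pred & !ypos); fn <- sum(!pred & ypos)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  switch(metric,
    precision = prec, recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

eval_ind <- function(X, ypos, idx, coef, language, metric) {
  sc <- score_idx(X, idx, coef, language)
  sw <- threshold_sweep(sc, ypos)
  list(idx = idx, coef = coef, cut = sw$cut, dir = sw$dir, err = sw$err,
       fit = fitness_from_sweep(sc, sw, ypos, metric))
}

random_coef <- function(k, language) {
  if (language == "bin") rep(1, k) else sample(c(1, -1), k, replace = TRUE)
}

# build a btr_model from an internal individual
ind_to_model <- function(ind, language, feat_names, data_scale, class_map,
                         metric, n) {
  btr_model(language = language, features = feat_names[ind$idx],
            coefficients = ind$coef, data_scale = data_scale,
            threshold = ind$cut, direction = ind$dir, class_map = class_map,
            fitness = list(metric = metric, value = ind$fit))
}

model_to_ind <- function(model, m) {
  idx <- match(model$features, feature_ids(m))
  if (anyNA(idx)) btr_validation_error("model features absent from matrix")
  list(idx = idx, coef = model$coefficients)
}

# resolve the search scale: raw input is normalized (with a notice) and the
# terlog language works on log-transformed data but searches like ter
prepare_search_data <- function(m, language) {
  if (m$scale == "raw") {
    message("raw abundance table: applying normalize_relative() before fitting")
    m <- normalize_relative(m)
  }
  if (language == "terlog" && m$scale != "log") {
    message("terlog language: applying log_transform() before fitting")
    m <- log_transform(m)
  }
  m
}

class_map_of <- function(y) {
  list(positive = y$positive_class,
       negative = setdiff(sort(unique(y$values)), y$positive_class))
}

# ---- population container --------------------------------------------------

#' Assemble a population from a list of models
#'
#' Builds a `btr_population` from fitted models sharing one language and
#' data scale, e.g. to feed hand-constructed model sets to
#' [penalized_select()] or [extract_fbm()].
#'
#' @param models Non-empty list of fitted `btr_model`s (thresholds and
#'   fitness set).
#' @return A `btr_population`.
#' @export
model_population <- function(models) {
  if (length(models) == 0) btr_validation_error("empty model list")
  lang <- unique(vapply(models, `[[`, character(1), "language"))
  scale <- unique(vapply(models, `[[`, character(1), "data_scale"))
  if (length(lang) != 1 || length(scale) != 1)
    btr_validation_error("all models must share language and data scale")
  if (any(vapply(models, function(mm) is.null(mm$threshold) || is.null(mm$fitness),
                 logical(1))))
    btr_validation_error("all models must carry a fitted threshold and fitness")
  new_population(models, lang, scale, 0L,
                 data.frame(k = integer(), generation = integer(),
                            best_fitness = numeric()))
}

new_population <- function(models, language, data_scale, generation, history) {
  k <- vapply(models, model_size, integer(1))
  fit <- vapply(models, function(mm) mm$fitness$value, numeric(1))
  models <- models[order(k, -fit)]
  structure(list(models = models, language = language, data_scale = data_scale,
                 generation = generation, history = history),
            class = "btr_population")
}

#' @method print btr_population
#' @export
print.btr_population <- function(x, ...) {
  k <- vapply(x$models, model_size, integer(1))
  fit <- vapply(x$models, function(mm) mm$fitness$value, numeric(1))
  cat(sprintf("<btr_population> %s, %d models, k in [%d, %d], generation %d\n",
              x$language, length(x$models), min(k), max(k), x$generation))
  for (kk in sort(unique(k)))
    cat(sprintf("  k = %d: %d models, best fitness %.4f\n", kk, sum(k == kk),
                max(fit[k == kk])))
  invisible(x)
}

#' Fitness values and model sizes of a population
#'
#' @param pop A `btr_population`.
#' @return `population_fitness()`: numeric vector of training fitness
#'   values; `population_sizes()`: integer vector of model sizes k (both in
#'   the population's model order).
#' @export
population_fitness <- function(pop) {
  vapply(pop$models, function(mm) mm$fitness$value, numeric(1))
}

#' @rdname population_fitness
#' @export
population_sizes <- function(pop) {
  vapply(pop$models, model_size, integer(1))
}

# ---- initialization ---------------------------------------------------------

init_island <- function(X, ypos, k, cfg, ranked_idx, ranked_sign) {
  p <- nrow(X)
  N <- cfg$population_size
  language <- cfg$language
  pool <- ranked_idx[seq_len(min(p, max(10, 3 * cfg$k_max)))]
  n_seed <- max(1L, round(cfg$seeded_fraction * N))
  inds <- vector("list", N)
  for (i in seq_len(N)) {
    if (i == 1L) {
      idx <- ranked_idx[seq_len(k)]            # guaranteed top-ranked model
      coef <- if (language == "bin") rep(1, k) else ranked_sign[idx]
    } else if (i <= n_seed) {
      idx <- if (length(pool) == 1L) pool else sample(pool, k)
      coef <- if (language == "bin") rep(1, k) else ranked_sign[idx]
    } else {
      idx <- sample.int(p, k)
      coef <- random_coef(k, language)
    }
    cc <- canonicalize_ind(idx, coef, language)
    inds[[i]] <- eval_ind(X, ypos, cc$idx, cc$coef, language, cfg$fitness_metric)
  }
  inds
}

#' Initialize a population of BTR models
#'
#' For every model size k in `[k_min, k_max]`, seeds a mix of models built
#' from the top Mann-Whitney-ranked features (signs set by class-wise
#' enrichment direction; the first model of each island is exactly the top-k
#' ranked set) and uniform random feature subsets with random signs. All
#' thresholds are fitted. Deterministic given `cfg$seed`.
#'
#' @param m A `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param cfg A [search_config()].
#' @return A `btr_population`.
#' @export
initialize_population <- function(m, y, cfg) {
  m <- prepare_search_data(m, cfg$language)
  y <- align_target(y, m)
  if (cfg$k_max > n_features(m))
    btr_config_error("k_max exceeds the number of features")
  set.seed(cfg$seed)
  ypos <- positive_mask(y)
  rk <- mann_whitney_rank(m, y)
  ranked_idx <- match(rk$feature, feature_ids(m))
  ranked_sign <- integer(n_features(m))
  ranked_sign[ranked_idx] <- rk$direction
  models <- list()
  for (k in cfg$k_min:cfg$k_max) {
    inds <- init_island(m$values, ypos, k, cfg, ranked_idx, ranked_sign)
    models <- c(models, lapply(inds, ind_to_model, language = cfg$language,
                               feat_names = feature_ids(m),
                               data_scale = m$scale,
                               class_map = class_map_of(y),
                               metric = cfg$fitness_metric, n = length(ypos)))
  }
  new_population(models, cfg$language, m$scale, 0L,
                 data.frame(k = integer(), generation = integer(),
                            best_fitness = numeric()))
}

# ---- variation operators ----------------------------------------------------

mutate_ind <- function(ind, p, rate, language) {
  k <- length(ind$idx)
  hit <- which(stats::runif(k) < rate)
  if (length(hit) == 0L) return(NULL)          # unchanged
  idx <- ind$idx; coef <- ind$coef
  for (j in hit) {
    swap <- language == "bin" || stats::runif(1) < 0.5
    if (swap) {
      # swaps draw from features outside both the current and the original
      # selection, so a mutated position is genuinely replaced
      free <- setdiff(seq_len(p), c(ind$idx, idx))
      if (length(free) == 0L) next
      idx[j] <- if (length(free) == 1L) free else sample(free, 1L)
    } else {
      coef[j] <- -coef[j]                      # sign / ratio-side flip
    }
  }
  canonicalize_ind(idx, coef, language)
}

crossover_inds <- function(a, b, language) {
  uf <- unique(c(a$idx, b$idx))
  ia <- match(uf, a$idx); ib <- match(uf, b$idx)
  sgn <- ifelse(!is.na(ia), a$coef[ia], b$coef[ib])
  both <- !is.na(ia) & !is.na(ib) & a$coef[ia] != b$coef[ib]
  ka <- length(a$idx); kb <- length(b$idx)
  make_child <- function() {
    s <- sgn
    if (any(both))
      s[both] <- ifelse(stats::runif(sum(both)) < 0.5, a$coef[ia[both]], b$coef[ib[both]])
    kc <- if (ka == kb) ka else sample(seq(min(ka, kb), max(ka, kb)), 1L)
    sel <- if (length(uf) == kc) seq_along(uf) else sample.int(length(uf), kc)
    canonicalize_ind(uf[sel], s[sel], language)
  }
  list(make_child(), make_child())
}

#' Mutate a BTR model
#'
#' Each selected feature is independently, with probability `rate`, either
#' swapped for a random unselected feature or (for signed languages)
#' sign/side-flipped (each with probability 1/2). Model size is unchanged
#' and the threshold is refitted. Uses R's global random number generator.
#'
#' @param model A `btr_model`.
#' @param m Training `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param rate Per-feature mutation probability in \[0, 1\].
#' @param metric Fitness metric recorded on the refitted model.
#' @return A `btr_model` (identical to the input when no position mutates).
#' @export
mutate_model <- function(model, m, y, rate, metric = "accuracy") {
  if (rate < 0 || rate > 1) btr_config_error("rate must be in [0, 1]")
  m <- prepare_search_data(m, model$language)
  y <- align_target(y, m)
  ind <- model_to_ind(model, m)
  mut <- mutate_ind(ind, n_features(m), rate, model$language)
  if (is.null(mut)) return(model)
  ev <- eval_ind(m$values, positive_mask(y), mut$idx, mut$coef,
                 model$language, metric)
  ind_to_model(ev, model$language, feature_ids(m), m$scale, class_map_of(y),
               metric, n_samples(m))
}

#' Recombine two BTR models
#'
#' The two children draw their features (with their signs/sides) from the
#' union of the parents' features; child sizes are sampled between the
#' parents' sizes, duplicates are impossible, and thresholds are refitted.
#'
#' @param a,b Parent `btr_model`s sharing language and data scale.
#' @param m Training `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param metric Fitness metric recorded on the children.
#' @return List of two `btr_model`s.
#' @export
crossover_models <- function(a, b, m, y, metric = "accuracy") {
  if (a$language != b$language || a$data_scale != b$data_scale)
    btr_validation_error("parents must share language and data scale")
  m <- prepare_search_data(m, a$language)
  y <- align_target(y, m)
  ypos <- positive_mask(y)
  kids <- crossover_inds(model_to_ind(a, m), model_to_ind(b, m), a$language)
  lapply(kids, function(kk) {
    ev <- eval_ind(m$values, ypos, kk$idx, kk$coef, a$language, metric)
    ind_to_model(ev, a$language, feature_ids(m), m$scale, class_map_of(y),
                 metric, n_samples(m))
  })
}

# ---- evolution ---------------------------------------------------------------

evolve_island <- function(X, ypos, k, cfg, ranked_idx, ranked_sign) {
  N <- cfg$population_size
  language <- cfg$language
  metric <- cfg$fitness_metric
  p <- nrow(X)
  pop <- init_island(X, ypos, k, cfg, ranked_idx, ranked_sign)
  fit <- vapply(pop, `[[`, numeric(1), "fit")
  n_elite <- max(1L, ceiling(cfg$elite_fraction * N))
  hist_best <- numeric(0)
  best <- max(fit)
  stale <- 0L
  gen <- 0L
  while (gen < cfg$generations) {
    gen <- gen + 1L
    ord <- order(-fit)
    newpop <- pop[ord[seq_len(n_elite)]]
    newfit <- fit[ord[seq_len(n_elite)]]
    while (length(newpop) < N) {
      t1 <- sample.int(N, 2L); p1 <- ord_pick(pop, fit, t1)
      t2 <- sample.int(N, 2L); p2 <- ord_pick(pop, fit, t2)
      if (stats::runif(1) < cfg$crossover_rate) {
        kids <- crossover_inds(p1, p2, language)
        kids <- lapply(kids, function(kk)
          eval_ind(X, ypos, kk$idx, kk$coef, language, metric))
      } else {
        kids <- list(p1, p2)
      }
      for (kid in kids) {
        mut <- mutate_ind(kid, p, cfg$mutation_rate, language)
        if (!is.null(mut))
          kid <- eval_ind(X, ypos, mut$idx, mut$coef, language, metric)
        if (length(newpop) < N) {
          newpop[[length(newpop) + 1L]] <- kid
          newfit[length(newpop)] <- kid$fit
        }
      }
    }
    pop <- newpop
    fit <- newfit
    gen_best <- max(fit)
    if (gen_best > best + 1e-12) {
      best <- gen_best
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    hist_best[gen] <- best
    if (cfg$verbose)
      message(sprintf("k=%d generation %d: best %s = %.4f", k, gen, metric, best))
    if (stale >= cfg$patience) break
  }
  list(pop = pop[order(-fit)], history = hist_best, generations = gen)
}

ord_pick <- function(pop, fit, ii) {
  if (fit[ii[1]] >= fit[ii[2]]) pop[[ii[1]]] else pop[[ii[2]]]
}

#' Evolve BTR models with a genetic algorithm
#'
#' Runs, independently for every model size k in `[k_min, k_max]`, an island
#' of elitism-preserving tournament selection, crossover and mutation over
#' the training fitness. The best-so-far fitness per island is non-decreasing
#' (elitism) and the whole search is deterministic given `cfg$seed`. Raw
#' input is normalized to relative abundances first; the `terlog` language
#' log-transforms the data and then searches ternary models on it.
#'
#' @param m A `btr_abundance`.
#' @param y Binary `btr_target`.
#' @param cfg A [search_config()].
#' @return A `btr_population` sorted by fitness within each k, with a
#'   per-generation best-fitness history.
#' @export
evolve <- function(m, y, cfg) {
  stopifnot(inherits(cfg, "btr_search_config"))
  m <- prepare_search_data(m, cfg$language)
  y <- align_target(y, m)
  if (cfg$k_max > n_features(m))
    btr_config_error("k_max exceeds the number of features")
  set.seed(cfg$seed)
  ypos <- positive_mask(y)
  rk <- mann_whitney_rank(m, y)
  ranked_idx <- match(rk$feature, feature_ids(m))
  ranked_sign <- integer(n_features(m))
  ranked_sign[ranked_idx] <- rk$direction
  if (cfg$generations == 0L)
    return(initialize_population(m, y, cfg))
  models <- list()
  hist <- list()
  for (k in cfg$k_min:cfg$k_max) {
    isl <- evolve_island(m$values, ypos, k, cfg, ranked_idx, ranked_sign)
    models <- c(models, lapply(isl$pop, ind_to_model, language = cfg$language,
                               feat_names = feature_ids(m),
                               data_scale = m$scale,
                               class_map = class_map_of(y),
                               metric = cfg$fitness_metric, n = length(ypos)))
    hist[[length(hist) + 1L]] <- data.frame(k = k,
                                            generation = seq_along(isl$history),
                                            best_fitness = isl$history)
  }
  new_population(models, cfg$language, m$scale, cfg$generations,
                 do.call(rbind, hist))
}
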