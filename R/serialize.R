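# JSON serialization. Numbers are written with 17 significant digits so a
# reloaded model reproduces predictions bit-identically against any table
# sharing the feature names.

model_to_list <- function(model) {
  list(language = model$language,
       features = model$features,
       coefficients = model$coefficients,
       threshold = model$threshold,
       direction = model$direction,
       class_map = model$class_map,
       data_scale = model$data_scale,
       fitness = if (!is.null(model$fitness))
         list(metric = model$fitness$metric,
              value = unname(model$fitness$value)))
}

model_from_list <- function(x) {
  btr_model(language = x$language, features = unlist(x$features),
            coefficients = unlist(x$coefficients),
            data_scale = x$data_scale,
            threshold = if (!is.null(x$threshold)) unname(unlist(x$threshold)),
            direction = x$direction,
            class_map = if (!is.null(x$class_map))
              list(positive = x$class_map$positive, negative = x$class_map$negative),
            fitness = if (!is.null(x$fitness))
              list(metric = x$fitness$metric, value = x$fitness$value))
}

#' Serialize a BTR model to JSON
#'
#' @param model A `btr_model`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(model_to_list(model), digits = 17L, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Re-instantiate a BTR model from JSON
#'
#' @param json A JSON string or path to a JSON file written by
#'   [model_to_json()].
#' @return A `btr_model`.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  model_from_list(x)
}

#' Serialize an FBM to JSON
#'
#' @param fbm A `btr_fbm`.
#' @param path Optional output file.
#' @return The JSON string (invisibly when written to a file).
#' @export
fbm_to_json <- function(fbm, path = NULL) {
  x <- list(best_fitness = unname(fbm$best_fitness), window = fbm$window,
            n_train = fbm$n_train, p_level = fbm$p_level,
            models = lapply(fbm$models, model_to_list))
  js <- jsonlite::toJSON(x, digits = 17L, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Re-instantiate an FBM from JSON
#'
#' @param json A JSON string or path written by [fbm_to_json()].
#' @return A `btr_fbm`.
#' @export
fbm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(models = lapply(x$models, model_from_list),
                 best_fitness = x$best_fitness, window = x$window,
                 n_train = as.integer(x$n_train), p_level = x$p_level),
            class = "btr_fbm")
}

#' Barcode representation of a model
#'
#' The ordered list of (feature, sign) pairs used for barcode-style plots:
#' +1 (numerator) features in one color, -1 (denominator) in the other.
#'
#' @param model A `btr_model`.
#' @return Data frame with columns `feature`, `sign`, `side`.
#' @export
barcode_table <- function(model) {
  side <- if (model$language == "ratio") {
    ifelse(model$coefficients > 0, "numerator", "denominator")
  } else {
    ifelse(model$coefficients > 0, "positive", "negative")
  }
  data.frame(feature = model$features, sign = as.integer(model$coefficients),
             side = side, stringsAsFactors = FALSE)
}

#' Write a model barcode as TSV
#'
#' @param model A `btr_model`.
#' @param path Output path.
#' @export
write_barcode_tsv <- function(model, path) {
  utils::write.table(barcode_table(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
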