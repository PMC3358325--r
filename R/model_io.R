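MODEL_MAGIC <- "eccloc-model"
MODEL_VERSION <- 1L

# "+ 0" canonicalizes IEEE negative zeros so re-saving a loaded model is
# byte-identical.
serialize_learner <- function(l) list(w = l$w + 0, b = l$b + 0)

serialize_classifier <- function(model) {
  if (inherits(model, "br_model")) {
    list(kind = "br", universe = model$universe, p = model$p,
         seed = model$seed, spec = unclass(model$spec),
         learners = lapply(model$learners, serialize_learner))
  } else if (inherits(model, "ecc_model")) {
    list(kind = "ecc", universe = model$universe, p = model$p,
         m = model$m, threshold = model$threshold,
         subset_fraction = model$subset_fraction, seed = model$seed,
         spec = unclass(model$spec),
         chains = lapply(model$chains, function(ch) {
           list(chain_order = ch$chain_order,
                learners = lapply(ch$learners, serialize_learner))
         }))
  } else {
    stop_user("unknown classifier class")
  }
}

deserialize_classifier <- function(x) {
  spec <- structure(x$spec, class = "learner_spec")
  if (x$kind == "br") {
    structure(list(universe = x$universe, learners = x$learners,
                   p = x$p, spec = spec, seed = x$seed),
              class = "br_model")
  } else {
    chains <- lapply(x$chains, function(ch) {
      structure(list(universe = x$universe,
                     chain_order = as.integer(ch$chain_order),
                     learners = ch$learners, p = x$p, spec = spec,
                     seed = x$seed),
                class = "cc_model")
    })
    structure(list(universe = x$universe, chains = chains, m = x$m,
                   threshold = x$threshold,
                   subset_fraction = x$subset_fraction, p = x$p,
                   spec = spec, seed = x$seed),
              class = "ecc_model")
  }
}

#' Save a trained localizer to a versioned text archive
#'
#' The archive is JSON; numeric values are written with 17 significant
#' digits so that every double round-trips exactly and a loaded model
#' reproduces byte-identical predictions. Saving a freshly loaded model
#' reproduces the file byte for byte.
#'
#' @param model A trained `localizer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "localizer"))
  payload <- list(
    magic = MODEL_MAGIC, version = MODEL_VERSION,
    config = unclass(model$config), universe = model$universe,
    index = if (is.null(model$index)) NULL else
      list(term = model$index$term, idx = model$index$index),
    go_map = if (is.null(model$go_map)) NULL else
      list(accession = model$go_map$accession, term = model$go_map$term),
    route_counts = list(route = names(model$route_counts),
                        n = as.integer(model$route_counts)),
    models = lapply(model$models, serialize_classifier))
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = FALSE)
  readr::write_lines(as.character(json), path)
  invisible(path)
}

#' Load a localizer saved by [save_model()]
#'
#' @param path Path to a model archive.
#' @return A `localizer`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop_user("not an eccloc model archive: %s", path))
  if (!identical(payload$magic, MODEL_MAGIC)) {
    stop_user("not an eccloc model archive: %s", path)
  }
  if (!identical(as.integer(payload$version), MODEL_VERSION)) {
    stop_user("unsupported model archive version %s (expected %d)",
              payload$version, MODEL_VERSION)
  }
  cfg <- payload$config
  config <- localizer_config(
    feature_mode = cfg$feature_mode, classifier = cfg$classifier,
    evalue_max = cfg$evalue_max, identity_min = cfg$identity_min,
    m = cfg$m, threshold = cfg$threshold,
    subset_fraction = cfg$subset_fraction, C = cfg$C,
    learner = cfg$learner, seed = cfg$seed)
  index <- if (is.null(payload$index)) NULL else
    tibble(term = as.character(payload$index$term),
           index = as.integer(payload$index$idx))
  go_map <- if (is.null(payload$go_map)) NULL else
    tibble(accession = as.character(payload$go_map$accession),
           term = as.character(payload$go_map$term))
  models <- lapply(payload$models, deserialize_classifier)
  counts <- as.table(setNames(as.integer(payload$route_counts$n),
                              payload$route_counts$route))
  structure(list(version = MODEL_VERSION, config = config,
                 universe = as.character(payload$universe), index = index,
                 go_map = go_map, models = models, route_counts = counts),
            class = "localizer")
}
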