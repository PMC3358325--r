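#' Bundle the four inputs of a localization dataset
#'
#' @param records Sequence tibble (`id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param labels A [label_matrix()] (optional for pure prediction sets).
#' @param go_map GO annotation tibble (`accession`, `term`) or `NULL`.
#' @param hits Homology tibble (`query`, `subject`, `identity`, `evalue`) or
#'   `NULL`; with no homology information every protein takes the
#'   dipeptide-composition route.
#' @return An object of class `loc_data`.
#' @export
loc_data <- function(records, labels = NULL, go_map = NULL, hits = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (!is.null(labels)) {
    missing <- setdiff(records$id, rownames(labels))
    if (length(missing) > 0L) {
      stop_user("no labels for protein %s", missing[1L])
    }
    labels <- labels[records$id, , drop = FALSE]
    class(labels) <- c("label_matrix", "matrix", "array")
  }
  structure(list(records = records, labels = labels,
                 go_map = go_map, hits = hits),
            class = "loc_data")
}

#' @export
print.loc_data <- function(x, ...) {
  cat(sprintf("<loc_data> %d proteins%s, %d GO annotation rows, %d homology hits\n",
              nrow(x$records),
              if (is.null(x$labels)) "" else
                sprintf(" x %d locations", ncol(x$labels)),
              if (is.null(x$go_map)) 0L else nrow(x$go_map),
              if (is.null(x$hits)) 0L else nrow(x$hits)))
  invisible(x)
}

#' Configuration of the localization pipeline
#'
#' @param feature_mode `"fallback"` (GO homology transfer with dipeptide
#'   composition as backup; the default) or `"concat"` (one concatenated
#'   vector).
#' @param classifier `"ecc"` (default) or `"br"`.
#' @param evalue_max,identity_min Homology filter cutoffs (defaults 1e-3 and
#'   60 percent, inclusive).
#' @param m,threshold,subset_fraction Ensemble parameters, see [train_ecc()].
#' @param C Regularization constant of the linear base learner.
#' @param learner `"svm"` (linear max-margin, default) or `"centroid"`.
#' @param seed Integer seed for all randomness.
#' @return An object of class `localizer_config`.
#' @export
localizer_config <- function(feature_mode = c("fallback", "concat"),
                             classifier = c("ecc", "br"),
                             evalue_max = 1e-3, identity_min = 60,
                             m = 10L, threshold = 0.5,
                             subset_fraction = 0.67, C = 1,
                             learner = c("svm", "centroid"), seed = 1L) {
  structure(list(feature_mode = match.arg(feature_mode),
                 classifier = match.arg(classifier),
                 evalue_max = evalue_max, identity_min = identity_min,
                 m = as.integer(m), threshold = threshold,
                 subset_fraction = subset_fraction, C = C,
                 learner = match.arg(learner), seed = as.integer(seed)),
            class = "localizer_config")
}

config_learner <- function(config) {
  if (config$learner == "centroid") centroid_learner()
  else linear_learner(C = config$C)
}

train_route_classifier <- function(features, labels, config) {
  learner <- config_learner(config)
  if (config$classifier == "br") {
    train_br(features, labels, learner = learner, seed = config$seed)
  } else {
    train_ecc(features, labels, m = config$m,
              subset_fraction = config$subset_fraction, learner = learner,
              threshold = config$threshold, seed = config$seed)
  }
}

predict_route_classifier <- function(model, features) {
  out <- if (inherits(model, "br_model")) predict_br(model, features)
         else predict_ecc(model, features)
  list(pred = out$pred, votes = out[[2L]])
}

#' Train the full localizer
#'
#' Builds the GO index from the annotation corpus, routes every training
#' protein to a feature representation, and fits one multi-label classifier
#' per route (a single classifier in `concat` mode).
#'
#' @param data A [loc_data()] with labels.
#' @param config A [localizer_config()].
#' @return An object of class `localizer`.
#' @export
train_localizer <- function(data, config = localizer_config()) {
  stopifnot(inherits(data, "loc_data"))
  if (is.null(data$labels)) stop_user("training data has no labels")
  index <- if (!is.null(data$go_map) && nrow(data$go_map) > 0L) {
    build_go_index(data$go_map)
  } else NULL
  bundles <- build_feature_bundles(data$records, data$hits, data$go_map,
                                   index, mode = config$feature_mode,
                                   evalue_max = config$evalue_max,
                                   identity_min = config$identity_min)
  models <- lapply(bundles$matrices, function(m) {
    train_route_classifier(m, data$labels[rownames(m), , drop = FALSE],
                           config)
  })
  structure(list(version = 1L, config = config,
                 universe = colnames(data$labels), index = index,
                 go_map = data$go_map, models = models,
                 route_counts = table(bundles$routing$source)),
            class = "localizer")
}

#' @export
print.localizer <- function(x, ...) {
  cat(sprintf("<localizer> %s / %s mode, %d locations; routes: %s\n",
              toupper(x$config$classifier), x$config$feature_mode,
              length(x$universe),
              paste(sprintf("%s=%d", names(x$route_counts),
                            as.integer(x$route_counts)), collapse = ", ")))
  invisible(x)
}

#' Predict subcellular locations for query proteins
#'
#' Each query is routed the same way as at training time: the GO
#' homology-transfer vector when it is defined, otherwise dipeptide
#' composition (or the concatenated vector in `concat` mode). Queries whose
#' route has no trained model (possible on tiny training sets) are scored
#' through the other route's representation.
#'
#' @param model A trained `localizer`.
#' @param data A [loc_data()] (labels not required) or a record tibble.
#' @return A tibble with columns `id`, `source` (feature route), `locations`
#'   (list-column of predicted location names) and `votes` (list-column of
#'   the per-label vote/score vector). The binary prediction matrix and the
#'   vote matrix are attached as attributes `pred` and `votes`.
#' @export
predict_localizer <- function(model, data) {
  if (!inherits(data, "loc_data")) data <- loc_data(data)
  bundles <- build_feature_bundles(data$records, data$hits, model$go_map,
                                   model$index,
                                   mode = model$config$feature_mode,
                                   evalue_max = model$config$evalue_max,
                                   identity_min = model$config$identity_min)
  n <- nrow(data$records)
  L <- length(model$universe)
  pred <- matrix(0L, n, L, dimnames = list(data$records$id, model$universe))
  votes <- matrix(0, n, L, dimnames = list(data$records$id, model$universe))
  routing <- bundles$routing
  for (src in unique(routing$source)) {
    ids <- routing$id[routing$source == src]
    feats <- bundles$matrices[[src]][ids, , drop = FALSE]
    use <- src
    if (is.null(model$models[[use]])) {
      # no model was trained on this route; re-extract through the other one
      other <- setdiff(names(model$models), src)
      if (length(other) == 0L) stop_user("model has no trained route")
      use <- other[1L]
      feats <- switch(use,
        DC = do.call(rbind, lapply(
          setNames(data$records$sequence[match(ids, data$records$id)], ids),
          dipeptide_composition)),
        GO = stop_user(
          "queries on the DC route cannot be scored by a GO-only model"),
        feats)
    }
    out <- predict_route_classifier(model$models[[use]], feats)
    pred[ids, ] <- out$pred
    votes[ids, ] <- out$votes
  }
  res <- tibble(
    id = data$records$id,
    source = routing$source[match(data$records$id, routing$id)],
    locations = lapply(seq_len(n),
                       function(i) model$universe[pred[i, ] == 1L]),
    votes = lapply(seq_len(n), function(i) votes[i, ]))
  attr(res, "pred") <- pred
  attr(res, "votes") <- votes
  res
}
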