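align_predictions <- function(truth, pred) {
  stopifnot(is.matrix(pred))
  missing <- setdiff(rownames(truth), rownames(pred))
  if (length(missing) > 0L) {
    stop_user("missing prediction for protein %s", missing[1L])
  }
  if (length(intersect(colnames(truth), colnames(pred))) == 0L) {
    stop_user("prediction and truth share no locations")
  }
  pred[rownames(truth), colnames(truth), drop = FALSE]
}

#' Locative success rates
#'
#' Scoring over (protein, location) pairs — "locative proteins": a protein
#' with k true locations contributes k pairs. The per-location rate is the
#' fraction of that location's proteins whose predicted set contains it, the
#' average is the unweighted mean over non-empty locations, and the overall
#' rate is the total number of recovered pairs over N(loc) — equivalently
#' the n-weighted mean of the per-location rates. Average and overall can
#' differ widely when location sizes are unbalanced.
#'
#' @param truth A [label_matrix()].
#' @param pred Binary prediction matrix with matching row/column names
#'   (e.g. `attr(predict_localizer(...), "pred")`).
#' @return List with `per_location` (tibble: location, n, correct, rate),
#'   `average` and `overall`.
#' @export
locative_success <- function(truth, pred) {
  pred <- align_predictions(truth, pred)
  tm <- unclass(truth)
  n_i <- colSums(tm)
  correct <- colSums(tm == 1L & pred == 1L)
  per <- tibble(location = colnames(tm), n = as.integer(n_i),
                correct = as.integer(correct),
                rate = unname(ifelse(n_i > 0, correct / n_i, NA_real_)))
  list(per_location = per,
       average = mean(per$rate[per$n > 0]),
       overall = sum(correct) / sum(n_i))
}

#' Exact-match success rates
#'
#' A protein scores 1 only when its predicted location set equals its true
#' set — no underprediction and no overprediction. Rates are reported per
#' true multiplicity (number of true locations) and overall across all
#' proteins.
#'
#' @inheritParams locative_success
#' @return List with `by_multiplicity` (tibble: multiplicity, n, correct,
#'   rate) and `overall`.
#' @export
exact_match <- function(truth, pred) {
  pred <- align_predictions(truth, pred)
  tm <- unclass(truth)
  hit <- rowSums(tm != pred) == 0L
  k <- rowSums(tm)
  by <- tibble(multiplicity = as.integer(sort(unique(k)))) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(k == .data$multiplicity),
                  correct = sum(hit[k == .data$multiplicity]),
                  rate = .data$correct / .data$n) |>
    dplyr::ungroup()
  list(by_multiplicity = by, overall = mean(hit))
}

#' Full evaluation report
#'
#' Aggregates the locative and exact-match scorers into one object with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams locative_success
#' @return An object of class `eccloc_report`.
#' @export
evaluate_predictions <- function(truth, pred) {
  structure(list(locative = locative_success(truth, pred),
                 exact = exact_match(truth, pred),
                 n_seq = nrow(truth), n_loc = n_locative(truth)),
            class = "eccloc_report")
}

#' @export
print.eccloc_report <- function(x, ...) {
  cat(sprintf("<eccloc_report> %d proteins, %d locative proteins\n",
              x$n_seq, x$n_loc))
  print(x$locative$per_location, n = Inf)
  cat(sprintf("Average  %.4f\nOverall  %.4f\n",
              x$locative$average, x$locative$overall))
  cat("Exact match by multiplicity:\n")
  print(x$exact$by_multiplicity)
  cat(sprintf("Overall exact match  %.4f\n", x$exact$overall))
  invisible(x)
}

#' @export
tidy.eccloc_report <- function(x, ...) {
  dplyr::bind_rows(
    x$locative$per_location |>
      dplyr::transmute(metric = "locative", group = .data$location,
                       n = .data$n, correct = .data$correct,
                       rate = .data$rate),
    x$exact$by_multiplicity |>
      dplyr::transmute(metric = "exact_match",
                       group = as.character(.data$multiplicity),
                       n = .data$n, correct = .data$correct,
                       rate = .data$rate))
}

#' @export
glance.eccloc_report <- function(x, ...) {
  tibble(n_seq = x$n_seq, n_loc = x$n_loc,
         average_rate = x$locative$average,
         overall_locative_rate = x$locative$overall,
         overall_exact_match = x$exact$overall)
}

#' @export
autoplot.eccloc_report <- function(object, ...) {
  per <- object$locative$per_location
  per$location <- factor(per$location, levels = per$location)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$location, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$locative$overall,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "locative success rate",
                  title = "Per-location success rates",
                  subtitle = sprintf("average %.3f, overall %.3f (dashed)",
                                     object$locative$average,
                                     object$locative$overall)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write / read an evaluation report as TSV
#'
#' Two tab-separated tables: per-location counts with `Average` and
#' `Overall` summary lines, and exact-match counts by multiplicity. Rates
#' are stored as counts (`n`, `correct`) so the round trip is lossless.
#'
#' @param report An `eccloc_report`.
#' @param path Output path.
#' @return `path` invisibly; `read_report()` returns the reconstructed
#'   `eccloc_report`.
#' @export
write_report <- function(report, path) {
  per <- report$locative$per_location
  by <- report$exact$by_multiplicity
  lines <- c("#eccloc-report\tv1",
             "locative\tlocation\tn\tcorrect",
             sprintf("locative\t%s\t%d\t%d", per$location, per$n, per$correct),
             "exact\tmultiplicity\tn\tcorrect",
             sprintf("exact\t%d\t%d\t%d", by$multiplicity, by$n, by$correct))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#eccloc-report")) {
    stop_user("not an eccloc report: %s", path)
  }
  body <- lines[-1L]
  f <- strsplit(body[!startsWith(body, "locative\tlocation") &
                       !startsWith(body, "exact\tmultiplicity")],
                "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  loc <- m[m[, 1L] == "locative", , drop = FALSE]
  ex <- m[m[, 1L] == "exact", , drop = FALSE]
  per <- tibble(location = loc[, 2L], n = as.integer(loc[, 3L]),
                correct = as.integer(loc[, 4L])) |>
    dplyr::mutate(rate = ifelse(.data$n > 0, .data$correct / .data$n,
                                NA_real_))
  by <- tibble(multiplicity = as.integer(ex[, 2L]),
               n = as.integer(ex[, 3L]),
               correct = as.integer(ex[, 4L])) |>
    dplyr::mutate(rate = .data$correct / .data$n)
  structure(list(
    locative = list(per_location = per,
                    average = mean(per$rate[per$n > 0]),
                    overall = sum(per$correct) / sum(per$n)),
    exact = list(by_multiplicity = by,
                 overall = sum(by$correct) / sum(by$n)),
    n_seq = sum(by$n), n_loc = sum(per$n)),
    class = "eccloc_report")
}

#' Cross-validated predictions (jackknife or K-fold)
#'
#' The reference protocol is the jackknife (leave-one-out): for each protein
#' the classifiers are retrained on the other N-1 proteins and applied to
#' the held-out one. Feature routing is label-free — the GO index is built
#' once from the annotation corpus and each protein's own accession is
#' excluded from its homology set — so feature bundles are shared across
#' folds and only the classifiers are refitted. `folds = K` gives the
#' K-fold variant; `folds = N` is identical to the jackknife.
#'
#' @param data A [loc_data()] with labels.
#' @param config A [localizer_config()].
#' @param folds Number of folds, or `NULL` (default) for the jackknife.
#' @return List with `pred` (binary matrix over all proteins), `votes`, and
#'   `report` (an `eccloc_report` against the true labels).
#' @export
jackknife_predict <- function(data, config = localizer_config(),
                              folds = NULL) {
  stopifnot(inherits(data, "loc_data"))
  if (is.null(data$labels)) stop_user("evaluation requires labels")
  N <- nrow(data$records)
  if (N < 2L) stop_user("need at least 2 proteins")
  if (is.null(folds)) folds <- N
  folds <- as.integer(folds)
  stopifnot(folds >= 2L, folds <= N)
  index <- if (!is.null(data$go_map) && nrow(data$go_map) > 0L) {
    build_go_index(data$go_map)
  } else NULL
  bundles <- build_feature_bundles(data$records, data$hits, data$go_map,
                                   index, mode = config$feature_mode,
                                   evalue_max = config$evalue_max,
                                   identity_min = config$identity_min)
  set.seed(config$seed)
  assignment <- sample(rep_len(seq_len(folds), N))
  L <- ncol(data$labels)
  ids <- data$records$id
  pred <- matrix(0L, N, L, dimnames = list(ids, colnames(data$labels)))
  votes <- matrix(0, N, L, dimnames = list(ids, colnames(data$labels)))
  routing <- bundles$routing
  for (f in seq_len(folds)) {
    test_ids <- ids[assignment == f]
    train_ids <- setdiff(ids, test_ids)
    models <- list()
    for (src in names(bundles$matrices)) {
      rows <- intersect(rownames(bundles$matrices[[src]]), train_ids)
      if (length(rows) == 0L) next
      models[[src]] <- train_route_classifier(
        bundles$matrices[[src]][rows, , drop = FALSE],
        data$labels[rows, , drop = FALSE], config)
    }
    if (length(models) == 0L) stop_user("fold %d has no trainable route", f)
    for (id in test_ids) {
      src <- routing$source[routing$id == id]
      feats <- bundles$matrices[[src]][id, , drop = FALSE]
      use <- src
      if (is.null(models[[use]])) {
        use <- names(models)[1L]
        if (use == "DC" && src == "GO") {
          feats <- matrix(dipeptide_composition(
            data$records$sequence[match(id, ids)]), nrow = 1L)
        } else if (use == "GO" && src == "DC") {
          stop_user("protein %s has no usable homology and no DC model", id)
        }
      }
      out <- predict_route_classifier(models[[use]], feats)
      pred[id, ] <- out$pred
      votes[id, ] <- out$votes
    }
  }
  list(pred = pred, votes = votes,
       report = evaluate_predictions(data$labels, pred))
}
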