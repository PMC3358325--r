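as_binary_labels <- function(labels) {
  m <- unclass(labels)
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)))
  m
}

check_width <- function(X, p, what) {
  if (ncol(X) != p) {
    stop_user("%s: feature width %d does not match training width %d",
              what, ncol(X), p)
  }
}

as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

# Empty predicted sets fall back to the single highest-scoring label,
# lowest index on ties (every training protein has >= 1 location).
apply_fallback <- function(pred, scores) {
  empty <- which(rowSums(pred) == 0L)
  for (i in empty) pred[i, which.max(scores[i, ])] <- 1L
  pred
}

#' Train a Binary Relevance model
#'
#' Decomposes an L-label problem into L independent binary classifiers: for
#' label j the positive training samples are the proteins annotated to
#' location j and the negatives are all remaining proteins.
#'
#' @param features Numeric matrix, rows aligned with `labels`.
#' @param labels A [label_matrix()] (or binary matrix) with one column per
#'   location.
#' @param learner Base learner specification ([linear_learner()] default).
#' @param seed Integer seed (the default learners are deterministic; the seed
#'   is recorded for reproducibility of any stochastic learner).
#' @return An object of class `br_model`.
#' @export
train_br <- function(features, labels, learner = linear_learner(), seed = 1L) {
  Y <- as_binary_labels(labels)
  features <- as.matrix(features)
  if (nrow(features) != nrow(Y)) {
    stop_user("features (%d rows) and labels (%d rows) are misaligned",
              nrow(features), nrow(Y))
  }
  set.seed(seed)
  learners <- lapply(seq_len(ncol(Y)), function(j) {
    fit_learner(learner, features, ifelse(Y[, j] == 1L, 1, -1))
  })
  structure(list(universe = colnames(Y), learners = learners,
                 p = ncol(features), spec = learner, seed = seed),
            class = "br_model")
}

#' Predict with a Binary Relevance model
#'
#' The prediction set is the union of the labels whose classifier fires
#' (decision value > 0); an all-negative query falls back to the label with
#' the highest decision score.
#'
#' @param model A `br_model`.
#' @param features Numeric vector (one query) or matrix (one query per row).
#' @return List with `pred` (binary matrix, universe column order) and
#'   `scores` (decision values).
#' @export
predict_br <- function(model, features) {
  X <- as_row_matrix(features)
  check_width(X, model$p, "predict_br")
  scores <- vapply(model$learners, function(l) learner_decision(l, X),
                   numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(rownames(X), model$universe))
  pred <- ifelse(scores > 0, 1L, 0L)
  list(pred = apply_fallback(pred, scores), scores = scores)
}

#' Train a Classifier Chain
#'
#' Classifiers are linked along a permutation of the labels; the k-th
#' classifier in the chain predicts label `order[k]` from the base feature
#' vector extended with the 0/1 associations of the k-1 previous chain
#' labels. At training time the augmentation uses the ground-truth labels;
#' at prediction time the chain consumes its own predicted bits.
#'
#' @param features Numeric matrix, rows aligned with `labels`.
#' @param labels A [label_matrix()] or binary matrix.
#' @param chain_order Permutation of `1..L` (default identity).
#' @param learner Base learner specification.
#' @param seed Integer seed, recorded.
#' @return An object of class `cc_model`.
#' @export
train_cc <- function(features, labels, chain_order = NULL,
                     learner = linear_learner(), seed = 1L) {
  Y <- as_binary_labels(labels)
  features <- as.matrix(features)
  L <- ncol(Y)
  if (is.null(chain_order)) chain_order <- seq_len(L)
  if (!identical(sort(as.integer(chain_order)), seq_len(L))) {
    stop_user("chain_order must be a permutation of 1..%d", L)
  }
  if (nrow(features) != nrow(Y)) {
    stop_user("features (%d rows) and labels (%d rows) are misaligned",
              nrow(features), nrow(Y))
  }
  set.seed(seed)
  learners <- vector("list", L)
  aug <- features
  for (k in seq_len(L)) {
    j <- chain_order[k]
    learners[[k]] <- fit_learner(learner, aug, ifelse(Y[, j] == 1L, 1, -1))
    aug <- cbind(aug, as.numeric(Y[, j]))
  }
  structure(list(universe = colnames(Y), chain_order = as.integer(chain_order),
                 learners = learners, p = ncol(features), spec = learner,
                 seed = seed),
            class = "cc_model")
}

#' Predict with a Classifier Chain
#'
#' Labels are produced in chain order, each classifier consuming the
#' previously predicted bits; the output is reported in universe order.
#'
#' @param model A `cc_model`.
#' @param features Numeric vector or matrix of queries.
#' @return List with `pred` (binary matrix in universe order) and `scores`
#'   (decision values in universe order).
#' @export
predict_cc <- function(model, features) {
  X <- as_row_matrix(features)
  check_width(X, model$p, "predict_cc")
  L <- length(model$chain_order)
  pred <- matrix(0L, nrow(X), L,
                 dimnames = list(rownames(X), model$universe))
  scores <- matrix(0, nrow(X), L,
                   dimnames = list(rownames(X), model$universe))
  aug <- X
  for (k in seq_len(L)) {
    j <- model$chain_order[k]
    s <- learner_decision(model$learners[[k]], aug)
    scores[, j] <- s
    pred[, j] <- as.integer(s > 0)
    aug <- cbind(aug, as.numeric(pred[, j]))
  }
  list(pred = pred, scores = scores)
}

#' Train an Ensemble of Classifier Chains
#'
#' Trains `m` classifier chains, each with an independent random label
#' permutation and a random subset of the training rows (a fraction
#' `subset_fraction`, drawn without replacement). Subsets in which some label
#' column is single-class are redrawn up to five times; a still-degenerate
#' column is handled by the constant-class learner rule. All randomness
#' derives from `seed`.
#'
#' @param features Numeric matrix, rows aligned with `labels`.
#' @param labels A [label_matrix()] or binary matrix.
#' @param m Number of chains (>= 1, default 10).
#' @param subset_fraction Fraction of rows per chain, in (0, 1] (default 0.67).
#' @param learner Base learner specification.
#' @param threshold Vote threshold t in (0, 1) used at prediction (default
#'   0.5; a label is predicted when its vote share is `>= t`).
#' @param seed Integer seed.
#' @return An object of class `ecc_model`.
#' @export
train_ecc <- function(features, labels, m = 10L, subset_fraction = 0.67,
                      learner = linear_learner(), threshold = 0.5,
                      seed = 1L) {
  if (!is.numeric(m) || m < 1L) stop_user("ensemble size m must be >= 1")
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop_user("subset_fraction must be in (0, 1]")
  }
  if (threshold <= 0 || threshold >= 1) {
    stop_user("threshold must be in (0, 1)")
  }
  Y <- as_binary_labels(labels)
  features <- as.matrix(features)
  N <- nrow(Y)
  L <- ncol(Y)
  size <- ceiling(subset_fraction * N)
  # Draw every chain's permutation and subset before any fitting, so the
  # draws depend only on `seed` and not on what a learner does with the RNG.
  set.seed(seed)
  draws <- lapply(seq_len(m), function(i) {
    ord <- sample.int(L)
    rows <- sample.int(N, size)
    for (attempt in seq_len(5L)) {
      degenerate <- any(apply(Y[rows, , drop = FALSE], 2L,
                              function(col) length(unique(col)) == 1L))
      if (!degenerate || size == N) break
      rows <- sample.int(N, size)
    }
    list(ord = ord, rows = rows)
  })
  chains <- lapply(draws, function(d) {
    train_cc(features[d$rows, , drop = FALSE], Y[d$rows, , drop = FALSE],
             chain_order = d$ord, learner = learner, seed = seed)
  })
  structure(list(universe = colnames(Y), chains = chains, m = as.integer(m),
                 threshold = threshold, subset_fraction = subset_fraction,
                 p = ncol(features), spec = learner, seed = seed),
            class = "ecc_model")
}

#' Predict with an Ensemble of Classifier Chains
#'
#' Each chain votes 0/1 per label; votes are summed and normalized by `m`
#' into a score vector `W` in \[0,1\] whose entries are multiples of `1/m`.
#' Labels with `W >= threshold` form the prediction set; an empty set falls
#' back to the label with the largest vote share (lowest index on ties).
#'
#' @param model An `ecc_model`.
#' @param features Numeric vector or matrix of queries.
#' @param threshold Optional override of the model's vote threshold.
#' @return List with `pred` (binary matrix) and `votes` (the normalized vote
#'   matrix `W`).
#' @export
predict_ecc <- function(model, features, threshold = NULL) {
  X <- as_row_matrix(features)
  check_width(X, model$p, "predict_ecc")
  t <- if (is.null(threshold)) model$threshold else threshold
  votes <- matrix(0, nrow(X), length(model$universe),
                  dimnames = list(rownames(X), model$universe))
  for (chain in model$chains) {
    votes <- votes + predict_cc(chain, X)$pred
  }
  votes <- votes / model$m
  pred <- ifelse(votes >= t, 1L, 0L)
  list(pred = apply_fallback(pred, votes), votes = votes)
}
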