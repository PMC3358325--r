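#' Linear max-margin base learner specification
#'
#' The base binary classifier used inside Binary Relevance and the classifier
#' chains: an L2-regularized linear support vector machine (fitted with the
#' linear kernel of \pkg{e1071}). The fitted state is collapsed to its affine
#' decision function `f(x) = x . w + b`, predicted class `+1` when
#' `f(x) > 0`; this keeps fitted models exactly serializable.
#'
#' @param C Regularization constant (> 0, default 1).
#' @return A learner specification usable by the `train_*` functions.
#' @export
linear_learner <- function(C = 1) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop_user("regularization constant C must be > 0")
  }
  structure(list(type = "svm", C = C), class = "learner_spec")
}

#' Nearest-centroid base learner specification
#'
#' A trivially learnable linear classifier (decision = difference of squared
#' distances to the class centroids) satisfying the same contract as
#' [linear_learner()]. Useful for hand-checkable fixtures.
#' @export
centroid_learner <- function() {
  structure(list(type = "centroid"), class = "learner_spec")
}

# Fit a binary learner on features X and targets y in {-1, +1}; returns the
# affine decision (w, b). Single-class targets yield a constant learner
# (w = 0, b = sign of the class), per the degenerate-column contract.
fit_learner <- function(spec, X, y) {
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  p <- ncol(X)
  if (length(unique(y)) == 1L) {
    return(list(w = numeric(p), b = as.numeric(y[1L])))
  }
  if (spec$type == "centroid") {
    mu_pos <- colMeans(X[y == 1, , drop = FALSE])
    mu_neg <- colMeans(X[y == -1, , drop = FALSE])
    w <- mu_pos - mu_neg
    b <- -(sum(mu_pos^2) - sum(mu_neg^2)) / 2
    return(list(w = as.numeric(w), b = as.numeric(b)))
  }
  fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = spec$C, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values toward whichever class it saw first;
  # normalize so that a positive decision means class +1.
  own <- as.numeric(as.character(predict(fit, X)))
  mine <- as.numeric(X %*% w + b)
  if (mean((mine > 0) == (own > 0)) < 0.5) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

# Affine decision values for a row matrix X.
learner_decision <- function(learner, X) {
  as.numeric(X %*% learner$w + learner$b)
}
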