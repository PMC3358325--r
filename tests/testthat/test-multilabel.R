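test_that("binary relevance fits one learner per label and unions predictions", {
  fx <- toy_features(n = 40, L = 2)
  model <- train_br(fx$X, fx$Y, seed = 1)
  expect_length(model$learners, 2L)
  out <- predict_br(model, fx$X)
  expect_equal(unname(out$pred[, 1]), unname(fx$Y[, 1]))  # separable column

  # all-positive label column -> constant-positive learner
  Y <- fx$Y
  Y[, 2] <- 1L
  m2 <- train_br(fx$X, Y)
  expect_equal(m2$learners[[2]]$w, c(0, 0))
  expect_equal(m2$learners[[2]]$b, 1)
  expect_true(all(predict_br(m2, fx$X)$pred[, 2] == 1L))

  expect_error(predict_br(model, matrix(0, 1, 5)), "width")
  expect_error(train_br(fx$X[1:10, ], fx$Y), "misaligned")
})

test_that("an all-negative BR query falls back to the top decision score", {
  model <- structure(list(universe = c("a", "b", "c"),
                          learners = list(const_learner(-0.2),
                                          const_learner(-0.9),
                                          const_learner(-0.5)),
                          p = 1L, spec = linear_learner(), seed = 1L),
                     class = "br_model")
  out <- predict_br(model, matrix(0, 1, 1))
  expect_equal(unname(out$pred[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(out$scores[1, ]), c(-0.2, -0.9, -0.5))

  all_pos <- structure(list(universe = c("a", "b"),
                            learners = list(const_learner(1),
                                            const_learner(2)),
                            p = 1L, spec = linear_learner(), seed = 1L),
                       class = "br_model")
  expect_equal(unname(predict_br(all_pos, matrix(0, 1, 1))$pred[1, ]),
               c(1L, 1L))
})

test_that("classifier chains augment with previous labels and learn copies", {
  fx <- toy_features(n = 40, L = 2, copy = TRUE)
  model <- train_cc(fx$X, fx$Y, chain_order = c(1, 2))
  # learner 2 consumes one augmented bit
  expect_length(model$learners[[2]]$w, ncol(fx$X) + 1L)
  out <- predict_cc(model, fx$X)
  expect_equal(unname(out$pred), unname(fx$Y))

  expect_error(train_cc(fx$X, fx$Y, chain_order = c(1, 1)), "permutation")

  # a chain whose second learner copies the previous predicted bit
  copycat <- structure(list(universe = c("a", "b"), chain_order = c(1L, 2L),
                            learners = list(list(w = c(1, 0), b = 0),
                                            list(w = c(0, 0, 1), b = -0.5)),
                            p = 2L, spec = linear_learner(), seed = 1L),
                       class = "cc_model")
  set.seed(9)
  Q <- matrix(rnorm(40), 20, 2)
  out2 <- predict_cc(copycat, Q)
  expect_equal(out2$pred[, "b"], out2$pred[, "a"])
  expect_identical(out2, predict_cc(copycat, Q))   # deterministic
})

test_that("chain predictions reproduce the hand-computed centroid oracle", {
  # 4 samples, 1 feature, 2 identical labels, chain order (1, 2).
  # Centroid arithmetic done by hand:
  #   learner1: mu+ = 1.5, mu- = -1.5 -> w = 3, b = 0
  #   learner2 on (x, y1): mu+ = (1.5, 1), mu- = (-1.5, 0)
  #             -> w = (3, 1), b = -((1.5^2 + 1) - 1.5^2)/2 = -0.5
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  Y <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 0L, 1L, 1L))
  model <- train_cc(X, Y, chain_order = c(1, 2),
                    learner = centroid_learner())
  expect_equal(model$learners[[1]]$w, 3)
  expect_equal(model$learners[[1]]$b, 0)
  expect_equal(model$learners[[2]]$w, c(3, 1))
  expect_equal(model$learners[[2]]$b, -0.5)

  out <- predict_cc(model, matrix(c(0.5, -0.5, 2, -3), ncol = 1))
  expect_equal(unname(out$pred),
               rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L), c(0L, 0L)))
  expect_equal(unname(out$scores[, "a"]), c(1.5, -1.5, 6, -9))
  expect_equal(unname(out$scores[, "b"]),
               c(3 * 0.5 + 1 - 0.5, 3 * -0.5 + 0 - 0.5,
                 3 * 2 + 1 - 0.5, 3 * -3 + 0 - 0.5))
})

test_that("ECC vote shares are multiples of 1/m, thresholded monotonically", {
  fx <- toy_features(n = 60, L = 3, seed = 3)
  fx$Y[, 3] <- rep(c(1L, 0L), length.out = 60)
  model <- train_ecc(fx$X, fx$Y, m = 5, subset_fraction = 0.6, seed = 11)
  out <- predict_ecc(model, fx$X)
  expect_true(all(out$votes >= 0 & out$votes <= 1))
  expect_true(all(abs(out$votes * 5 - round(out$votes * 5)) < 1e-12))

  lo <- predict_ecc(model, fx$X, threshold = 0.2)$pred
  hi <- predict_ecc(model, fx$X, threshold = 0.9)$pred
  # raising the threshold never adds labels (up to the non-empty fallback)
  gained <- hi == 1L & lo == 0L
  expect_true(all(rowSums(gained) <= 1))
  expect_true(all(rowSums(lo[rowSums(gained) > 0, , drop = FALSE]) == 0))

  # determinism: same data + seed -> identical ensembles
  model2 <- train_ecc(fx$X, fx$Y, m = 5, subset_fraction = 0.6, seed = 11)
  expect_identical(predict_ecc(model2, fx$X), out)
})

test_that("a one-chain full-data ensemble reduces to its classifier chain", {
  fx <- toy_features(n = 30, L = 2, seed = 5)
  model <- train_ecc(fx$X, fx$Y, m = 1, subset_fraction = 1.0, seed = 2)
  chain <- train_cc(fx$X, fx$Y,
                    chain_order = model$chains[[1]]$chain_order, seed = 2)
  set.seed(31)
  Q <- matrix(rnorm(20), 10, 2)
  cc_pred <- predict_cc(chain, Q)$pred
  ecc <- predict_ecc(model, Q)
  expect_true(all(ecc$votes %in% c(0, 1)))
  # equal up to the non-empty fallback rule
  nonempty <- rowSums(cc_pred) > 0
  expect_equal(ecc$pred[nonempty, , drop = FALSE],
               cc_pred[nonempty, , drop = FALSE])
})

test_that("all-zero votes fall back to the lowest-index top label", {
  neg <- structure(list(universe = c("a", "b"), chain_order = c(1L, 2L),
                        learners = list(list(w = 0, b = -1),
                                        list(w = c(0, 0), b = -1)),
                        p = 1L, spec = linear_learner(), seed = 1L),
                   class = "cc_model")
  model <- structure(list(universe = c("a", "b"), chains = list(neg),
                          m = 1L, threshold = 0.5, subset_fraction = 1,
                          p = 1L, spec = linear_learner(), seed = 1L),
                     class = "ecc_model")
  out <- predict_ecc(model, matrix(0, 1, 1))
  expect_equal(unname(out$votes[1, ]), c(0, 0))
  expect_equal(unname(out$pred[1, ]), c(1L, 0L))
})

test_that("single-label BR, CC and one-chain ECC agree exactly", {
  set.seed(17)
  for (i in 1:10) {
    n <- 30
    X <- matrix(rnorm(2 * n), n, 2)
    Y <- matrix(as.integer(X[, 1] + 0.3 * rnorm(n) > 0), ncol = 1,
                dimnames = list(NULL, "only"))
    Q <- matrix(rnorm(10), 5, 2)
    br <- predict_br(train_br(X, Y, seed = i), Q)$pred
    cc <- predict_cc(train_cc(X, Y, seed = i), Q)$pred
    ec <- predict_ecc(train_ecc(X, Y, m = 1, subset_fraction = 1,
                                seed = i), Q)$pred
    # single-label prediction sets after fallback are always {1}
    expect_equal(br, ec)
    expect_true(all(br == 1L))
    expect_true(all(cc %in% c(0L, 1L)))
  }
})

test_that("duplicate conflicting points train and predict the majority class", {
  X <- matrix(c(1, 1, 1, 1, -1), ncol = 1)
  y <- matrix(c(1L, 1L, 1L, 0L, 0L), ncol = 1, dimnames = list(NULL, "l"))
  model <- train_br(X, y)
  expect_equal(unname(predict_br(model, matrix(1, 1, 1))$pred[1, 1]), 1L)
  expect_error(linear_learner(C = -1), "C must be")
})

test_that("ECC matches or beats BR on exactly-copied labels across seeds", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 80
    y1 <- rbinom(n, 1, 0.5)
    y3 <- rbinom(n, 1, 0.5)
    Y <- cbind(a = y1, b = y1, c = y3)   # label b copies label a
    Y[rowSums(Y) == 0, 3] <- 1L
    # features carry a noisy signal for labels a and c only
    X <- cbind(y1 + rnorm(n, sd = 0.8), Y[, 3] + rnorm(n, sd = 0.8),
               rnorm(n))
    tr <- 1:60
    te <- 61:80
    br <- predict_br(train_br(X[tr, ], Y[tr, ], seed = seed),
                     X[te, ])$pred
    ec <- predict_ecc(train_ecc(X[tr, ], Y[tr, ], m = 10, seed = seed),
                      X[te, ])$pred
    em <- function(p) mean(rowSums(p != Y[te, ]) == 0)
    if (em(ec) >= em(br)) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
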