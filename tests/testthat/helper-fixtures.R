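# Brute-force dipeptide-composition oracle: enumerates every length-2 window
# of the sequence directly, independent of the package's implementation.
dc_oracle <- function(sequence) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  dips <- as.vector(sapply(aa, function(x) paste0(x, aa)))
  chars <- strsplit(sequence, "")[[1]]
  std <- chars[chars %in% aa]
  aac <- sapply(aa, function(r) sum(std == r)) / length(std)
  windows <- character()
  for (i in seq_len(nchar(sequence) - 1L)) {
    win <- substr(sequence, i, i + 1L)
    c1 <- substr(win, 1L, 1L)
    c2 <- substr(win, 2L, 2L)
    if (c1 %in% aa && c2 %in% aa) windows <- c(windows, win)
  }
  dc <- sapply(dips, function(d) sum(windows == d)) / length(windows)
  c(aac, dc)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# The hand-counted three-protein toy used throughout the scorer tests:
# truth P1 -> {l1}, P2 -> {l1, l2}, P3 -> {l3};
# pred  P1 -> {l1}, P2 -> {l1},     P3 -> {l2}.
toy_truth <- function() {
  label_matrix(c("P1", "P2", "P3"),
               list("l1", c("l1", "l2"), "l3"),
               universe = c("l1", "l2", "l3"))
}

toy_pred <- function() {
  m <- matrix(0L, 3, 3, dimnames = list(c("P1", "P2", "P3"),
                                        c("l1", "l2", "l3")))
  m["P1", "l1"] <- 1L
  m["P2", "l1"] <- 1L
  m["P3", "l2"] <- 1L
  m
}

# A separable two-cluster feature matrix with labels driven by the first
# coordinate; label 2 copies label 1 when copy = TRUE.
toy_features <- function(n = 40, L = 2, copy = FALSE, seed = 1) {
  set.seed(seed)
  y1 <- rep(c(0L, 1L), length.out = n)
  X <- cbind(ifelse(y1 == 1L, 2, -2) + rnorm(n, sd = 0.3),
             rnorm(n, sd = 0.3))
  Y <- matrix(0L, n, L, dimnames = list(NULL, paste0("l", seq_len(L))))
  Y[, 1] <- y1
  if (L >= 2) Y[, 2] <- if (copy) y1 else rep(c(1L, 1L, 0L, 0L), length.out = n)
  # keep rows non-empty except in copy mode, where col2 must mirror col1
  if (!copy && any(rowSums(Y) == 0)) Y[rowSums(Y) == 0, 1] <- 1L
  X[, 1] <- ifelse(Y[, 1] == 1L, 2, -2) + rnorm(n, sd = 0.3)
  list(X = X, Y = Y)
}

# A constant-decision binary learner state, for hand-built models.
const_learner <- function(score, p = 1L) list(w = numeric(p), b = score)
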