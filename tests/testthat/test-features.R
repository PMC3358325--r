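test_that("GO index renumbers terms lexicographically and deterministically", {
  gm <- tibble::tibble(accession = c("A", "A", "B"),
                       term = c("GO:0005622", "GO:0004866", "GO:0004869"))
  idx <- build_go_index(gm)
  expect_equal(idx$term, c("GO:0004866", "GO:0004869", "GO:0005622"))
  expect_equal(idx$index, 1:3)
  expect_identical(idx, build_go_index(gm))

  shared <- tibble::tibble(accession = c("A", "B"),
                           term = c("GO:0000001", "GO:0000001"))
  expect_equal(nrow(build_go_index(shared)), 1L)
  expect_error(build_go_index(tibble::tibble(accession = character(),
                                             term = character())),
               "no GO terms")
})

test_that("homology filtering is inclusive at 60%, drops self, dedups", {
  hits <- tibble::tibble(
    query = c("Q", "Q", "Q", "Q", "Q", "X"),
    subject = c("S1", "S2", "Q", "S1", "S3", "S9"),
    identity = c(60.0, 59.9, 100, 70, 80, 99),
    evalue = c(1e-5, 1e-5, 0, 1e-9, 1e-2, 1e-30))
  hs <- filter_homologs(hits, "Q", evalue_max = 1e-3, identity_min = 60)
  expect_equal(hs$representatives, "S1")   # S2 below 60, S3 above cutoff,
  expect_equal(hs$M, 1L)                   # self dropped, S1 once, X ignored

  self_only <- filter_homologs(
    tibble::tibble(query = "Q", subject = "Q", identity = 100, evalue = 0),
    "Q")
  expect_equal(self_only$M, 0L)

  keep_self <- filter_homologs(
    tibble::tibble(query = "Q", subject = "Q", identity = 100, evalue = 0),
    "Q", exclude_self = FALSE)
  expect_equal(keep_self$representatives, "Q")

  # idempotent and order-preserving
  many <- tibble::tibble(query = "Q",
                         subject = c("B", "A", "C", "B"),
                         identity = c(90, 85, 70, 95),
                         evalue = rep(1e-10, 4))
  hs1 <- filter_homologs(many, "Q")
  expect_equal(hs1$representatives, c("B", "A", "C"))
})

test_that("GO vector averages annotation indicators over the homology set", {
  gm <- tibble::tibble(
    accession = c("R1", "R1", "R2"),
    term = c("GO:0000001", "GO:0000003", "GO:0000003"))
  idx <- build_go_index(dplyr::bind_rows(
    gm, tibble::tibble(accession = "Z", term = "GO:0000002")))
  hs <- structure(list(query = "Q", representatives = c("R1", "R2"), M = 2L),
                  class = "homology_set")
  v <- go_feature_vector(hs, gm, idx)
  expect_equal(unname(v), c(0.5, 0, 1.0))
  expect_true(all(v >= 0 & v <= 1))

  empty <- structure(list(query = "Q", representatives = character(), M = 0L),
                     class = "homology_set")
  expect_null(go_feature_vector(empty, gm, idx))

  unannotated <- structure(list(query = "Q",
                                representatives = c("U1", "U2", "U3"),
                                M = 3L),
                           class = "homology_set")
  expect_null(go_feature_vector(unannotated, gm, idx))
})

test_that("dipeptide composition matches hand counts and handles ambiguity", {
  v <- dipeptide_composition("AAA")
  expect_equal(unname(v["A"]), 1.0)
  expect_equal(unname(v["AA"]), 1.0)
  expect_equal(sum(v[1:20]), 1.0)
  expect_equal(sum(v[21:420]), 1.0)
  expect_length(v, 420L)

  v2 <- dipeptide_composition("ACD")
  expect_equal(unname(v2[c("A", "C", "D")]), rep(1 / 3, 3))
  expect_equal(unname(v2[c("AC", "CD")]), c(0.5, 0.5))
  expect_equal(unname(v2["AD"]), 0)

  v3_aac <- dipeptide_composition("AXAC")[1:20]  # X excluded from counts
  expect_equal(unname(v3_aac["A"]), 2 / 3)
  expect_error(dipeptide_composition("AXA"), "DC undefined")
  expect_error(dipeptide_composition("XXX"), "DC undefined")
})

test_that("dipeptide composition agrees with the brute-force window oracle", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_sequence(sample(2:80, 1))
    expect_lt(max(abs(dipeptide_composition(s) - dc_oracle(s))), 1e-12)
  }
  # block sums are exactly 1 for pure-standard sequences
  set.seed(7)
  for (i in 1:50) {
    v <- dipeptide_composition(random_sequence(sample(2:200, 1)))
    expect_lt(abs(sum(v[1:20]) - 1), 1e-12)
    expect_lt(abs(sum(v[21:420]) - 1), 1e-12)
  }
})

test_that("representation selection falls back to DC and zero-fills concat", {
  gm <- tibble::tibble(accession = "R1", term = "GO:0000001")
  idx <- build_go_index(gm)
  with_homs <- structure(list(query = "Q", representatives = "R1", M = 1L),
                         class = "homology_set")
  no_homs <- structure(list(query = "Q", representatives = character(),
                            M = 0L), class = "homology_set")

  b1 <- select_representation("ACD", with_homs, gm, idx, mode = "fallback")
  expect_equal(b1$source, "GO")
  expect_length(b1$vector, 1L)

  b2 <- select_representation("ACD", no_homs, gm, idx, mode = "fallback")
  expect_equal(b2$source, "DC")
  expect_length(b2$vector, 420L)

  b3 <- select_representation("ACD", no_homs, gm, idx, mode = "concat")
  expect_equal(b3$source, "CONCAT")
  expect_length(b3$vector, 421L)
  expect_equal(unname(b3$vector[1]), 0)

  b4 <- select_representation("ACD", with_homs, gm, idx, mode = "concat")
  expect_equal(unname(b4$vector[1]), 1)
})
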