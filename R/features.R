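#' Index GO terms into consecutive integers
#'
#' The GO ids appearing in an annotation corpus are renumbered into a compact
#' 1..K index (the column order of the GO feature vector). Ordering is
#' lexicographic by GO id so the bijection is deterministic and depends only
#' on the set of terms in the corpus.
#'
#' @param go_map Annotation tibble with columns `accession`, `term`.
#' @return A tibble with columns `term`, `index` (1..K, lexicographic).
#' @export
build_go_index <- function(go_map) {
  terms <- sort(unique(go_map$term))
  if (length(terms) == 0L) stop_user("no GO terms to index")
  tibble(term = terms, index = seq_along(terms))
}

#' Filter a hit table into a query's homology set
#'
#' Keeps subjects whose e-value is at most `evalue_max` and whose percent
#' identity is at least `identity_min` (inclusive at the 60% default), drops
#' the query's own accession when `exclude_self` (required for an honest
#' leave-one-out protocol), preserves input order and deduplicates subjects.
#' An empty result is legal and signals the dipeptide-composition fallback.
#'
#' @param hits Homology tibble from [read_homology_table()].
#' @param query_id Accession of the query protein.
#' @param evalue_max Maximum e-value (default 1e-3).
#' @param identity_min Minimum percent identity (default 60, inclusive).
#' @param exclude_self Drop hits whose subject equals the query (default TRUE).
#' @return An object of class `homology_set`: list with `query`,
#'   `representatives` (ordered, unique) and `M` (their count).
#' @export
filter_homologs <- function(hits, query_id, evalue_max = 1e-3,
                            identity_min = 60, exclude_self = TRUE) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 100)
  keep <- hits$query == query_id &
    hits$evalue <= evalue_max &
    hits$identity >= identity_min
  if (exclude_self) keep <- keep & hits$subject != query_id
  reps <- unique(hits$subject[keep])
  structure(list(query = query_id, representatives = reps,
                 M = length(reps)),
            class = "homology_set")
}

#' @export
print.homology_set <- function(x, ...) {
  cat(sprintf("<homology_set> query %s: M = %d representative(s)\n",
              x$query, x$M))
  invisible(x)
}

#' GO homology-transfer feature vector
#'
#' Component u is the fraction of the query's representative proteins
#' annotated with GO term u: an average of 0/1 indicators over the homology
#' set, hence always in \[0,1\] and equal to 1 only when every representative
#' carries the term. Returns `NULL` (the "naught or meaningless" condition)
#' when the homology set is empty or no representative carries any indexed
#' term; the caller then falls back to dipeptide composition.
#'
#' @param homology_set A [filter_homologs()] result.
#' @param go_map Annotation tibble (`accession`, `term`).
#' @param index GO index tibble from [build_go_index()].
#' @return Numeric vector of length K named by GO term, or `NULL`.
#' @export
go_feature_vector <- function(homology_set, go_map, index) {
  if (homology_set$M == 0L) return(NULL)
  sets <- go_term_sets(go_map, homology_set$representatives)
  counts <- table(factor(unlist(sets, use.names = FALSE),
                         levels = index$term))
  a <- as.numeric(counts) / homology_set$M
  if (all(a == 0)) return(NULL)
  setNames(a, index$term)
}

#' Dipeptide composition feature vector
#'
#' A 420-dimensional vector: components 1-20 are the amino-acid composition
#' (fractions of the 20 standard residues, alphabetical order A..Y) and
#' components 21-420 are the fractions of the 400 dipeptides in the fixed
#' enumeration AA, AC, ..., YY, counted over adjacent residue pairs.
#' Positions holding ambiguity codes (B, J, O, U, X, Z) are excluded from
#' both numerators and denominators, and any pair containing one is excluded
#' from the dipeptide counts.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of length 420.
#' @export
dipeptide_composition <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(AA20, AA_AMBIGUOUS))
  if (length(bad) > 0L) {
    stop_user("illegal character at position %d", bad[1L])
  }
  std <- chars %in% AA20
  if (!any(std)) stop_user("DC undefined: no standard residue")
  aac <- as.numeric(table(factor(chars[std], levels = AA20))) / sum(std)
  n <- length(chars)
  if (n < 2L) stop_user("DC undefined: no standard adjacent pair")
  pair_ok <- std[-n] & std[-1L]
  if (!any(pair_ok)) stop_user("DC undefined: no standard adjacent pair")
  dips <- paste0(chars[-n][pair_ok], chars[-1L][pair_ok])
  dc <- as.numeric(table(factor(dips, levels = DIPEPTIDES))) / sum(pair_ok)
  setNames(c(aac, dc), c(AA20, DIPEPTIDES))
}

#' Choose a protein's feature representation
#'
#' In `fallback` mode (the default) the GO homology-transfer vector is used
#' whenever it is defined, and dipeptide composition acts as backup. In
#' `concat` mode a single vector of K + 420 components is built, the GO part
#' zero-filled when undefined.
#'
#' @param sequence Amino-acid string of the query.
#' @param homology_set A [filter_homologs()] result for the query.
#' @param go_map Annotation tibble.
#' @param index GO index tibble.
#' @param mode `"fallback"` or `"concat"`.
#' @return List with `source` (`"GO"` or `"DC"`; `"CONCAT"` in concat mode)
#'   and `vector`.
#' @export
select_representation <- function(sequence, homology_set, go_map, index,
                                  mode = c("fallback", "concat")) {
  mode <- match.arg(mode)
  g <- go_feature_vector(homology_set, go_map, index)
  if (mode == "fallback") {
    if (!is.null(g)) {
      list(source = "GO", vector = g)
    } else {
      list(source = "DC", vector = dipeptide_composition(sequence))
    }
  } else {
    if (is.null(g)) g <- setNames(numeric(nrow(index)), index$term)
    list(source = "CONCAT", vector = c(g, dipeptide_composition(sequence)))
  }
}

# Feature bundles for a whole dataset: routing tibble plus per-route feature
# matrices. Bundles depend only on sequences, hits and the annotation corpus,
# so they are computed once and shared across cross-validation folds.
build_feature_bundles <- function(records, hits, go_map, index,
                                  mode = "fallback", evalue_max = 1e-3,
                                  identity_min = 60, exclude_self = TRUE) {
  if (is.null(go_map) || is.null(index)) hits <- NULL
  bundles <- purrr::map2(records$id, records$sequence, function(id, seq) {
    hs <- if (is.null(hits)) {
      structure(list(query = id, representatives = character(), M = 0L),
                class = "homology_set")
    } else {
      filter_homologs(hits, id, evalue_max = evalue_max,
                      identity_min = identity_min,
                      exclude_self = exclude_self)
    }
    select_representation(seq, hs, go_map, index, mode = mode)
  })
  routing <- tibble(id = records$id,
                    source = purrr::map_chr(bundles, "source"))
  mats <- lapply(split(seq_len(nrow(routing)), routing$source), function(i) {
    m <- do.call(rbind, lapply(bundles[i], `[[`, "vector"))
    rownames(m) <- routing$id[i]
    m
  })
  list(routing = routing, matrices = mats, mode = mode, index = index)
}
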