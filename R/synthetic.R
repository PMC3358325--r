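#' Specification of a synthetic localization world
#'
#' Describes the statistical structure of a generated dataset: a multi-label
#' matrix (independent labels, an exact copy pair, or a noisy copy with flip
#' probability `flip_prob`), random amino-acid sequences, and a homology
#' world in which each protein's homologs carry GO terms enriched for the
#' informative terms of its true labels. Hit identities and e-values are
#' drawn so that they straddle the homology-filter cutoffs by default — both
#' filter branches are exercised and a fraction of proteins genuinely falls
#' back to dipeptide composition.
#'
#' @param n_proteins Number of proteins.
#' @param n_labels Number of locations L (>= 2; copy models need L >= 3 so
#'   that rows other than the copied pair keep the matrix non-degenerate).
#' @param label_model `"independent"`, `"copy"` (label 2 := label 1) or
#'   `"noisy_copy"` (label 2 = label 1 flipped with probability `flip_prob`).
#' @param label_prob Bernoulli probability of each free label.
#' @param flip_prob Flip probability of the noisy copy (default 0.1).
#' @param n_go_terms Size of the GO vocabulary (default 60).
#' @param informative_per_label Informative terms per label (default 5).
#' @param enrichment Probability that a homolog of a protein carrying label j
#'   is annotated with each informative term of j (default 0.9).
#' @param background Probability of each non-informative term on any homolog
#'   (default 0.05).
#' @param homologs_range Range (min, max) of homologs per protein.
#' @param seq_len_range Range of sequence lengths.
#' @param identity_range Range of hit percent identities (default c(40, 95),
#'   straddling the 60% cutoff).
#' @param log10_evalue_range Range of log10 e-values (default c(-50, 0),
#'   straddling the 1e-3 cutoff).
#' @param seed Integer seed; generation is byte-reproducible given the spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_proteins = 100L, n_labels = 3L,
                     label_model = c("independent", "copy", "noisy_copy"),
                     label_prob = 0.4, flip_prob = 0.1,
                     n_go_terms = 60L, informative_per_label = 5L,
                     enrichment = 0.9, background = 0.05,
                     homologs_range = c(2L, 6L),
                     seq_len_range = c(50L, 120L),
                     identity_range = c(40, 95),
                     log10_evalue_range = c(-50, 0), seed = 1L) {
  label_model <- match.arg(label_model)
  probs <- c(label_prob, flip_prob, enrichment, background)
  if (any(probs < 0 | probs > 1)) stop_user("probabilities must be in [0,1]")
  if (n_proteins < 1L || n_labels < 2L) {
    stop_user("need n_proteins >= 1 and n_labels >= 2")
  }
  if (label_model != "independent" && n_labels < 3L) {
    stop_user("copy label models need n_labels >= 3")
  }
  if (seq_len_range[1L] < 2L) stop_user("sequence lengths must be >= 2")
  if (n_labels * informative_per_label > n_go_terms) {
    stop_user("infeasible: more informative terms than GO terms")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_labels = as.integer(n_labels), label_model = label_model,
                 label_prob = label_prob, flip_prob = flip_prob,
                 n_go_terms = as.integer(n_go_terms),
                 informative_per_label = as.integer(informative_per_label),
                 enrichment = enrichment, background = background,
                 homologs_range = as.integer(homologs_range),
                 seq_len_range = as.integer(seq_len_range),
                 identity_range = identity_range,
                 log10_evalue_range = log10_evalue_range,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

r_sequences <- function(n, len_range) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(AA20, l, replace = TRUE), collapse = "")
  }, character(1))
}

r_labels <- function(spec) {
  n <- spec$n_proteins
  L <- spec$n_labels
  draw_row <- function() {
    repeat {
      y <- rbinom(L, 1L, spec$label_prob)
      if (spec$label_model == "copy") {
        y[2L] <- y[1L]
      } else if (spec$label_model == "noisy_copy") {
        y[2L] <- as.integer(xor(y[1L] == 1L, rbinom(1L, 1L, spec$flip_prob) == 1L))
      }
      if (sum(y) >= 1L) return(y)
    }
  }
  m <- t(vapply(seq_len(n), function(i) draw_row(), integer(L)))
  colnames(m) <- paste0("loc", seq_len(L))
  m
}

#' Generate random protein sequences
#'
#' Residues i.i.d. over the 20-letter standard alphabet; deterministic given
#' the spec's seed. Minimum length 2 guarantees the dipeptide composition is
#' defined for every generated sequence.
#'
#' @param spec A [sim_spec()].
#' @return A tibble with columns `id`, `sequence`.
#' @export
gen_sequences <- function(spec) {
  set.seed(spec$seed)
  tibble(id = sprintf("SP%05d", seq_len(spec$n_proteins)),
         sequence = r_sequences(spec$n_proteins, spec$seq_len_range))
}

#' Generate a complete synthetic localization world
#'
#' Produces the four inputs of the pipeline: sequences, a label matrix
#' following the spec's dependence model and with every protein carrying at
#' least one location, a GO annotation map over synthetic homolog
#' accessions, and a homology hit table. Homologs of a protein carry each
#' informative term of the protein's true labels with probability
#' `enrichment` plus background terms with probability `background`, so the
#' GO homology-transfer vector is informative about the labels to a tunable
#' degree.
#'
#' @param spec A [sim_spec()].
#' @return A [loc_data()].
#' @export
gen_multilabel_world <- function(spec) {
  set.seed(spec$seed)
  ids <- sprintf("SP%05d", seq_len(spec$n_proteins))
  seqs <- r_sequences(spec$n_proteins, spec$seq_len_range)
  Y <- r_labels(spec)
  terms <- sprintf("GO:%07d", seq_len(spec$n_go_terms))
  informative <- split(
    terms[seq_len(spec$n_labels * spec$informative_per_label)],
    rep(seq_len(spec$n_labels), each = spec$informative_per_label))
  bg_terms <- setdiff(terms, unlist(informative))
  go_rows <- list()
  hit_rows <- list()
  for (i in seq_len(spec$n_proteins)) {
    m_i <- sample(seq(spec$homologs_range[1L], spec$homologs_range[2L]), 1L)
    own <- unlist(informative[which(Y[i, ] == 1L)], use.names = FALSE)
    for (h in seq_len(m_i)) {
      subj <- sprintf("%s_H%02d", ids[i], h)
      keep_inf <- own[runif(length(own)) < spec$enrichment]
      keep_bg <- bg_terms[runif(length(bg_terms)) < spec$background]
      ts <- c(keep_inf, keep_bg)
      if (length(ts) > 0L) {
        go_rows[[length(go_rows) + 1L]] <-
          tibble(accession = subj, term = ts)
      }
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        query = ids[i], subject = subj,
        identity = runif(1L, spec$identity_range[1L],
                         spec$identity_range[2L]),
        evalue = 10^runif(1L, spec$log10_evalue_range[1L],
                          spec$log10_evalue_range[2L]))
    }
  }
  go_map <- if (length(go_rows) > 0L) dplyr::bind_rows(go_rows) else
    tibble(accession = character(), term = character())
  hits <- dplyr::bind_rows(hit_rows)
  labels <- structure(Y, dimnames = list(ids, colnames(Y)),
                      class = c("label_matrix", "matrix", "array"))
  loc_data(records = tibble(id = ids, sequence = seqs),
           labels = labels, go_map = go_map, hits = hits)
}

#' Label-matrix skeleton with a prescribed multiplicity mix
#'
#' Draws per-protein multiplicities matching the given proportions by
#' largest-remainder rounding (ties broken toward lower multiplicity), then
#' assigns that many labels uniformly at random. This emulates, at small n,
#' the heavily single-label multiplicity structure of real eukaryotic
#' benchmarks.
#'
#' @param n Number of proteins.
#' @param proportions Proportions over multiplicities `1..length(proportions)`,
#'   summing to 1.
#' @param n_labels Number of locations (default `max(4, length(proportions))`).
#' @param seed Integer seed.
#' @return A [label_matrix()]; attribute `multiplicity_counts` holds the
#'   rounded count per multiplicity.
#' @export
gen_multiplicity_mix <- function(n, proportions,
                                 n_labels = max(4L, length(proportions)),
                                 seed = 1L) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop_user("proportions must be non-negative and sum to 1")
  }
  if (length(proportions) > n_labels) {
    stop_user("maximum multiplicity exceeds the number of labels")
  }
  q <- n * proportions
  counts <- floor(q)
  remainder <- n - sum(counts)
  if (remainder > 0L) {
    frac <- q - counts
    extra <- order(-frac, seq_along(frac))[seq_len(remainder)]
    counts[extra] <- counts[extra] + 1L
  }
  set.seed(seed)
  mult <- rep(seq_along(counts), times = counts)
  ids <- sprintf("SP%05d", seq_len(n))
  uni <- paste0("loc", seq_len(n_labels))
  sets <- lapply(mult, function(k) sample(uni, k))
  out <- label_matrix(ids, sets, universe = uni)
  attr(out, "multiplicity_counts") <- setNames(as.integer(counts),
                                               seq_along(counts))
  out
}

#' Write a synthetic world to a directory as the four standard files
#'
#' @param data A [loc_data()].
#' @param dir Output directory (created if needed).
#' @return A named character vector of the four paths, invisibly.
#' @export
write_world <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             labels = file.path(dir, "labels.tsv"),
             go_map = file.path(dir, "go_map.tsv"),
             homology = file.path(dir, "homology.tsv"))
  write_fasta(data$records, paths[["fasta"]])
  write_label_table(data$labels, paths[["labels"]])
  write_go_annotation_map(data$go_map, paths[["go_map"]])
  write_homology_table(data$hits, paths[["homology"]])
  invisible(paths)
}
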