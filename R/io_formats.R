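#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard residue
#' letters plus the ambiguity codes B, J, O, U, X and Z. How ambiguity codes
#' are treated is deferred to the feature extractors (they are excluded from
#' composition counts); here they only have to be legal.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   each header) and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop_user("no records in %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop_user("empty FASTA header in %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop_user("duplicate id: %s", dup[1L])
  seqs <- toupper(as.character(set))
  allowed <- paste0(c(AA20, AA_AMBIGUOUS), collapse = "")
  bad <- regexpr(sprintf("[^%s]", allowed), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop_user("illegal character at position %d in sequence '%s'",
              bad[i], ids[i])
  }
  if (any(nchar(seqs) < 1L)) {
    stop_user("empty sequence for id '%s'", ids[which(nchar(seqs) < 1L)[1L]])
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#' @param records Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Read a tab-separated file with "#" comment lines into a character matrix of
# exactly n_cols fields per row; shared by the three TSV readers.
read_tsv_fields <- function(path, n_cols, what) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = n_cols))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_cols)
  if (length(bad) > 0L) {
    stop_user("%s: expected %d tab-separated fields on row %d",
              what, n_cols, bad[1L])
  }
  matrix(unlist(fields), ncol = n_cols, byrow = TRUE)
}

#' Read a protein-to-locations label table
#'
#' Rows are `protein_id<TAB>loc1,loc2,...` with comma-separated location
#' names. Every protein must carry at least one location.
#'
#' @param path Path to the TSV file.
#' @param universe Optional character vector of location names fixing the
#'   column order; names in the file outside it are an error. When omitted,
#'   the universe is inferred in first-appearance order.
#' @return A [label_matrix()].
#' @export
read_label_table <- function(path, universe = NULL) {
  f <- read_tsv_fields(path, 2L, "label table")
  if (nrow(f) == 0L) stop_user("label table %s has no rows", path)
  sets <- strsplit(f[, 2L], ",", fixed = TRUE)
  sets <- lapply(sets, function(s) trimws(s[nzchar(trimws(s))]))
  empty <- which(lengths(sets) == 0L)
  if (length(empty) > 0L) {
    stop_user("protein %s has no location label", f[empty[1L], 1L])
  }
  label_matrix(f[, 1L], sets, universe = universe)
}

#' Write a label matrix as a label table
#' @param labels A `label_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  uni <- colnames(labels)
  lines <- vapply(seq_len(nrow(labels)), function(i) {
    paste0(rownames(labels)[i], "\t",
           paste(uni[labels[i, ] == 1L], collapse = ","))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a tabular homology hit table
#'
#' The format mirrors the first columns of tabular BLAST output
#' (`query<TAB>subject<TAB>pct_identity<TAB>evalue`), so real BLAST `-outfmt 6`
#' results can be fed in after column selection. No filtering is applied here;
#' see [filter_homologs()].
#'
#' @param path Path to the TSV file. An empty file is legal and yields an
#'   empty table (all downstream homology sets are then empty).
#' @return A tibble with columns `query`, `subject`, `identity`, `evalue`,
#'   in file order.
#' @export
read_homology_table <- function(path) {
  f <- read_tsv_fields(path, 4L, "homology table")
  identity <- suppressWarnings(as.numeric(f[, 3L]))
  evalue <- suppressWarnings(as.numeric(f[, 4L]))
  if (anyNA(identity) || anyNA(evalue)) {
    stop_user("homology table: non-numeric identity or e-value on row %d",
              which(is.na(identity) | is.na(evalue))[1L])
  }
  if (any(identity < 0 | identity > 100)) {
    stop_user("homology table: percent identity outside [0,100] on row %d",
              which(identity < 0 | identity > 100)[1L])
  }
  if (any(!is.finite(evalue) | evalue < 0)) {
    stop_user("homology table: e-value must be finite and non-negative (row %d)",
              which(!is.finite(evalue) | evalue < 0)[1L])
  }
  tibble(query = f[, 1L], subject = f[, 2L],
         identity = identity, evalue = evalue)
}

#' Write a homology hit table
#' @param hits Tibble with columns `query`, `subject`, `identity`, `evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", hits$query, hits$subject,
                   format(hits$identity, trim = TRUE, digits = 15),
                   format(hits$evalue, trim = TRUE, digits = 15))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an accession-to-GO-term annotation map
#'
#' Rows are `accession<TAB>GO:NNNNNNN`, one term per row, emulating a
#' two-column extract of a GOA association file. Repeated accessions
#' accumulate into a term set; duplicate rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession`, `term` (deduplicated).
#' @export
read_go_annotation_map <- function(path) {
  f <- read_tsv_fields(path, 2L, "GO annotation map")
  if (nrow(f) > 0L) {
    bad <- which(!grepl("^GO:\\d{7}$", f[, 2L]))
    if (length(bad) > 0L) {
      stop_user("malformed GO id '%s' on row %d", f[bad[1L], 2L], bad[1L])
    }
  }
  dplyr::distinct(tibble(accession = f[, 1L], term = f[, 2L]))
}

#' Write a GO annotation map
#' @param go_map Tibble with columns `accession`, `term`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_annotation_map <- function(go_map, path) {
  readr::write_lines(paste0(go_map$accession, "\t", go_map$term), path)
  invisible(path)
}

#' Term sets of an annotation map
#' @param go_map Tibble with columns `accession`, `term`.
#' @param accessions Accessions to look up; absent accessions yield empty sets.
#' @return Named list of character vectors.
#' @export
go_term_sets <- function(go_map, accessions) {
  idx <- split(go_map$term, factor(go_map$accession, levels = accessions))
  lapply(idx, as.character)
}
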