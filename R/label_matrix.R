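#' Build a binary protein-by-location label matrix
#'
#' The label matrix is the canonical representation of a multi-label
#' localization dataset: one row per protein, one column per subcellular
#' location, entries 1 where the protein resides in that location. A protein
#' annotated to k locations contributes k "locative proteins", so the sum of
#' all entries is the locative count N(loc) while the number of rows is the
#' distinct-protein count N(seq).
#'
#' @param ids Character vector of protein accessions (unique, non-empty).
#' @param location_sets List of character vectors, one per protein, each the
#'   set of location names the protein occupies (at least one each).
#' @param universe Optional character vector fixing the location ordering
#'   (column order). Defaults to first-appearance order across
#'   `location_sets`.
#' @return A binary integer matrix of class `label_matrix` with `ids` as row
#'   names and the universe as column names.
#' @export
label_matrix <- function(ids, location_sets, universe = NULL) {
  stopifnot(is.character(ids), is.list(location_sets),
            length(ids) == length(location_sets))
  if (anyDuplicated(ids)) {
    stop_user("duplicate protein id: %s", ids[duplicated(ids)][1L])
  }
  if (any(!nzchar(ids))) stop_user("empty protein id")
  seen <- unique(unlist(location_sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- seen
  } else {
    unknown <- setdiff(seen, universe)
    if (length(unknown) > 0L) {
      stop_user("unknown location name: %s", unknown[1L])
    }
  }
  if (length(universe) < 1L || anyDuplicated(universe)) {
    stop_user("label universe must be non-empty with unique names")
  }
  m <- matrix(0L, nrow = length(ids), ncol = length(universe),
              dimnames = list(ids, universe))
  for (i in seq_along(ids)) {
    locs <- unique(location_sets[[i]])
    if (length(locs) < 1L) {
      stop_user("protein %s has no location label", ids[i])
    }
    m[i, locs] <- 1L
  }
  structure(m, class = c("label_matrix", class(m)))
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d proteins x %d locations, N(loc) = %d\n",
              nrow(x), ncol(x), n_locative(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  invisible(x)
}

#' Multiplicity of each protein (number of true locations)
#' @param labels A `label_matrix`.
#' @return Named integer vector of row sums.
#' @export
multiplicity <- function(labels) {
  as.integer(rowSums(labels)) |> setNames(rownames(labels))
}

#' Total number of locative proteins N(loc)
#'
#' A protein with k locations counts k times, so this is the sum of all
#' matrix entries and equals the sum over k of k times the number of
#' proteins with multiplicity k.
#' @param labels A `label_matrix`.
#' @export
n_locative <- function(labels) as.integer(sum(labels))

#' @export
tidy.label_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "location", values_to = "member") |>
    dplyr::filter(.data$member == 1L) |>
    dplyr::select("id", "location")
}

#' Coerce a long (id, location) tibble to a label matrix
#' @param data Data frame with columns `id` and `location` (one row per
#'   locative protein).
#' @param universe Optional location ordering.
#' @return A `label_matrix`.
#' @export
as_label_matrix <- function(data, universe = NULL) {
  stopifnot(all(c("id", "location") %in% names(data)))
  ids <- unique(data$id)
  sets <- split(data$location, factor(data$id, levels = ids))
  label_matrix(ids, unname(as.list(sets)), universe = universe)
}
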