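#' The 22-location eukaryotic benchmark: per-location breakdown
#'
#' The published benchmark of 7,766 eukaryotic proteins spanning 22
#' subcellular locations that this toolkit's evaluation protocol was designed
#' for (none of its proteins shares >= 25% pairwise identity with another in
#' the same location subset). Because multi-location proteins count once per
#' location, the per-location counts sum to the locative total N(loc) rather
#' than the number of distinct proteins.
#'
#' @return A tibble with columns `code` (1..22), `location`, `n` (number of
#'   locative proteins in that location).
#' @seealso [euk22_multiplicity()] for the multiplicity breakdown.
#' @export
euk22_locations <- function() {
  tibble(
    code = 1:22,
    location = c("acrosome", "cell membrane", "cell wall", "centrosome",
                 "chloroplast", "cyanelle", "cytoplasm", "cytoskeleton",
                 "endoplasmic reticulum", "endosome", "extracellular",
                 "Golgi apparatus", "hydrogenosome", "lysosome",
                 "melanosome", "microsome", "mitochondrion", "nucleus",
                 "peroxisome", "spindle pole body", "synapse", "vacuole"),
    n = c(14L, 697L, 49L, 96L, 385L, 79L, 2186L, 139L, 457L, 41L, 1048L,
          254L, 10L, 57L, 47L, 13L, 610L, 2320L, 110L, 68L, 47L, 170L))
}

#' The 22-location eukaryotic benchmark: multiplicity breakdown
#'
#' Number of benchmark proteins truly residing in 1, 2, 3 and 4 subcellular
#' locations. Summing the counts gives the number of distinct proteins
#' N(seq); summing multiplicity times count gives the locative total N(loc),
#' which must also equal the sum of the per-location counts of
#' [euk22_locations()].
#'
#' @return A tibble with columns `multiplicity` (1..4) and `n`.
#' @export
euk22_multiplicity <- function() {
  tibble(multiplicity = 1:4, n = c(6687L, 1029L, 48L, 2L))
}
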