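#' Model species
#'
#' The 13 molecular species tracked per cell. Paralogs are collapsed to the
#' granularity of the tissue-level network: `her` stands for both her1 and
#' her7, `mespa` for mespaa/mespab, `mespb` for mespba/mespbb. Tbx6 is
#' modelled at the protein level only (its regulation in the model is
#' post-translational, via Ripply-dependent removal), so it has no mRNA slot.
#'
#' @return Character vector of species names in canonical state-vector order:
#'   five mRNAs (`her_m`, `delta_m`, `mespa_m`, `mespb_m`, `ripply_m`), six
#'   proteins (`Her`, `Delta`, `Mespa`, `Mespb`, `Ripply`, `Tbx6`), and two
#'   complexes (`HerDimer`, the transcriptionally active Her homodimer, and
#'   `NICD`, the Notch intracellular domain released by neighbour Delta).
#' @export
species_names <- function() {
  c("her_m", "delta_m", "mespa_m", "mespb_m", "ripply_m",
    "Her", "Delta", "Mespa", "Mespb", "Ripply", "Tbx6",
    "HerDimer", "NICD")
}

#' Index of a species in the state vector
#'
#' @param species Character vector of species names.
#' @return Integer indices into the canonical species order.
#' @export
species_index <- function(species) {
  idx <- match(species, species_names())
  if (anyNA(idx)) {
    stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
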