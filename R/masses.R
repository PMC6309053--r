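#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues, i.e. the
#' mass each residue contributes inside a peptide chain (the free amino acid
#' minus one water). All masses in this package are neutral monoisotopic
#' masses, the convention of deconvoluted top-down spectra.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() .RESIDUE_MASSES

.RESIDUE_MASSES <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# monoisotopic mass of H2O; added to a residue-mass sum to give the neutral
# mass of an intact (unfragmented) segment
.WATER <- 18.010565

#' Standard amino-acid alphabet
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
amino_acids <- function() names(.RESIDUE_MASSES)

# residue-mass lookup for a sequence string; errors on unknown letters
residue_mass_vector <- function(sequence) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .RESIDUE_MASSES[letters]
  if (anyNA(m)) {
    bad <- unique(letters[is.na(m)])
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Neutral monoisotopic mass of an unmodified protein segment
#'
#' Sum of residue masses plus one water.
#'
#' @param segment Amino-acid string.
#' @return Mass in Da.
#' @export
#' @examples
#' segment_mass("GG")  # 2 glycines + water
segment_mass <- function(segment) {
  sum(residue_mass_vector(segment)) + .WATER
}
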