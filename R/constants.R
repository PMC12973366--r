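# Physical constants and modification registry. Monoisotopic residue masses
# are the standard values for the 20 canonical amino-acid residues (Da);
# pinned here so peptide masses are fully deterministic.

#' Monoisotopic residue masses (Da)
#'
#' Named numeric vector of monoisotopic masses for the 20 canonical amino-acid
#' residues (residue = amino acid minus water). Non-canonical letters
#' (B, J, O, U, X, Z) are deliberately absent: sequences containing them are
#' rejected rather than mass-approximated.
#'
#' @format Named numeric vector of length 20.
#' @export
RESIDUE_MONO_MASS <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Mass of a proton (Da)
#' @export
PROTON_MASS <- 1.007276466

#' Monoisotopic mass of water (Da)
#' @export
WATER_MASS <- 18.0105646863

#' Modification specification
#'
#' Describes a peptide modification by name, monoisotopic delta mass, the
#' sites it targets (residue letters and/or `"N-term"`) and whether it is
#' applied as a fixed (static) modification.
#'
#' @param name Modification name.
#' @param delta_mass Monoisotopic mass shift in Da.
#' @param targets Character vector of residue letters and/or `"N-term"`.
#' @param fixed Logical; `TRUE` for a static modification.
#' @return An object of class `modification_spec`.
#' @examples
#' modification_spec("TMTpro", 304.2071, c("K", "N-term"), fixed = TRUE)
#' @export
modification_spec <- function(name, delta_mass, targets, fixed = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta_mass), length(delta_mass) == 1L,
            is.character(targets), length(targets) >= 1L)
  structure(
    list(name = name, delta_mass = delta_mass,
         targets = unique(targets), fixed = fixed),
    class = "modification_spec"
  )
}

#' Registry of standard modifications
#'
#' The amine-reactive isobaric labels and the common static/dynamic
#' modifications used in TMT workflows, with their monoisotopic delta masses:
#' TMT6plex +229.1629 (K, N-term), TMTpro +304.2071 (K, N-term),
#' carbamidomethyl +57.0215 (C), oxidation +15.9949 (M) and deamidation
#' +0.984 (N, Q).
#'
#' @return Named list of [modification_spec()] objects.
#' @examples
#' modification_registry()$TMTpro$delta_mass
#' @export
modification_registry <- function() {
  list(
    TMT6plex        = modification_spec("TMT6plex", 229.1629,
                                        c("K", "N-term"), fixed = TRUE),
    TMTpro          = modification_spec("TMTpro", 304.2071,
                                        c("K", "N-term"), fixed = TRUE),
    carbamidomethyl = modification_spec("carbamidomethyl", 57.0215,
                                        "C", fixed = TRUE),
    oxidation       = modification_spec("oxidation", 15.9949,
                                        "M", fixed = FALSE),
    deamidation     = modification_spec("deamidation", 0.984,
                                        c("N", "Q"), fixed = FALSE)
  )
}
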