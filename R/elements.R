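#' @keywords internal
#' @name elements
#' @title Pinned element data
#'
#' @description Monoisotopic masses (most abundant isotope, u), standard
#'   atomic weights (u), and default valences used throughout the package.
#'   Values are pinned here so that every mass printed by the package is
#'   bit-stable across platforms and sessions.  Monoisotopic masses follow
#'   CODATA/AME2020 to six decimals; atomic weights are the IUPAC abridged
#'   values.
NULL

.monoisotopic <- c(
  H = 1.007825, B = 11.009305, C = 12.000000, N = 14.003074, O = 15.994915,
  F = 18.998403, Na = 22.989770, Mg = 23.985042, Si = 27.976927,
  P = 30.973762, S = 31.972071, Cl = 34.968853, K = 38.963707,
  Ca = 39.962591, Se = 79.916522, Br = 78.918338, I = 126.904473,
  Li = 7.016003
)

.atomic_weight <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904,
  I = 126.904, Li = 6.94
)

# allowed valence states (smallest state >= bond-order sum is used when
# assigning implicit hydrogens); metals get 0 so bare cations carry no H
.valences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
  P = c(3, 5), S = c(2, 4, 6), Se = c(2, 4, 6), Si = 4,
  Na = 0, K = 0, Li = 0, Mg = 0, Ca = 0
)

# particle masses for ESI adduct arithmetic (u)
.proton_mass <- 1.007276
.electron_mass <- 0.000549

#' ESI adduct specifications
#'
#' Singly charged electrospray adducts supported by
#' [predict_adduct_mz()]: the deprotonated anion, the protonated cation and
#' the sodiated cation.  Mass deltas are derived from the pinned proton,
#' electron and sodium masses.
#'
#' @return A data frame with columns `label`, `delta` (u) and `charge`.
#' @examples
#' adduct_specs()
#' @export
adduct_specs <- function() {
  data.frame(
    label = c("[M-H]-", "[M+H]+", "[M+Na]+"),
    delta = c(-.proton_mass, .proton_mass,
              .monoisotopic[["Na"]] - .electron_mass),
    charge = c(-1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}
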