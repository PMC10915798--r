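# Physical constants and element tables shared across the package.
# Unit conventions: lengths nm, times ps, energies kT at a stated temperature,
# charges in elementary-charge units.

AVOGADRO <- 6.02214076e23

#' Default analysis temperature in Kelvin
#'
#' All free energies are reported in units of kT; the temperature is carried
#' along for bookkeeping (300 K is the usual production temperature of
#' explicit-solvent protein simulations).
#' @export
DEFAULT_TEMPERATURE <- 300

# Bjerrum length of water near room temperature (nm); used only by the
# synthetic equilibrium sampler's screened-Coulomb term.
BJERRUM_NM <- 0.7

# van der Waals radii (nm) used for SASA and structure bookkeeping.
.ELEMENT_RADII <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  F = 0.147, Na = 0.227, Cl = 0.175, K = 0.275, Mg = 0.173, Ca = 0.231,
  Zn = 0.139
)

.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Na = 22.990, Cl = 35.45, K = 39.098, Mg = 24.305,
  Ca = 40.078, Zn = 65.38
)

#' Look up the van der Waals radius of an element
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"Na"`).
#' @return numeric vector of radii in nm.
#' @export
element_radius <- function(element) {
  r <- .ELEMENT_RADII[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unknown element(s) with no tabulated radius: ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

# Canonical capitalisation of an element symbol ("NA" -> "Na").
normalize_element <- function(x) {
  x <- trimws(x)
  ifelse(nchar(x) == 0L, x,
         paste0(toupper(substr(x, 1L, 1L)),
                tolower(substr(x, 2L, nchar(x)))))
}
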