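#' Henderson-Hasselbalch deprotonated fraction
#'
#' Fraction of a (two-state) acid/base pair in its more deprotonated (more
#' negative) state at a given pH: `1 / (1 + 10^(pKa - pH))`. Strictly
#' increasing in pH; equal to 1/2 at `pH == pKa`.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant of the transition between the two
#'   states.
#' @return fraction in `[0, 1]`.
#' @export
deprotonated_fraction <- function(pH, pKa) {
  if (!all(is.finite(pH)) || !all(is.finite(pKa)))
    stop("pH and pKa must be finite")
  1 / (1 + 10^(pKa - pH))
}

#' Two-state charge composition of a buffer
#'
#' Splits a buffer species between its two dominant charge states; the
#' protonated:deprotonated ratio equals `10^(pKa - pH)`.
#'
#' @inheritParams deprotonated_fraction
#' @return named numeric `c(protonated = 1 - f, deprotonated = f)`.
#' @export
two_state_composition <- function(pH, pKa) {
  f <- deprotonated_fraction(pH, pKa)
  c(protonated = 1 - f, deprotonated = f)
}

#' Number of ions matching a molar concentration in a cubic box
#'
#' `N = c * N_A * L^3` with c in mM and L in nm, rounded per `rounding`
#' (default nearest). E.g. 20 mM in a 12 nm box gives 20.81, i.e. 21 ions.
#'
#' @param concentration_mM concentration in mmol/L; nonnegative.
#' @param box_length cubic box edge in nm.
#' @param rounding `"nearest"`, `"floor"` or `"ceiling"`.
#' @return integer ion count.
#' @export
ion_count <- function(concentration_mM, box_length,
                      rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (concentration_mM < 0) stop("concentration must be nonnegative")
  n <- concentration_mM * 1e-3 * AVOGADRO * (box_length * 1e-9)^3 * 1e3
  as.integer(switch(rounding,
                    nearest = round(n),
                    floor = floor(n),
                    ceiling = ceiling(n)))
}

#' Largest-remainder apportionment of a total over state fractions
#'
#' Distributes `total` integer counts over states so that counts sum exactly
#' to `total`. Each state first receives `floor(total * fraction)`; remaining
#' units go to the largest fractional remainders. Remainder ties are broken in
#' favour of the state with the smaller `|charge|` (then by position).
#'
#' @param total nonnegative integer.
#' @param fractions numeric fractions summing to 1.
#' @param charges optional per-state charges used for tie-breaking.
#' @return integer vector of per-state counts summing to `total`.
#' @export
apportion_states <- function(total, fractions, charges = NULL) {
  if (total < 0) stop("total must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  ideal <- total * fractions
  counts <- floor(ideal + 1e-12)
  remainder <- ideal - counts
  short <- total - sum(counts)
  if (short > 0) {
    tie <- if (!is.null(charges)) abs(charges) else seq_along(fractions)
    ord <- order(-remainder, tie, seq_along(fractions))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Charge-state specification of a buffer species
#'
#' Combines Henderson-Hasselbalch speciation with integer apportionment of a
#' molecule count over the two dominant charge states.
#'
#' @param species species label (e.g. `"Phos"`, `"Cit"`).
#' @param pH solution pH.
#' @param pKa pKa of the transition between the two states.
#' @param charges length-2 numeric: charges of the (protonated, deprotonated)
#'   states, in elementary-charge units.
#' @param total total number of buffer molecules.
#' @return object of class `charge_state_spec` with a `states` data.frame
#'   (`charge`, `fraction`, `count`).
#' @export
charge_state_spec <- function(species, pH, pKa, charges, total) {
  if (length(charges) != 2L)
    stop("exactly two charge states are modelled per species")
  fr <- two_state_composition(pH, pKa)
  counts <- apportion_states(total, fr, charges)
  structure(
    list(species = species, pH = pH, pKa = pKa,
         states = data.frame(state = names(fr), charge = charges,
                             fraction = as.numeric(fr), count = counts)),
    class = "charge_state_spec")
}

#' @export
print.charge_state_spec <- function(x, ...) {
  cat("charge_state_spec:", x$species, " pH", x$pH, " pKa", x$pKa, "\n")
  print(x$states)
  invisible(x)
}
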