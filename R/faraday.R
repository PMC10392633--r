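#' Electrochemical constants for charge-to-molecule conversion
#'
#' Bundle of constants used to convert an integrated spike charge into a
#' molecule count via Faraday's law, Q = n N F, where Q is the charge
#' transferred at the electrode, n the number of electrons exchanged per
#' molecule oxidised, N the number of moles and F the Faraday constant.
#'
#' @param n_electrons Electrons transferred per molecule. Defaults to 2,
#'   the standard assumption for the two-electron oxidation of
#'   catecholamines at a carbon surface. Configurable for other analytes.
#'
#' @return A list with class `"faraday_constants"`: `n_electrons`,
#'   `faraday` (96,485 C/mol, fixed) and `avogadro` (molecules/mol).
#' @examples
#' molecules_from_charge(1000, faraday_constants())  # 1 pC -> ~3.12e6 molecules
#' @export
faraday_constants <- function(n_electrons = 2) {
  stopifnot(is.numeric(n_electrons), length(n_electrons) == 1L, n_electrons > 0)
  structure(
    list(
      n_electrons = n_electrons,
      faraday = 96485,           # C/mol
      avogadro = 6.02214076e23   # /mol
    ),
    class = "faraday_constants"
  )
}

#' Convert spike charge to molecule count (Faraday's law)
#'
#' Inverts Q = n N F and scales moles to molecules:
#' molecules = (Q / (n F)) * N_A. Linear in Q.
#'
#' @param charge_fC Charge in femtocoulombs (1 fC = 1e-15 C). Vectorised.
#' @param constants A [faraday_constants()] object.
#' @return Number of molecules (not moles), same length as `charge_fC`.
#' @export
molecules_from_charge <- function(charge_fC, constants = faraday_constants()) {
  stopifnot(inherits(constants, "faraday_constants"), is.numeric(charge_fC))
  if (any(charge_fC < 0, na.rm = TRUE)) {
    stop("charge_fC must be non-negative", call. = FALSE)
  }
  charge_fC * 1e-15 / (constants$n_electrons * constants$faraday) * constants$avogadro
}

#' Convert a molecule count to the equivalent spike charge
#'
#' Inverse of [molecules_from_charge()]: Q = n F (molecules / N_A),
#' returned in femtocoulombs. Used by the simulator to turn a drawn
#' quantal size into the charge its spike must carry.
#'
#' @inheritParams molecules_from_charge
#' @param molecules Number of molecules (vectorised, non-negative).
#' @return Charge in fC.
#' @export
charge_from_molecules <- function(molecules, constants = faraday_constants()) {
  stopifnot(inherits(constants, "faraday_constants"), is.numeric(molecules))
  if (any(molecules < 0, na.rm = TRUE)) {
    stop("molecules must be non-negative", call. = FALSE)
  }
  molecules / constants$avogadro * constants$n_electrons * constants$faraday / 1e-15
}
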