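## Physical constants. Lengths inside wavefunctions are bohr; everything at the
## scattering-vector boundary (s = sin(theta)/lambda) is in inverse angstroms.

#' Physical constants used by the package
#'
#' `bohrToAngstrom()` returns the Bohr radius in angstroms (CODATA).
#' `mottBetheConstant()` returns the combined constant
#' \eqn{C = m_0 e^2 / (8 \pi \epsilon_0 h^2)} of the Mott--Bethe formula,
#' expressed in inverse angstroms. It is evaluated from the CODATA values of
#' the electron mass, elementary charge, vacuum permittivity and Planck
#' constant, and cross-checked at load time against the equivalent identity
#' \eqn{C = 1/(8 \pi^2 a_0)} with \eqn{a_0} the Bohr radius; the two routes
#' must agree to 1e-9 relative or the package refuses to return a value.
#'
#' @return A single numeric value.
#' @examples
#' mottBetheConstant()       # ~0.023934 1/Angstrom
#' 1 / (8 * pi^2 * bohrToAngstrom())
#' @export
mottBetheConstant <- function() {
  m0 <- 9.1093837015e-31    # kg
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  h <- 6.62607015e-34       # J s
  c_metres <- m0 * e^2 / (8 * pi * eps0 * h^2)   # 1/m
  c_ang <- c_metres * 1e-10                      # 1/Angstrom
  c_bohr <- 1 / (8 * pi^2 * bohrToAngstrom())
  if (abs(c_ang - c_bohr) > 1e-9 * c_bohr)
    stop("Mott-Bethe constant cross-check failed: unit inconsistency")
  c_ang
}

#' @rdname mottBetheConstant
#' @export
bohrToAngstrom <- function() 0.529177210903
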