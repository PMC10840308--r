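## Electron-diffraction scattering factors by the Mott-Bethe transformation
## of the analytic X-ray factors, with the correct s -> 0 limits.

#' Mott-Bethe transformation of an X-ray scattering factor
#'
#' \eqn{f^e(s) = C\,(Z - f^X(s))/s^2} with the combined constant
#' \eqn{C = m_0 e^2/(8\pi\epsilon_0 h^2)} in inverse angstroms (see
#' [mottBetheConstant()]). Valid only for `s > 0`; the small-angle limit is
#' handled by [edFormFactor()].
#'
#' @param fX X-ray scattering factor in electrons (vectorized).
#' @param zNuclear Atomic number Z.
#' @param s sin(theta)/lambda in inverse angstroms, `s > 0`.
#' @return Electron scattering factor in angstroms.
#' @export
mottBethe <- function(fX, zNuclear, s) {
  if (any(s <= 0))
    stop("'s' must be positive; use edFormFactor() for the s = 0 limit")
  mottBetheConstant() * (zNuclear - fX) / s^2
}

#' Electron-diffraction scattering factor of a Slater wavefunction
#'
#' For `s > 0` this is the Mott-Bethe transform of the analytic X-ray factor.
#' At `s = 0` a neutral species has the finite limit
#' \deqn{f^e(0) = C\,\frac{8\pi^2}{3}\, N_e \langle r^2\rangle
#'             = \frac{N_e \langle r^2\rangle_{\AA}}{3 a_0}}
#' which follows from the small-angle expansion
#' \eqn{f^X(s) \approx N_e (1 - k^2 \langle r^2\rangle/6)} with
#' \eqn{k = 4\pi s}; \eqn{\langle r^2\rangle} is the per-electron mean square
#' radius ([meanSquareRadius()]) converted to square angstroms. For an ion
#' the Coulomb monopole makes \eqn{f^e} diverge as \eqn{C q / s^2}; `s = 0`
#' raises an error naming the net charge.
#'
#' @param wf A [SlaterWavefunction-class].
#' @param s sin(theta)/lambda in inverse angstroms (vectorized), `s >= 0`.
#' @return Electron scattering factor in angstroms.
#' @examples
#' edFormFactor(makeHydrogen(1.0), 0)    # the Bohr radius, ~0.529 A
#' @export
edFormFactor <- function(wf, s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  out <- numeric(length(s))
  zero <- s == 0
  if (any(zero)) {
    q <- wf@charge
    if (q != 0)
      stop(sprintf(
        "electron scattering factor diverges at s = 0 for an ion (net charge %+g)", q))
    r2ang <- meanSquareRadius(wf) * bohrToAngstrom()^2
    out[zero] <- electronCount(wf) * r2ang / (3 * bohrToAngstrom())
  }
  pos <- !zero
  ## below s ~ 5e-3 the difference Z - f^X cancels catastrophically in
  ## double precision; evaluate it by the convergent moment series instead
  small <- pos & s < 5e-3
  if (any(small)) out[small] <- .edSmallS(wf, s[small])
  rest <- pos & !small
  if (any(rest))
    out[rest] <- mottBethe(xrayFormFactor(wf, s[rest]), wf@zNuclear, s[rest])
  out
}

## small-angle expansion: with radial moments M_2j = int 4 pi r^(2j+2) rho dr,
## Z - f^X(k) = q + sum_{j>=1} (-1)^(j+1) k^(2j) M_2j / (2j+1)!   (q = Z - N_e)
.edSmallS <- function(wf, s) {
  ct <- .crossTermsCached(wf)
  k <- 4 * pi * s * bohrToAngstrom()
  q <- wf@zNuclear - electronCount(wf)
  D <- rep(q, length(s))
  for (j in 1:30) {
    M2j <- sum(ct$weight * factorial(ct$m + 2 * j) / ct$zsum^(ct$m + 2 * j + 1))
    piece <- (-1)^(j + 1) * k^(2 * j) / factorial(2 * j + 1) * M2j
    D <- D + piece
    if (all(abs(piece) < 1e-16 * pmax(abs(D), 1e-300))) break
  }
  mottBetheConstant() * D / s^2
}

#' Evaluate a Peng-style Gaussian electron scattering factor
#'
#' The electron-diffraction Gaussian parameterization
#' \eqn{f^e(s) = \sum_i a_i e^{-b_i s^2}} in angstroms; unlike the X-ray
#' 4G+c tables it carries no constant term (a constant would Fourier
#' transform to a delta distribution), so a nonzero `c` is rejected.
#'
#' @param model A [GaussianFFModel-class] with `c == 0`.
#' @param s sin(theta)/lambda in inverse angstroms (vectorized), `s >= 0`.
#' @return Electron scattering factor in angstroms.
#' @export
pengEdFormFactor <- function(model, s) {
  if (model@c != 0)
    stop("electron Gaussian models must have zero constant term")
  gaussianFormFactor(model, s)
}
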