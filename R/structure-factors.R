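## Kinematic structure factors and SHELX-type weighting / R statistics.

#' Scattering-factor providers
#'
#' A provider is a function `(element, charge, s) -> f` used by
#' [structureFactor()] and [buildTsc()] to supply the per-species scattering
#' factor at arbitrary s. `slaterProvider` evaluates the analytic factors
#' from a [WavefunctionTable-class] (X-ray or electron via the Mott-Bethe
#' transform, with neutral fallback for missing ions);
#' `gaussianProvider` evaluates a list of [GaussianFFModel-class] keyed by
#' species (charge keys "El+1"/"El-1"); `constantProvider` returns a fixed
#' value per element, mainly for map oracles.
#'
#' @param table A [WavefunctionTable-class].
#' @param radiation `"xray"` or `"electron"`.
#' @return A function `(element, charge, s) -> numeric`.
#' @export
slaterProvider <- function(table, radiation = c("xray", "electron")) {
  radiation <- match.arg(radiation)
  force(table)
  function(element, charge, s) {
    wf <- lookupWavefunction(table, element, charge)
    if (radiation == "xray") xrayFormFactor(wf, s) else edFormFactor(wf, s)
  }
}

#' @rdname slaterProvider
#' @param models Named list of [GaussianFFModel-class] (names are species
#'   keys).
#' @param electron If TRUE evaluate as electron Gaussians (reject nonzero c).
#' @export
gaussianProvider <- function(models, electron = FALSE) {
  force(models); force(electron)
  function(element, charge, s) {
    key <- if (charge == 0) element else sprintf("%s%+g", element, charge)
    m <- models[[key]]
    if (is.null(m) && charge != 0) {
      m <- models[[element]]
      if (!is.null(m))
        warning("no Gaussian model for ", key, "; falling back to neutral ",
                element)
    }
    if (is.null(m)) stop("no Gaussian model for species '", key, "'")
    if (electron) pengEdFormFactor(m, s) else gaussianFormFactor(m, s)
  }
}

#' @rdname slaterProvider
#' @param values Named numeric vector, element -> constant f.
#' @export
constantProvider <- function(values) {
  force(values)
  function(element, charge, s) {
    if (!element %in% names(values)) stop("no constant for element '", element, "'")
    rep(values[[element]], length(s))
  }
}

#' Kinematic structure factor
#'
#' \eqn{F(h) = \sum_{sites} occ\; f(s)\, T(h)\, e^{2\pi i\, h\cdot x}} summed
#' over the symmetry-expanded (P1) site list, where \eqn{T} is the
#' Debye-Waller factor. Spherical scattering factors are real, so Friedel
#' symmetry \eqn{F(-h) = \overline{F(h)}} holds.
#'
#' @param model A [CrystalModel-class].
#' @param hkl Integer triple or n x 3 matrix of triples.
#' @param ffProvider Function `(element, charge, s) -> f`; see
#'   [slaterProvider()].
#' @return Complex vector of structure factors, one per reflection.
#' @export
structureFactor <- function(model, hkl, ffProvider) {
  H <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  s <- stol(model@cell, H)
  sites <- expandToP1(model)
  F <- complex(length.out = nrow(H))
  ## group sites by species so each f(s) vector is computed once
  speciesOf <- vapply(sites, function(st) paste(st@element, st@charge), character(1))
  for (sp in unique(speciesOf)) {
    first <- sites[[match(sp, speciesOf)]]
    f <- tryCatch(
      ffProvider(first@element, first@charge, s),
      error = function(e) stop("scattering-factor provider failed for species '",
                               first@element,
                               if (first@charge != 0) sprintf("%+g", first@charge) else "",
                               "': ", conditionMessage(e)))
    for (st in sites[speciesOf == sp]) {
      dw <- debyeWaller(st, model@cell, H)
      phase <- exp(2i * pi * as.numeric(H %*% st@xyz))
      F <- F + st@occupancy * f * dw * phase
    }
  }
  F
}

## ---- reflection records and statistics -------------------------------------

#' Reflection data container
#'
#' A plain data.frame with columns `h, k, l, Fo2, sigFo2` and optionally a
#' complex `Fc`; helper to attach s values from a cell.
#'
#' @param hkl n x 3 integer matrix.
#' @param Fo2,sigFo2 Observed squared structure factors and uncertainties.
#' @param Fc Optional complex calculated structure factors.
#' @return data.frame of reflection records.
#' @export
reflectionRecords <- function(hkl, Fo2, sigFo2, Fc = NULL) {
  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   Fo2 = Fo2, sigFo2 = sigFo2)
  if (!is.null(Fc)) df$Fc <- Fc
  df
}

#' SHELX-type weights and R statistics
#'
#' With \eqn{P = (\max(F_o^2, 0) + 2 F_c^2)/3}, the weights are
#' \deqn{w = 1 / [\sigma^2(F_o^2) + (aP)^2 + bP]}
#' and the residuals
#' \deqn{wR2 = \sqrt{\sum w (F_o^2 - F_c^2)^2 / \sum w (F_o^2)^2}, \quad
#'       R1 = \sum | |F_o| - |F_c| | / \sum |F_o|}
#' where R1 uses only reflections with \eqn{F_o^2 > 2\sigma(F_o^2)} (the
#' conventional I > 2 sigma cutoff). Negative \eqn{F_o^2} enter P clamped at
#' zero and contribute \eqn{|F_o| = 0} to R1.
#'
#' @param records data.frame with columns `Fo2`, `sigFo2` and complex or
#'   numeric `Fc` (|Fc| is used).
#' @param a,b Weighting parameters.
#' @return `list(R1, wR2, weights, nR1)` where `nR1` is the number of
#'   reflections above the R1 cutoff.
#' @export
weightsAndRstats <- function(records, a = 0, b = 0) {
  if (nrow(records) == 0) stop("empty reflection set")
  if (any(records$sigFo2 <= 0)) stop("sigFo2 must be positive")
  Fo2 <- records$Fo2
  Fc2 <- Mod(records$Fc)^2
  P <- (pmax(Fo2, 0) + 2 * Fc2) / 3
  w <- 1 / (records$sigFo2^2 + (a * P)^2 + b * P)
  wR2 <- sqrt(sum(w * (Fo2 - Fc2)^2) / sum(w * Fo2^2))
  strong <- Fo2 > 2 * records$sigFo2
  Fo <- sqrt(pmax(Fo2[strong], 0))
  Fc <- sqrt(Fc2[strong])
  R1 <- if (any(strong)) sum(abs(Fo - Fc)) / sum(Fo) else NA_real_
  list(R1 = R1, wR2 = wR2, weights = w, nR1 = sum(strong))
}
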