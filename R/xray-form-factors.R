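## Analytic X-ray scattering factors: three-dimensional Fourier transform of
## the Slater-orbital density, evaluated through sine/cosine integral
## recursions, plus the conventional Gaussian (4G+c) reference models.

#' Slater sine and cosine integrals
#'
#' \eqn{I_s(m; a, b) = \int_0^\infty r^m e^{-ar} \sin(br)\, dr} and the
#' analogous cosine integral \eqn{I_c}. Two independent evaluations are
#' provided: `method = "closed"` uses the closed forms
#' \eqn{m!\,\mathrm{Im}[(a - ib)^{-(m+1)}]} and
#' \eqn{m!\,\mathrm{Re}[(a - ib)^{-(m+1)}]}; `method = "recursion"` uses the
#' partial-integration recursion
#' \deqn{I_s(m) = \frac{m}{a^2+b^2}\,[a I_s(m-1) + b I_c(m-1)], \quad
#'       I_c(m) = \frac{m}{a^2+b^2}\,[a I_c(m-1) - b I_s(m-1)]}
#' seeded by \eqn{I_s(0) = b/(a^2+b^2)} and \eqn{I_c(0) = a/(a^2+b^2)}.
#' The two agree to better than 1e-12 relative for \eqn{m \le 16}.
#'
#' @param m Non-negative integer power of r.
#' @param a Positive exponential decay.
#' @param b Non-negative oscillation frequency (vectorized).
#' @param method `"closed"` (default) or `"recursion"`.
#' @return Integral values, same length as `b`.
#' @examples
#' slaterSinIntegral(1, 1, 1)   # 0.5
#' slaterCosIntegral(1, 1, 0)   # 1
#' @export
slaterSinIntegral <- function(m, a, b, method = c("closed", "recursion")) {
  .slaterTrigIntegral(m, a, b, match.arg(method))$sin
}

#' @rdname slaterSinIntegral
#' @export
slaterCosIntegral <- function(m, a, b, method = c("closed", "recursion")) {
  .slaterTrigIntegral(m, a, b, match.arg(method))$cos
}

.slaterTrigIntegral <- function(m, a, b, method) {
  if (length(m) != 1 || m < 0 || m != round(m))
    stop("'m' must be a single non-negative integer")
  if (length(a) != 1 || a <= 0) stop("'a' must be a single positive value")
  if (method == "closed") {
    w <- complex(real = a, imaginary = -b)^(-(m + 1)) * factorial(m)
    list(sin = Im(w), cos = Re(w))
  } else {
    d <- a^2 + b^2
    is <- b / d
    ic <- a / d
    k <- 0
    while (k < m) {
      k <- k + 1
      isNew <- (k / d) * (a * is + b * ic)
      ic <- (k / d) * (a * ic - b * is)
      is <- isNew
    }
    list(sin = is, cos = ic)
  }
}

## ---- cross-term expansion --------------------------------------------------

## Squaring each contracted orbital gives cross terms
##   weight * r^(nj + nl - 2) * exp(-(zj + zl) r),  weight = o N_j N_l c_j c_l.
## The triples (m = nj+nl, zsum, weight) fully determine the form factor and
## are computed once per wavefunction; results are identical to naive
## re-evaluation (tested).

#' Cross-term expansion of a squared Slater wavefunction
#'
#' Expands \eqn{\sum_i o_i R_i(r)^2} into elementary terms
#' \eqn{w\, r^{m-2} e^{-Z r}} and returns the data.frame of triples
#' (`m` = sum of radial orders, `zsum`, `weight`). All analytic integrals of
#' the density reduce to factorial/trig-integral identities on these triples.
#'
#' @param wf A [SlaterWavefunction-class].
#' @return data.frame with columns `m`, `zsum`, `weight`, aggregated over
#'   duplicate (m, zsum) pairs.
#' @export
crossTerms <- function(wf) {
  ms <- integer(); zs <- numeric(); ws <- numeric()
  for (orb in wf@orbitals) {
    p <- orb@primitives
    w <- p$norm * p$coeff
    W <- orb@occupation * outer(w, w)
    M <- outer(p$n, p$n, `+`)
    Z <- outer(p$zeta, p$zeta, `+`)
    ms <- c(ms, as.integer(M)); zs <- c(zs, as.numeric(Z)); ws <- c(ws, as.numeric(W))
  }
  key <- paste(ms, signif(zs, 14))
  agg <- rowsum(ws, key)
  first <- !duplicated(key)
  out <- data.frame(m = ms[first], zsum = zs[first], weight = agg[match(key[first], rownames(agg)), 1])
  rownames(out) <- NULL
  out
}

## Cache of cross terms keyed by a content signature, so repeated structure
## factor evaluations do not redo the outer products.
.ctCache <- new.env(parent = emptyenv())

.crossTermsCached <- function(wf) {
  sig <- paste(wf@element, wf@charge, wf@source,
               paste(vapply(wf@orbitals, function(o)
                 paste(o@occupation, paste(o@primitives$n, o@primitives$zeta,
                                           o@primitives$coeff, collapse = " ")),
                 character(1)), collapse = "|"))
  ct <- .ctCache[[sig]]
  if (is.null(ct)) {
    ct <- crossTerms(wf)
    assign(sig, ct, envir = .ctCache)
  }
  ct
}

## ---- the analytic form factor ----------------------------------------------

#' Analytic X-ray scattering factor of a Slater wavefunction
#'
#' Evaluates \eqn{f(s) = \int \rho(r)\, 4\pi r^2\, \mathrm{sinc}(kr)\, dr}
#' in closed form, where \eqn{k = 4\pi s} is converted from inverse angstroms
#' to inverse bohr at the boundary. Each cross term contributes
#' \eqn{(w/k)\, I_s(m - 1; Z, k)}; at \eqn{k = 0} (and below 1e-8 inverse
#' bohr, to guard underflow) the analytic limit \eqn{w\, m! / Z^{m+1}} is
#' used. The limit branch makes \eqn{f(0)} equal the electron count exactly
#' and is continuous with the k > 0 branch.
#'
#' @param wf A [SlaterWavefunction-class].
#' @param s sin(theta)/lambda in inverse angstroms (vectorized), `s >= 0`.
#' @return Scattering factor in electrons, same length as `s`.
#' @examples
#' xrayFormFactor(makeHydrogen(1.0), 0)     # 1 electron
#' @export
xrayFormFactor <- function(wf, s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  ct <- .crossTermsCached(wf)
  k <- 4 * pi * s * bohrToAngstrom()   # inverse bohr
  f <- numeric(length(s))
  small <- k < 1e-8
  if (any(small))
    f[small] <- sum(ct$weight * factorial(ct$m) / ct$zsum^(ct$m + 1))
  if (any(!small)) {
    kk <- k[!small]
    acc <- numeric(length(kk))
    for (t in seq_len(nrow(ct))) {
      acc <- acc + ct$weight[t] *
        slaterSinIntegral(ct$m[t] - 1L, ct$zsum[t], kk) / kk
    }
    f[!small] <- acc
  }
  f
}

## ---- Gaussian reference models ---------------------------------------------

#' Gaussian scattering-factor model (4G+c and relatives)
#'
#' The conventional parameterization
#' \eqn{f(s) = \sum_i a_i \exp(-b_i s^2) + c} with four (or five) Gaussian
#' terms; `c = 0` for electron-diffraction Gaussian tables.
#'
#' @slot species Species tag ("C", "O-1", ...).
#' @slot a Amplitudes (electrons, or angstroms for electron tables).
#' @slot b Widths in square angstroms, same length as `a`, all >= 0.
#' @slot c Constant term.
#' @export
setClass("GaussianFFModel",
  representation(species = "character", a = "numeric", b = "numeric",
                 c = "numeric"))

setValidity("GaussianFFModel", function(object) {
  msgs <- character()
  if (length(object@a) != length(object@b))
    msgs <- c(msgs, "a and b must have equal length")
  if (any(object@b < 0)) msgs <- c(msgs, "b terms must be >= 0")
  if (length(object@c) != 1) msgs <- c(msgs, "c must be a scalar")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GaussianFFModel-class
#' @param species,a,b,c Model fields.
#' @return A `GaussianFFModel`.
#' @export
gaussianFFModel <- function(species, a, b, c = 0) {
  new("GaussianFFModel", species = species, a = as.numeric(a),
      b = as.numeric(b), c = as.numeric(c))
}

setMethod("show", "GaussianFFModel", function(object) {
  cat(sprintf("GaussianFFModel %s: %dG%s, f(0) = %.4f\n", object@species,
              length(object@a), if (object@c != 0) "+c" else "",
              sum(object@a) + object@c))
  invisible(NULL)
})

#' Evaluate a Gaussian scattering-factor model
#'
#' \eqn{f(s) = \sum_i a_i e^{-b_i s^2} + c}.
#'
#' @param model A [GaussianFFModel-class].
#' @param s sin(theta)/lambda in inverse angstroms (vectorized).
#' @return Scattering factor values.
#' @export
gaussianFormFactor <- function(model, s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  vapply(s, function(si) sum(model@a * exp(-model@b * si^2)) + model@c,
         numeric(1))
}

#' Read a Gaussian coefficient table
#'
#' CSV with columns `species, a1..a5, b1..b5, c` (unused terms zero,
#' `#`-comment header lines allowed). Trailing all-zero Gaussian terms are
#' dropped, so a 4G+c table and a 5G table share the format.
#'
#' @param path CSV file path.
#' @return Named list of [GaussianFFModel-class], keyed by species.
#' @export
readGaussianTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", paste0("a", 1:5), paste0("b", 1:5), "c")
  if (!all(need %in% names(df)))
    stop("Gaussian table must have columns: ", paste(need, collapse = ", "))
  models <- lapply(seq_len(nrow(df)), function(i) {
    a <- as.numeric(df[i, paste0("a", 1:5)])
    b <- as.numeric(df[i, paste0("b", 1:5)])
    keep <- !(a == 0 & b == 0)
    ## keep a contiguous prefix; all bundled tables are laid out this way
    nterm <- max(which(keep), 0L)
    gaussianFFModel(df$species[i], a[seq_len(nterm)], b[seq_len(nterm)],
                    df$c[i])
  })
  names(models) <- df$species
  models
}

## ---- scattering curves -----------------------------------------------------

#' Tabulated scattering curve of one species
#'
#' A scattering factor sampled on an ascending grid of
#' s = sin(theta)/lambda values for one species and one radiation type.
#' X-ray values are in electrons, electron-diffraction values in angstroms.
#'
#' @slot species Species tag.
#' @slot radiation `"xray"` or `"electron"`.
#' @slot sGrid Strictly increasing s values (inverse angstroms, >= 0).
#' @slot values Scattering factor values, finite.
#' @export
setClass("ScatteringCurve",
  representation(species = "character", radiation = "character",
                 sGrid = "numeric", values = "numeric"))

setValidity("ScatteringCurve", function(object) {
  msgs <- character()
  if (!object@radiation %in% c("xray", "electron"))
    msgs <- c(msgs, "radiation must be 'xray' or 'electron'")
  if (length(object@sGrid) != length(object@values))
    msgs <- c(msgs, "sGrid and values must have equal length")
  if (length(object@sGrid) && (any(diff(object@sGrid) <= 0) || any(object@sGrid < 0)))
    msgs <- c(msgs, "sGrid must be non-negative and strictly increasing")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScatteringCurve-class
#' @param species,radiation,sGrid,values Curve fields.
#' @return A `ScatteringCurve`.
#' @export
scatteringCurve <- function(species, radiation, sGrid, values) {
  new("ScatteringCurve", species = species, radiation = radiation,
      sGrid = as.numeric(sGrid), values = as.numeric(values))
}

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve %s [%s], %d points, s in [%g, %g]\n",
              object@species, object@radiation, length(object@sGrid),
              min(object@sGrid), max(object@sGrid)))
  invisible(NULL)
})

#' Pointwise difference of two scattering curves
#'
#' Curves must share the s grid and radiation type; the species of the
#' result records the pair as "A - B".
#'
#' @param curveA,curveB [ScatteringCurve-class] objects.
#' @return A [ScatteringCurve-class] of differences.
#' @export
differenceCurve <- function(curveA, curveB) {
  if (curveA@radiation != curveB@radiation)
    stop("radiation types differ")
  if (length(curveA@sGrid) != length(curveB@sGrid) ||
      any(abs(curveA@sGrid - curveB@sGrid) > 1e-12))
    stop("s grids differ")
  scatteringCurve(paste(curveA@species, "-", curveB@species),
                  curveA@radiation, curveA@sGrid,
                  curveA@values - curveB@values)
}

#' Export a scattering curve as two-column CSV
#'
#' @param curve A [ScatteringCurve-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeCurveCSV <- function(curve, path) {
  utils::write.csv(data.frame(s = curve@sGrid, f = curve@values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
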