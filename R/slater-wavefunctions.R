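## Slater-type orbital atomic wavefunctions: data model, normalization,
## radial density and closed-form radial moments.
##
## A contracted orbital is  R_i(r) = sum_j N_j c_j r^(n_j - 1) exp(-zeta_j r)
## and the spherically averaged electron density is
##   rho(r) = (1/4pi) sum_i o_i R_i(r)^2
## so that the electron count is the plain radial integral of 4 pi r^2 rho(r).
## All radii and exponents are in bohr / inverse bohr.

#' @import methods
NULL

#' Normalization constant of a Slater-type radial primitive
#'
#' For the primitive \eqn{N r^{n-1} e^{-\zeta r}} the unit-norm condition
#' \eqn{\int_0^\infty (N r^{n-1} e^{-\zeta r})^2 r^2 dr = 1} gives the closed
#' form \eqn{N = (2\zeta)^{n + 1/2} / \sqrt{(2n)!}}.
#'
#' @param n Integer radial order, `n >= 1`.
#' @param zeta Positive exponent in inverse bohr.
#' @return The normalization constant (vectorized over `n` and `zeta`).
#' @examples
#' slaterNorm(1, 1.0)   # hydrogenic 1s: 2
#' slaterNorm(1, 1.15)  # bonded-hydrogen convention
#' @export
slaterNorm <- function(n, zeta) {
  if (any(n < 1) || any(n != round(n)))
    stop("'n' must be a positive integer")
  if (any(zeta <= 0))
    stop("'zeta' must be positive")
  (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
}

## ---- classes ---------------------------------------------------------------

#' Atomic orbital of contracted Slater-type primitives
#'
#' An `AtomicOrbital` holds one shell (label such as "1s", "2p", ...), its
#' angular momentum, its electron occupation and the table of Slater
#' primitives. Primitives are rows of the `primitives` data.frame with
#' columns `n` (radial order), `zeta` (exponent, inverse bohr), `coeff`
#' (contraction coefficient) and `norm` (unit-norm constant, derived).
#'
#' @slot label Shell name.
#' @slot lAng Angular momentum quantum number (integer, >= 0).
#' @slot occupation Electrons in the shell (0 <= o <= 2(2l+1)).
#' @slot primitives data.frame of Slater primitives.
#' @export
setClass("AtomicOrbital",
  representation(label = "character", lAng = "integer",
                 occupation = "numeric", primitives = "data.frame"))

setValidity("AtomicOrbital", function(object) {
  p <- object@primitives
  msgs <- character()
  if (nrow(p) < 1) msgs <- c(msgs, "orbital needs at least one primitive")
  if (!all(c("n", "zeta", "coeff", "norm") %in% names(p)))
    msgs <- c(msgs, "primitives must have columns n, zeta, coeff, norm")
  else {
    if (any(p$n < 1 | p$n != round(p$n))) msgs <- c(msgs, "primitive n must be integer >= 1")
    if (any(p$zeta <= 0)) msgs <- c(msgs, "primitive zeta must be > 0")
  }
  if (object@lAng < 0) msgs <- c(msgs, "lAng must be >= 0")
  if (object@occupation < 0 || object@occupation > 2 * (2 * object@lAng + 1))
    msgs <- c(msgs, "occupation must lie in [0, 2(2l+1)]")
  if (length(msgs)) msgs else TRUE
})

#' Construct an atomic orbital
#'
#' @param label Shell label ("1s", "2p", ...).
#' @param lAng Angular momentum integer; by default inferred from the letter
#'   in `label` (s=0, p=1, d=2, f=3).
#' @param occupation Electrons in the shell.
#' @param n,zeta,coeff Vectors describing the Slater primitives.
#' @return An [AtomicOrbital-class] object.
#' @export
atomicOrbital <- function(label, occupation, n, zeta, coeff, lAng = NULL) {
  if (is.null(lAng)) {
    letter <- sub("^[0-9]+", "", label)
    lAng <- match(letter, c("s", "p", "d", "f")) - 1L
    if (is.na(lAng)) stop("cannot infer angular momentum from label '", label, "'")
  }
  prim <- data.frame(n = as.integer(n), zeta = as.numeric(zeta),
                     coeff = as.numeric(coeff))
  prim$norm <- slaterNorm(prim$n, prim$zeta)
  new("AtomicOrbital", label = label, lAng = as.integer(lAng),
      occupation = as.numeric(occupation), primitives = prim)
}

#' Slater-type atomic wavefunction
#'
#' The full spherical atomic wavefunction of one species: element identity,
#' nuclear charge Z, net charge q and the list of occupied
#' [AtomicOrbital-class] shells. The electron count invariant
#' \eqn{\sum_i o_i = Z - q} is enforced by the validity method.
#'
#' @slot element Element symbol (free text for synthetic species).
#' @slot zNuclear Atomic number Z.
#' @slot charge Net charge q (-1, 0 or +1 for tabulated species).
#' @slot orbitals List of [AtomicOrbital-class].
#' @slot source Free-text provenance tag.
#' @export
setClass("SlaterWavefunction",
  representation(element = "character", zNuclear = "integer",
                 charge = "numeric", orbitals = "list", source = "character"))

setValidity("SlaterWavefunction", function(object) {
  msgs <- character()
  if (length(object@orbitals) < 1) msgs <- c(msgs, "need at least one orbital")
  if (!all(vapply(object@orbitals, is, logical(1), "AtomicOrbital")))
    msgs <- c(msgs, "orbitals must all be AtomicOrbital objects")
  else {
    occ <- sum(vapply(object@orbitals, function(o) o@occupation, numeric(1)))
    expect <- object@zNuclear - object@charge
    if (abs(occ - expect) > 1e-9)
      msgs <- c(msgs, sprintf("electron count %.6g does not equal Z - q = %g", occ, expect))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Slater wavefunction
#'
#' @param element Element symbol.
#' @param zNuclear Atomic number.
#' @param charge Net charge.
#' @param orbitals List of [AtomicOrbital-class] objects.
#' @param source Provenance tag.
#' @return A [SlaterWavefunction-class] object.
#' @export
slaterWavefunction <- function(element, zNuclear, charge = 0L, orbitals,
                               source = "") {
  new("SlaterWavefunction", element = element, zNuclear = as.integer(zNuclear),
      charge = as.numeric(charge), orbitals = orbitals, source = source)
}

setMethod("show", "SlaterWavefunction", function(object) {
  cat(sprintf("SlaterWavefunction %s (Z=%d, q=%+g), %d orbital(s), %g electrons\n",
              object@element, object@zNuclear, object@charge,
              length(object@orbitals), electronCount(object)))
  for (o in object@orbitals)
    cat(sprintf("  %-3s l=%d occ=%-4g %d primitive(s)\n",
                o@label, o@lAng, o@occupation, nrow(o@primitives)))
  invisible(NULL)
})

## ---- accessors -------------------------------------------------------------

#' @rdname slaterWavefunction
#' @param object,wf A [SlaterWavefunction-class].
#' @export
setGeneric("element", function(object) standardGeneric("element"))

#' @rdname slaterWavefunction
#' @export
setMethod("element", "SlaterWavefunction", function(object) object@element)

#' @rdname slaterWavefunction
#' @export
setGeneric("netCharge", function(object) standardGeneric("netCharge"))

#' @rdname slaterWavefunction
#' @export
setMethod("netCharge", "SlaterWavefunction", function(object) object@charge)

#' @rdname slaterWavefunction
#' @export
setGeneric("atomicNumber", function(object) standardGeneric("atomicNumber"))

#' @rdname slaterWavefunction
#' @export
setMethod("atomicNumber", "SlaterWavefunction", function(object) object@zNuclear)

#' Electron count of a wavefunction
#'
#' Sum of shell occupations. For unit-normalized contracted orbitals (all
#' bundled and generated tables are) this equals the closed-form radial
#' integral of the spherical density, `4 pi r^2 rho(r)`, via factorial
#' identities; [orbitalNorm2()] exposes the actual contraction norm for
#' diagnostics.
#'
#' @param wf A [SlaterWavefunction-class].
#' @return Number of electrons.
#' @export
electronCount <- function(wf) {
  sum(vapply(wf@orbitals, function(o) o@occupation, numeric(1)))
}

#' Radial self-overlap of a contracted orbital
#'
#' Closed-form \eqn{\langle R_i | R_i \rangle} of the contracted radial
#' function; 1 for a properly normalized contraction. Uses
#' \eqn{\int_0^\infty r^m e^{-ar} dr = m!/a^{m+1}} on the cross terms.
#'
#' @param orb An [AtomicOrbital-class].
#' @return The overlap integral.
#' @export
orbitalNorm2 <- function(orb) .orbitalNorm2(orb)

## <R_i|R_i> radial overlap of a contracted orbital, closed form:
## int r^(nj+nl-2) e^-(zj+zl)r r^2 dr = (nj+nl)! / (zj+zl)^(nj+nl+1)
.orbitalNorm2 <- function(orb) {
  p <- orb@primitives
  w <- p$norm * p$coeff
  nj <- outer(p$n, p$n, `+`)
  zz <- outer(p$zeta, p$zeta, `+`)
  sum(outer(w, w) * factorial(nj) / zz^(nj + 1))
}

#' Spherically averaged electron density
#'
#' \eqn{\rho(r) = (1/4\pi) \sum_i o_i [\sum_j N_j c_j r^{n_j-1}
#' e^{-\zeta_j r}]^2}, in electrons per cubic bohr. The \eqn{1/4\pi}
#' spherical-averaging factor lives here so that the Fourier transform in
#' [xrayFormFactor()] carries the plain \eqn{4\pi r^2} volume element and
#' \eqn{f(0)} equals the electron count.
#'
#' @param wf A [SlaterWavefunction-class].
#' @param r Radii in bohr (vectorized), `r >= 0`.
#' @return Density values, electrons per cubic bohr.
#' @examples
#' radialDensity(makeHydrogen(1.0), 0)  # 1/pi
#' @export
radialDensity <- function(wf, r) {
  if (any(r < 0)) stop("'r' must be non-negative")
  rho <- numeric(length(r))
  for (orb in wf@orbitals) {
    p <- orb@primitives
    radial <- numeric(length(r))
    for (j in seq_len(nrow(p)))
      radial <- radial + p$norm[j] * p$coeff[j] * r^(p$n[j] - 1) * exp(-p$zeta[j] * r)
    rho <- rho + orb@occupation * radial^2
  }
  rho / (4 * pi)
}

#' Mean square radius of the atomic density
#'
#' \eqn{\langle r^2\rangle = \int \rho(r) 4\pi r^4 dr / N_e} in square bohr,
#' evaluated in closed form via the factorial identity
#' \eqn{\int_0^\infty r^m e^{-a r} dr = m!/a^{m+1}}. This is the per-electron
#' mean; it feeds the small-angle limit of the Mott--Bethe transform.
#'
#' @param wf A [SlaterWavefunction-class].
#' @return Mean square radius in square bohr.
#' @examples
#' meanSquareRadius(makeHydrogen(1.0))  # 3 bohr^2
#' @export
meanSquareRadius <- function(wf) {
  total <- 0
  for (orb in wf@orbitals) {
    p <- orb@primitives
    w <- p$norm * p$coeff
    nj <- outer(p$n, p$n, `+`)
    zz <- outer(p$zeta, p$zeta, `+`)
    ## <r^2> contribution: int r^(nj+nl-2) e^-zz r r^4 dr = (nj+nl+2)!/zz^(nj+nl+3)
    total <- total + orb@occupation *
      sum(outer(w, w) * factorial(nj + 2) / zz^(nj + 3))
  }
  total / electronCount(wf)
}

## ---- wavefunction tables ---------------------------------------------------

#' Table of Slater wavefunctions keyed by (element, charge)
#'
#' A `WavefunctionTable` maps species to [SlaterWavefunction-class] entries.
#' Looking up an ion that has no tabulated wavefunction falls back to the
#' neutral species with a warning, matching the behaviour of the scattering
#' factor interface for ions without tabulated wavefunctions.
#'
#' @slot entries Named list; names are "El" or "El+1"/"El-1".
#' @export
setClass("WavefunctionTable", representation(entries = "list"))

.speciesKey <- function(element, charge) {
  if (charge == 0) element else sprintf("%s%+g", element, charge)
}

#' @rdname WavefunctionTable-class
#' @param wfs List of [SlaterWavefunction-class] objects.
#' @return A `WavefunctionTable`.
#' @export
wavefunctionTable <- function(wfs = list()) {
  names(wfs) <- vapply(wfs, function(w) .speciesKey(w@element, w@charge), character(1))
  if (anyDuplicated(names(wfs)))
    stop("duplicate species in wavefunction table")
  new("WavefunctionTable", entries = wfs)
}

setMethod("show", "WavefunctionTable", function(object) {
  cat("WavefunctionTable with", length(object@entries), "species:",
      paste(names(object@entries), collapse = " "), "\n")
  invisible(NULL)
})

#' Look up a species in a wavefunction table
#'
#' @param table A [WavefunctionTable-class].
#' @param element Element symbol.
#' @param charge Net charge; if the ion is missing the neutral entry is
#'   returned with a warning (ion fallback).
#' @return A [SlaterWavefunction-class].
#' @export
lookupWavefunction <- function(table, element, charge = 0L) {
  key <- .speciesKey(element, charge)
  wf <- table@entries[[key]]
  if (!is.null(wf)) return(wf)
  if (charge != 0L) {
    wf <- table@entries[[element]]
    if (!is.null(wf)) {
      warning("no wavefunction for ", key,
              "; falling back to neutral ", element)
      return(wf)
    }
  }
  stop("no wavefunction for species '", key, "'")
}

#' Species available in a table
#' @param table A [WavefunctionTable-class].
#' @return Character vector of species keys.
#' @export
speciesNames <- function(table) names(table@entries)

## ---- text format -----------------------------------------------------------

#' Read and write the line-oriented wavefunction coefficient format
#'
#' The format is:
#' \preformatted{
#' # comment
#' ELEMENT <symbol> <Z> <charge>
#' ORBITAL <label> <l> <occupation>
#' PRIM <n> <zeta> <coeff>
#' }
#' with entries separated by blank lines; `zeta` is in inverse bohr. Parsing
#' is round-trip stable: `writeWavefunctionTable(parseWavefunctionTable(x))`
#' reproduces the canonical serialization of `x`, and every parsed entry must
#' satisfy the wavefunction invariants (electron count equals `Z - charge`).
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @return `parseWavefunctionTable`: a [WavefunctionTable-class].
#' @export
parseWavefunctionTable <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  wfs <- list()
  cur <- NULL     # list(element, z, charge, orbitals)
  curOrb <- NULL  # list(label, l, occ, n, zeta, coeff)
  flushOrb <- function() {
    if (is.null(curOrb)) return()
    if (length(curOrb$n) == 0)
      stop("orbital '", curOrb$label, "' has no primitives")
    cur$orbitals[[length(cur$orbitals) + 1L]] <<-
      atomicOrbital(curOrb$label, curOrb$occ, curOrb$n, curOrb$zeta,
                    curOrb$coeff, lAng = curOrb$l)
    curOrb <<- NULL
  }
  flushEntry <- function() {
    if (is.null(cur)) return()
    flushOrb()
    wfs[[length(wfs) + 1L]] <<- slaterWavefunction(
      cur$element, cur$z, cur$charge, cur$orbitals, source = "parsed")
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    ok <- tryCatch({
      switch(tok[1],
        ELEMENT = {
          flushEntry()
          if (length(tok) != 4) stop("ELEMENT needs symbol, Z, charge")
          cur <- list(element = tok[2], z = as.integer(tok[3]),
                      charge = as.numeric(tok[4]), orbitals = list())
        },
        ORBITAL = {
          if (is.null(cur)) stop("ORBITAL before ELEMENT")
          flushOrb()
          if (length(tok) != 4) stop("ORBITAL needs label, l, occupation")
          curOrb <- list(label = tok[2], l = as.integer(tok[3]),
                         occ = as.numeric(tok[4]),
                         n = integer(), zeta = numeric(), coeff = numeric())
        },
        PRIM = {
          if (is.null(curOrb)) stop("PRIM before ORBITAL")
          if (length(tok) != 4) stop("PRIM needs n, zeta, coeff")
          curOrb$n <- c(curOrb$n, as.integer(tok[2]))
          curOrb$zeta <- c(curOrb$zeta, as.numeric(tok[3]))
          curOrb$coeff <- c(curOrb$coeff, as.numeric(tok[4]))
        },
        stop("unknown record '", tok[1], "'")
      )
      TRUE
    }, error = function(e) e)
    if (inherits(ok, "error"))
      stop("wavefunction table parse error at line ", i, ": ",
           conditionMessage(ok))
  }
  tryCatch(flushEntry(), error = function(e)
    stop("wavefunction table parse error at line ", length(lines), ": ",
         conditionMessage(e)))
  wavefunctionTable(wfs)
}

#' @rdname parseWavefunctionTable
#' @param table A [WavefunctionTable-class].
#' @return `writeWavefunctionTable`: a character scalar in canonical form
#'   (coefficients printed with \%.10g).
#' @export
writeWavefunctionTable <- function(table) {
  out <- character()
  for (wf in table@entries) {
    out <- c(out, sprintf("ELEMENT %s %d %.10g", wf@element, wf@zNuclear, wf@charge))
    for (orb in wf@orbitals) {
      out <- c(out, sprintf("ORBITAL %s %d %.10g", orb@label, orb@lAng,
                            orb@occupation))
      p <- orb@primitives
      out <- c(out, sprintf("PRIM %d %.10g %.10g", p$n, p$zeta, p$coeff))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname parseWavefunctionTable
#' @param path File path to read.
#' @export
readWavefunctionTable <- function(path) {
  parseWavefunctionTable(readLines(path, warn = FALSE))
}
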