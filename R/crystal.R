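## Crystal models: unit cell metrics, atomic sites with displacement
## parameters, symmetry operations, and reflection geometry.

#' Unit cell
#'
#' Cell lengths in angstroms, angles in degrees. The direct metric tensor
#' G, its inverse (the reciprocal metric, used for d-spacings) and the cell
#' volume are derived on construction.
#'
#' @slot a,b,c Cell lengths (angstroms).
#' @slot alpha,beta,gamma Cell angles (degrees).
#' @slot volume Cell volume (cubic angstroms), derived.
#' @slot metric Direct metric tensor (3x3).
#' @slot reciprocalMetric Inverse metric tensor (3x3, square inverse
#'   angstroms).
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 volume = "numeric", metric = "matrix",
                 reciprocalMetric = "matrix"))

setValidity("UnitCell", function(object) {
  msgs <- character()
  if (object@volume <= 0) msgs <- c(msgs, "cell volume must be positive")
  ev <- eigen(object@metric, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) msgs <- c(msgs, "metric must be positive definite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname UnitCell-class
#' @param a,b,c,alpha,beta,gamma Cell parameters (angstroms / degrees).
#' @return A `UnitCell`.
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a, a * b * cg, a * c * cb,
                a * b * cg, b * b, b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  vol <- sqrt(det(G))
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma, volume = vol, metric = G, reciprocalMetric = solve(G))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell a=%.4f b=%.4f c=%.4f  %.2f/%.2f/%.2f deg  V=%.3f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, object@volume))
  invisible(NULL)
})

#' Cell volume accessor
#' @param object A [UnitCell-class] or [CrystalModel-class].
#' @return Volume in cubic angstroms.
#' @export
setGeneric("cellVolume", function(object) standardGeneric("cellVolume"))

#' @rdname cellVolume
#' @export
setMethod("cellVolume", "UnitCell", function(object) object@volume)

#' Reciprocal cell axis lengths
#' @param cell A [UnitCell-class].
#' @return Numeric length-3 vector of a*, b*, c* (inverse angstroms).
#' @export
reciprocalLengths <- function(cell) sqrt(diag(cell@reciprocalMetric))

#' sin(theta)/lambda of a reflection
#'
#' \eqn{s = |h A^*|/2 = \sqrt{h^T G^{-1} h}/2} via the reciprocal metric;
#' equivalently \eqn{1/(2d)}.
#'
#' @param cell A [UnitCell-class].
#' @param hkl Integer triple, or an n x 3 matrix of triples.
#' @return s in inverse angstroms (one value per row).
#' @examples
#' stol(unitCell(10, 10, 10), c(2, 0, 0))   # 0.1
#' @export
stol <- function(cell, hkl) {
  H <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  0.5 * sqrt(rowSums((H %*% cell@reciprocalMetric) * H))
}

#' Enumerate all reflections to a resolution limit
#'
#' All Miller index triples (excluding 000) with d-spacing
#' \eqn{d = 1/(2s) \ge d_{min}}. Friedel mates are both present.
#'
#' @param cell A [UnitCell-class].
#' @param dMin Resolution limit in angstroms, > 0.
#' @return Integer matrix with columns h, k, l and attribute `"s"`.
#' @export
hklSphere <- function(cell, dMin) {
  if (dMin <= 0) stop("'dMin' must be positive")
  sMax <- 1 / (2 * dMin)
  ## per-axis bound: |h_i| <= |a_i| / d_min (projection on the direct axis)
  lim <- ceiling(c(cell@a, cell@b, cell@c) / dMin)
  g <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  H <- as.matrix(g)
  s <- stol(cell, H)
  keep <- s <= sMax + 1e-12 & s > 0
  H <- H[keep, , drop = FALSE]
  s <- s[keep]
  ord <- order(stol(cell, H), H[, 1], H[, 2], H[, 3])
  H <- H[ord, , drop = FALSE]
  storage.mode(H) <- "integer"
  dimnames(H) <- list(NULL, c("h", "k", "l"))
  attr(H, "s") <- s[ord]
  H
}

## ---- atomic sites ----------------------------------------------------------

#' Atomic site in a crystal model
#'
#' Fractional coordinates, occupancy and displacement parameters. The ADP is
#' either a scalar `uIso` (square angstroms) or a symmetric 3x3 `uAniso`
#' matrix in the CIF U_ij convention. Deposited occupancies are trusted
#' verbatim (they may include special-position multiplicity factors). A
#' non-positive-semidefinite anisotropic U warns but does not fail, since
#' deposited files occasionally contain such entries.
#'
#' @slot label Atom label (e.g. "Os1").
#' @slot element Element symbol.
#' @slot charge Charge hint used for species lookup.
#' @slot xyz Fractional coordinates, length 3.
#' @slot occupancy In (0, 1].
#' @slot uIso Isotropic U (square angstroms) or NA when anisotropic.
#' @slot uAniso 3x3 U_ij matrix or a 0x0 matrix when isotropic.
#' @export
setClass("AtomSite",
  representation(label = "character", element = "character",
                 charge = "integer", xyz = "numeric", occupancy = "numeric",
                 uIso = "numeric", uAniso = "matrix"))

setValidity("AtomSite", function(object) {
  msgs <- character()
  if (length(object@xyz) != 3) msgs <- c(msgs, "xyz must have length 3")
  if (object@occupancy <= 0 || object@occupancy > 1 + 1e-9)
    msgs <- c(msgs, "occupancy must lie in (0, 1]")
  if (!is.na(object@uIso) && object@uIso < 0)
    msgs <- c(msgs, "uIso must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AtomSite-class
#' @param label,element,xyz,occupancy,uIso,uAniso,charge Site fields.
#' @return An `AtomSite`.
#' @export
atomSite <- function(label, element, xyz, occupancy = 1, uIso = 0,
                     uAniso = NULL, charge = 0L) {
  if (!is.null(uAniso)) {
    uAniso <- (uAniso + t(uAniso)) / 2
    ev <- eigen(uAniso, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8))
      warning("anisotropic U of site '", label, "' is not positive-semidefinite")
    uIso <- NA_real_
  } else uAniso <- matrix(numeric(0), 0, 0)
  new("AtomSite", label = label, element = element, charge = as.integer(charge),
      xyz = as.numeric(xyz), occupancy = occupancy, uIso = uIso,
      uAniso = uAniso)
}

isAnisotropic <- function(site) nrow(site@uAniso) == 3

#' Crystal model
#'
#' Unit cell, symmetry operations in fractional coordinates, and atomic
#' sites. Each symmetry operation is a `list(R = 3x3 integer matrix,
#' t = length-3 translation)`. Validity checks that the identity is present
#' and warns if the set is not closed under composition modulo lattice
#' translations.
#'
#' @slot cell A [UnitCell-class].
#' @slot symops List of symmetry operations.
#' @slot sites List of [AtomSite-class].
#' @export
setClass("CrystalModel",
  representation(cell = "UnitCell", symops = "list", sites = "list"))

setValidity("CrystalModel", function(object) {
  msgs <- character()
  hasId <- any(vapply(object@symops, function(op)
    all(op$R == diag(3)) && all(abs(op$t %% 1) < 1e-9), logical(1)))
  if (!hasId) msgs <- c(msgs, "symmetry operations must include the identity")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CrystalModel-class
#' @param cell,symops,sites Model components; `symops` defaults to P1.
#' @return A `CrystalModel`.
#' @export
crystalModel <- function(cell, sites, symops = list(list(R = diag(3), t = c(0, 0, 0)))) {
  m <- new("CrystalModel", cell = cell, symops = symops, sites = sites)
  .checkSymopClosure(m)
  m
}

.symopKey <- function(R, t) paste(c(as.integer(round(R)), round((t %% 1) * 1e6)), collapse = ",")

.checkSymopClosure <- function(model) {
  keys <- vapply(model@symops, function(op) .symopKey(op$R, op$t), character(1))
  for (op1 in model@symops) for (op2 in model@symops) {
    R <- op1$R %*% op2$R
    t <- (op1$R %*% op2$t + op1$t) %% 1
    if (!.symopKey(R, t) %in% keys) {
      warning("symmetry operations are not closed under composition")
      return(invisible(FALSE))
    }
  }
  invisible(TRUE)
}

setMethod("show", "CrystalModel", function(object) {
  cat(sprintf("CrystalModel: %d site(s), %d symop(s)\n",
              length(object@sites), length(object@symops)))
  show(object@cell)
  invisible(NULL)
})

#' @rdname cellVolume
#' @export
setMethod("cellVolume", "CrystalModel", function(object) object@cell@volume)

## ---- symmetry expansion ----------------------------------------------------

#' Parse a symmetry operation string
#'
#' Accepts CIF-style strings such as `"-x, y+1/2, -z+1/2"` and returns the
#' rotation matrix / translation pair.
#'
#' @param xyz Symmetry string.
#' @return `list(R = 3x3 matrix, t = length-3 numeric)`.
#' @export
parseSymop <- function(xyz) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(xyz)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry string must have 3 components: ", xyz)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    ## tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (grepl("^[xyz]$", tm)) {
        R[i, match(tm, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        nd <- as.numeric(strsplit(tm, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        t[i] <- t[i] + sign * as.numeric(tm)
      } else if (grepl("^[0-9.]+[xyz]$", tm) || grepl("^[0-9]+/[0-9]+[xyz]$", tm)) {
        ax <- substring(tm, nchar(tm))
        co <- substring(tm, 1, nchar(tm) - 1)
        val <- if (grepl("/", co)) {
          nd <- as.numeric(strsplit(co, "/", fixed = TRUE)[[1]]); nd[1] / nd[2]
        } else as.numeric(co)
        R[i, match(ax, c("x", "y", "z"))] <- sign * val
      } else stop("cannot parse symmetry term '", tm, "' in: ", xyz)
    }
  }
  list(R = R, t = t)
}

#' Format a symmetry operation as a CIF-style string
#' @param op `list(R, t)` as returned by [parseSymop()].
#' @return Character scalar such as `"-x, y+1/2, -z+1/2"`.
#' @export
formatSymop <- function(op) {
  comp <- character(3)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    parts <- character()
    for (j in 1:3) {
      cf <- op$R[i, j]
      if (cf == 0) next
      piece <- if (abs(cf) == 1) ax[j] else paste0(abs(cf), ax[j])
      parts <- c(parts, paste0(if (cf < 0) "-" else if (length(parts)) "+" else "", piece))
    }
    tv <- op$t[i] %% 1
    if (abs(tv) > 1e-9) {
      fr <- .asFraction(tv)
      parts <- c(parts, paste0("+", fr))
    }
    comp[i] <- paste(parts, collapse = "")
  }
  paste(comp, collapse = ", ")
}

.asFraction <- function(x, maxden = 24) {
  for (d in 1:maxden) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(sprintf("%d/%d", n, d))
  }
  sprintf("%.6f", x)
}

#' Expand sites to P1
#'
#' Applies every symmetry operation to every site, wraps coordinates into
#' [0, 1) and removes duplicate positions within a fractional tolerance
#' (default 1e-4), so that special positions are not double counted.
#' Anisotropic U matrices are transformed as \eqn{U' = R U R^T}.
#'
#' @param model A [CrystalModel-class].
#' @param tol Fractional de-duplication tolerance.
#' @return List of [AtomSite-class] covering the full cell.
#' @export
expandToP1 <- function(model, tol = 1e-4) {
  out <- list()
  seen <- list()   # per original site: matrix of kept positions
  for (site in model@sites) {
    kept <- matrix(numeric(0), 0, 3)
    for (op in model@symops) {
      x <- (as.numeric(op$R %*% site@xyz) + op$t) %% 1
      dup <- FALSE
      if (nrow(kept)) {
        d <- abs(sweep(kept, 2, x))
        d <- pmin(d, 1 - d)   # periodic distance
        dup <- any(rowSums(d > tol) == 0)
      }
      if (dup) next
      kept <- rbind(kept, x)
      s2 <- site
      s2@xyz <- x
      if (isAnisotropic(site))
        s2@uAniso <- op$R %*% site@uAniso %*% t(op$R)
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

## ---- Debye-Waller ----------------------------------------------------------

#' Debye-Waller attenuation factor of a site
#'
#' Isotropic: \eqn{\exp(-8\pi^2 U_{iso} s^2)}. Anisotropic (CIF U_ij
#' convention): \eqn{\exp(-2\pi^2 \sum_{ij} h_i h_j a^*_i a^*_j U_{ij})}.
#'
#' @param site An [AtomSite-class].
#' @param cell A [UnitCell-class].
#' @param hkl Integer triple or n x 3 matrix.
#' @return Attenuation factor(s) in (0, 1] for positive-semidefinite U.
#' @export
debyeWaller <- function(site, cell, hkl) {
  H <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (isAnisotropic(site)) {
    astar <- reciprocalLengths(cell)
    M <- site@uAniso * outer(astar, astar)
    exp(-2 * pi^2 * rowSums((H %*% M) * H))
  } else {
    s <- stol(cell, H)
    exp(-8 * pi^2 * site@uIso * s^2)
  }
}
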