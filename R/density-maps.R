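## Fourier synthesis of electron-density maps on a fractional grid and the
## gross-residual / fractal-dimension analysis of residual densities.

#' Real-space density grid
#'
#' Density values sampled on an n1 x n2 x n3 grid of fractional coordinates
#' (point (i,j,k) at ((i-1)/n1, (j-1)/n2, (k-1)/n3)), with the cell volume
#' carried for integration. Values are in electrons per cubic angstrom.
#'
#' @slot dims Grid dimensions, each >= 2.
#' @slot values 3-d numeric array of densities.
#' @slot cellVolume Cell volume in cubic angstroms.
#' @export
setClass("DensityGrid",
  representation(dims = "integer", values = "array", cellVolume = "numeric"))

setValidity("DensityGrid", function(object) {
  msgs <- character()
  if (length(object@dims) != 3 || any(object@dims < 2))
    msgs <- c(msgs, "dims must be three values >= 2")
  if (!all(dim(object@values) == object@dims))
    msgs <- c(msgs, "values array does not match dims")
  if (any(!is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (object@cellVolume <= 0) msgs <- c(msgs, "cellVolume must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DensityGrid-class
#' @param values 3-d array.
#' @param cellVolume Cell volume.
#' @return A `DensityGrid`.
#' @export
densityGrid <- function(values, cellVolume) {
  new("DensityGrid", dims = as.integer(dim(values)), values = values,
      cellVolume = cellVolume)
}

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf(
    "DensityGrid %d x %d x %d, V = %.3f A^3, range [%.4g, %.4g] e/A^3\n",
    object@dims[1], object@dims[2], object@dims[3], object@cellVolume,
    min(object@values), max(object@values)))
  invisible(NULL)
})

#' Complete a coefficient set under Friedel symmetry
#'
#' For every (h, F) lacking the mate -h, adds (-h, Conj(F)). Conflicting
#' duplicates (same hkl twice) are an error.
#'
#' @param hkl n x 3 integer matrix.
#' @param F Complex coefficients.
#' @return `list(hkl, F)` closed under Friedel symmetry.
#' @export
friedelComplete <- function(hkl, F) {
  key <- apply(hkl, 1, paste, collapse = ",")
  if (anyDuplicated(key)) stop("duplicate hkl in coefficient set")
  negKey <- apply(-hkl, 1, paste, collapse = ",")
  missing <- !(negKey %in% key)
  ## self-mates (000 and nothing else for integer hkl) are never missing
  list(hkl = rbind(hkl, -hkl[missing, , drop = FALSE]),
       F = c(F, Conj(F[missing])))
}

#' Fourier synthesis of a density map
#'
#' \eqn{\rho(x) = (1/V) \sum_h F(h) e^{-2\pi i\, h \cdot x}} sampled on the
#' grid via a fast Fourier transform. The coefficient set is completed under
#' Friedel symmetry first so the synthesis is real (checked to 1e-10
#' relative). Any index with `2|h_i| >= dims[i]` cannot be represented on
#' the grid and raises an aliasing error.
#'
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param F Complex structure-factor coefficients, one per row of `hkl`.
#' @param cell A [UnitCell-class].
#' @param dims Grid dimensions (length 3).
#' @return A [DensityGrid-class].
#' @examples
#' cell <- unitCell(10, 10, 10)
#' g <- fourierMap(matrix(c(1, 0, 0), 1), complex(real = 500),
#'                 cell, c(8, 8, 8))
#' max(g@values)  # cos(2 pi x) has maximum 1 at x = 0
#' @export
fourierMap <- function(hkl, F, cell, dims) {
  dims <- as.integer(dims)
  cf <- friedelComplete(if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3), F)
  if (any(2L * apply(abs(cf$hkl), 2, max) >= dims))
    stop("grid dims ", paste(dims, collapse = "x"),
         " cannot index the coefficient set without aliasing")
  A <- array(complex(real = 0), dims)
  idx <- sweep(cf$hkl, 2, dims, function(h, n) (h %% n) + 1L)
  A[cbind(idx[, 1], idx[, 2], idx[, 3])] <- cf$F
  rho <- fft(A) / cell@volume     # forward FFT: sum F(h) exp(-2 pi i h.x)
  scale <- max(Mod(rho))
  if (scale > 0 && max(abs(Im(rho))) > 1e-10 * scale)
    stop("synthesis is not real: Friedel completion failed")
  densityGrid(array(Re(rho), dims), cell@volume)
}

#' Model-difference density map
#'
#' Fourier synthesis of \eqn{F_A(h) - F_B(h)} where both complex structure
#' factor sets are computed from the same model (identical positions and
#' ADPs) with two different scattering-factor providers. Using complex
#' differences avoids assigning one model's phases to a modulus difference.
#' F(000) is excluded, so the map is zero-mean.
#'
#' @param model A [CrystalModel-class].
#' @param providerA,providerB Scattering-factor providers
#'   ([slaterProvider()] etc.).
#' @param hkl Reflection set (n x 3 matrix), without 000.
#' @param dims Grid dimensions.
#' @return A [DensityGrid-class] of density differences.
#' @export
differenceMap <- function(model, providerA, providerB, hkl, dims) {
  H <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  FA <- structureFactor(model, H, providerA)
  FB <- structureFactor(model, H, providerB)
  fourierMap(H, FA - FB, model@cell, dims)
}

#' Residual density map
#'
#' Fourier synthesis with coefficients
#' \eqn{(|F_o| - |F_c|)\, e^{i\,\phi_c}} where \eqn{|F_o| =
#' \sqrt{\max(F_o^2, 0)}} and \eqn{\phi_c} is the phase of the calculated
#' structure factor. The set is Friedel-completed before synthesis; any 000
#' record is dropped (its scale is unknown).
#'
#' @param records data.frame with columns `h, k, l, Fo2` and complex `Fc`.
#' @param cell A [UnitCell-class].
#' @param dims Grid dimensions.
#' @return A [DensityGrid-class].
#' @export
residualMap <- function(records, cell, dims) {
  if (is.null(records$Fc)) stop("records must carry calculated Fc")
  H <- as.matrix(records[, c("h", "k", "l")])
  keep <- rowSums(H != 0) > 0
  H <- H[keep, , drop = FALSE]
  Fo <- sqrt(pmax(records$Fo2[keep], 0))
  Fc <- records$Fc[keep]
  coef <- (Fo - Mod(Fc)) * exp(1i * Arg(Fc))
  fourierMap(H, coef, cell, dims)
}

#' Gross residual and fractal-dimension analysis of a density grid
#'
#' Summarizes a residual (or difference) density grid:
#' \itemize{
#' \item `eGross`: \eqn{(V / 2N_{grid}) \sum_i |\rho_i|}, half the gross
#'   absolute density in electrons;
#' \item `dfCurve`: the fractal-dimension curve. Density values are binned
#'   into `nBins` equal-width bins over the value range and
#'   \eqn{d^f(\rho_0) = 3 \ln N(\rho_0) / \ln N_{grid}} is reported for
#'   non-empty bins (a flat, narrow, parabola-like curve indicates a
#'   featureless residual distribution);
#' \item `min`, `max`, `rms` of the grid values.
#' }
#'
#' @param grid A [DensityGrid-class].
#' @param nBins Number of histogram bins for the fractal curve.
#' @return `list(eGross, dfCurve, min, max, rms)`; `dfCurve` is a data.frame
#'   with columns `rho0` (bin centre, e/A^3) and `df` in [0, 3].
#' @export
residualAnalysis <- function(grid, nBins = 101) {
  v <- as.numeric(grid@values)
  n <- length(v)
  eGross <- grid@cellVolume / (2 * n) * sum(abs(v))
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    edges <- seq(lo, hi, length.out = nBins + 1)
    bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nBins)
    counts <- tabulate(bin, nBins)
    centres <- (edges[-1] + edges[-(nBins + 1)]) / 2
  } else {
    counts <- n; centres <- lo
  }
  keep <- counts > 0
  df <- if (n > 1) 3 * log(counts[keep]) / log(n) else rep(3, sum(keep))
  list(eGross = eGross,
       dfCurve = data.frame(rho0 = centres[keep], df = df),
       min = lo, max = hi, rms = sqrt(mean(v^2)))
}

#' Export a residual analysis as CSV
#'
#' Writes the fractal-dimension curve with the scalar summary statistics
#' (`eGross`, `min`, `max`, `rms`) in a comment header.
#'
#' @param analysis Result of [residualAnalysis()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
writeResidualAnalysisCSV <- function(analysis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eGross_e %.8g min_eA3 %.8g max_eA3 %.8g rms_eA3 %.8g",
                     analysis$eGross, analysis$min, analysis$max,
                     analysis$rms), con)
  utils::write.csv(analysis$dfCurve, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a density grid as portable text
#'
#' Header line `DIMS n1 n2 n3 VOLUME v`, then the flattened values (column-
#' major, 6 per line, \%.8g).
#'
#' @param grid A [DensityGrid-class].
#' @param path Optional output file.
#' @return The text (invisibly when written).
#' @export
writeGridText <- function(grid, path = NULL) {
  vals <- sprintf("%.8g", as.numeric(grid@values))
  rows <- tapply(vals, (seq_along(vals) - 1) %/% 6, paste, collapse = " ")
  txt <- paste0(paste(c(sprintf("DIMS %d %d %d VOLUME %.8g", grid@dims[1],
                                grid@dims[2], grid@dims[3], grid@cellVolume),
                        rows), collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' @rdname writeGridText
#' @param text Grid text or path.
#' @return `readGridText`: a [DensityGrid-class].
#' @export
readGridText <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  head <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (head[1] != "DIMS" || head[5] != "VOLUME")
    stop("grid text parse error: bad header")
  dims <- as.integer(head[2:4])
  vol <- as.numeric(head[6])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims)) stop("grid text parse error: value count")
  densityGrid(array(vals, dims), vol)
}
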