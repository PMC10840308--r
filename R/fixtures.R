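## Generators for wavefunctions, Gaussian tables access, toy crystals and
## noisy reflection data, so every module is testable without downloads.

.fixtureSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hydrogen wavefunction fixture
#'
#' A single 1s Slater orbital with occupation 1 and unit coefficient. The
#' default exponent 1.15 inverse bohr is the bonded-hydrogen convention
#' (matching the contracted scattering factor of Stewart, Davidson &
#' Simpson); `zeta = 1.0` gives the exact unbound hydrogen atom.
#'
#' @param zeta Exponent in inverse bohr, > 0.
#' @return A [SlaterWavefunction-class].
#' @examples
#' makeHydrogen()        # bonded convention, zeta = 1.15
#' makeHydrogen(1.0)     # free atom
#' @export
makeHydrogen <- function(zeta = 1.15) {
  if (zeta <= 0) stop("'zeta' must be positive")
  slaterWavefunction("H", 1L, 0L,
    list(atomicOrbital("1s", 1, n = 1L, zeta = zeta, coeff = 1)),
    source = sprintf("hydrogen 1s, zeta = %g", zeta))
}

## ---- Slater-rules minimal-basis atoms --------------------------------------

.slaterZ <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
              F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
              S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20)

#' Approximate atomic wavefunction from Slater's screening rules
#'
#' Builds a synthetic minimal-basis wavefunction for elements H--Ca (and
#' their +/-1 ions): one Slater primitive per subshell, with exponents
#' \eqn{\zeta = (Z - \sigma)/n^*} from Slater's screening constants. This is
#' an approximate single-zeta model, **not** a transcription of tabulated
#' Hartree-Fock wavefunctions; it exists so that multi-electron,
#' multi-shell species (and ions) are available for testing and
#' demonstration without external coefficient tables. Real tables in the
#' package's text format drop in via [readWavefunctionTable()].
#'
#' @param element Element symbol (H through Ca).
#' @param charge Net charge; electrons are removed from / added to the
#'   highest occupied subshell (the added electron must still fit it).
#' @return A [SlaterWavefunction-class].
#' @examples
#' slaterRulesWavefunction("O")        # 1s2 2s2 2p4
#' slaterRulesWavefunction("O", -1L)   # oxide-like anion, 9 electrons
#' @export
slaterRulesWavefunction <- function(element, charge = 0L) {
  Z <- unname(.slaterZ[element])
  if (is.na(Z)) stop("Slater-rules fixture supports H..Ca, not '", element, "'")
  nEl <- Z - as.integer(charge)
  if (nEl < 1) stop("species has no electrons")
  subshells <- data.frame(
    label = c("1s", "2s", "2p", "3s", "3p", "4s"),
    n = c(1, 2, 2, 3, 3, 4),
    l = c(0, 0, 1, 0, 1, 0),
    cap = c(2, 2, 6, 2, 6, 2))
  occ <- numeric(nrow(subshells))
  left <- nEl
  for (i in seq_len(nrow(subshells))) {
    occ[i] <- min(left, subshells$cap[i])
    left <- left - occ[i]
  }
  if (left > 0) stop("cannot place ", nEl, " electrons in shells up to 4s")
  ## Slater groups: (1s)(2s2p)(3s3p)(3d)(4s4p); n* = n for n<=3, 3.7 for n=4
  group <- c(1, 2, 2, 3, 3, 4)[seq_len(nrow(subshells))]
  nStar <- c(1, 2, 3, 3.7)
  orbitals <- list()
  for (i in which(occ > 0)) {
    g <- group[i]
    sameGroup <- sum(occ[group == g]) - 1
    inner1 <- sum(occ[group == g - 1])
    deeper <- sum(occ[group < g - 1])
    sigma <- if (g == 1) 0.30 * sameGroup
             else 0.35 * sameGroup + 0.85 * inner1 + 1.00 * deeper
    zeta <- (Z - sigma) / nStar[g]
    if (zeta <= 0) stop("screening exceeds nuclear charge for ", element)
    orbitals[[length(orbitals) + 1L]] <-
      atomicOrbital(subshells$label[i], occ[i], n = subshells$n[i],
                    zeta = zeta, coeff = 1, lAng = subshells$l[i])
  }
  slaterWavefunction(element, Z, charge, orbitals,
                     source = "synthetic: Slater screening rules, single-zeta")
}

#' Default wavefunction table of the package
#'
#' Hydrogen with the bonded-atom exponent (1.15 inverse bohr by default,
#' switchable to the free-atom 1.0) plus synthetic Slater-rules
#' wavefunctions for He--Ca and their +/-1 ions where the electron
#' configuration permits. Intended as the out-of-the-box species set for
#' the .tsc builder and the command line; transcribed Hartree-Fock tables
#' replace it via [readWavefunctionTable()].
#'
#' @param hydrogenZeta 1.15 (bonded convention, default) or 1.0 (free atom).
#' @return A [WavefunctionTable-class].
#' @export
defaultWavefunctionTable <- function(hydrogenZeta = 1.15) {
  wfs <- list(makeHydrogen(hydrogenZeta))
  for (el in names(.slaterZ)[-1]) {
    wfs[[length(wfs) + 1L]] <- slaterRulesWavefunction(el)
    for (q in c(-1L, 1L)) {
      wf <- tryCatch(slaterRulesWavefunction(el, q), error = function(e) NULL)
      if (!is.null(wf)) wfs[[length(wfs) + 1L]] <- wf
    }
  }
  wavefunctionTable(wfs)
}

#' Random synthetic Slater species
#'
#' Generates a wavefunction of `nOrbitals` s-type contracted orbitals with
#' `primsPerOrbital` primitives each: radial orders drawn from 1..3,
#' exponents uniform in [0.3, 40] inverse bohr, coefficients normalized in
#' closed form through the radial Gram matrix so every contracted orbital
#' has unit norm. Occupations are 2 per orbital, making the species neutral
#' with `2 * nOrbitals` electrons. Deterministic under `seed` (the global
#' RNG state is left untouched).
#'
#' @param nOrbitals,primsPerOrbital Counts, >= 1.
#' @param seed Integer seed.
#' @return A [SlaterWavefunction-class].
#' @export
makeSyntheticSpecies <- function(nOrbitals, primsPerOrbital, seed) {
  stopifnot(nOrbitals >= 1, primsPerOrbital >= 1)
  .fixtureSeed(seed, {
    orbitals <- lapply(seq_len(nOrbitals), function(i) {
      n <- sample(1:3, primsPerOrbital, replace = TRUE)
      zeta <- stats::runif(primsPerOrbital, 0.3, 40)
      coeff <- stats::runif(primsPerOrbital, -1, 1)
      ## unit-normalize the contraction: S_jl = N_j N_l (n_j+n_l)!/(z_j+z_l)^(n_j+n_l+1)
      N <- slaterNorm(n, zeta)
      S <- outer(N, N) * factorial(outer(n, n, `+`)) /
        outer(zeta, zeta, `+`)^(outer(n, n, `+`) + 1)
      coeff <- coeff / sqrt(as.numeric(t(coeff) %*% S %*% coeff))
      atomicOrbital(paste0(i, "s"), 2, n = n, zeta = zeta, coeff = coeff,
                    lAng = 0L)
    })
    slaterWavefunction("Zz", 2L * nOrbitals, 0L, orbitals,
                       source = sprintf("synthetic species, seed %d", seed))
  })
}

## ---- toy crystals ----------------------------------------------------------

.p21cSymops <- function() {
  lapply(c("x, y, z", "-x, y+1/2, -z+1/2", "-x, -y, -z", "x, -y+1/2, z+1/2"),
         parseSymop)
}

#' Toy crystal with synthetic noisy reflection data
#'
#' Builds a small P1 or P2_1/c crystal (1--5 sites drawn from `species`,
#' positions and isotropic U values seeded), computes kinematic structure
#' factors with the supplied wavefunction table, and simulates observed
#' intensities \eqn{F_o^2 = |F_c|^2 (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, noiseFraction)} and
#' \eqn{\sigma(F_o^2) = \max(noiseFraction, 10^{-3}) |F_c|^2} (the floor
#' keeps uncertainties positive in the noise-free case). Byte-identical
#' output under a fixed seed.
#'
#' @param seed Integer seed.
#' @param noiseFraction Relative noise level for Fo^2 (>= 0).
#' @param species Character vector of element symbols, length 1--5.
#' @param spaceGroup `"P1"` or `"P21/c"`.
#' @param cell A [UnitCell-class]; default 6 x 7 x 8 orthorhombic.
#' @param dMin Resolution limit for the simulated data (angstroms).
#' @param table Wavefunction table used to calculate Fc;
#'   default [defaultWavefunctionTable()].
#' @param radiation `"xray"` or `"electron"`.
#' @return List with `model` ([CrystalModel-class]), `cif` (text), `hklText`
#'   (HKLF4 text), `records` (data.frame h,k,l,Fo2,sigFo2,Fc at full
#'   precision) and `hkl` (the index matrix).
#' @export
makeToyCrystal <- function(seed = 1L, noiseFraction = 0.02,
                           species = c("O", "C"), spaceGroup = c("P1", "P21/c"),
                           cell = unitCell(6, 7, 8), dMin = 0.8,
                           table = defaultWavefunctionTable(),
                           radiation = c("xray", "electron")) {
  spaceGroup <- match.arg(spaceGroup)
  radiation <- match.arg(radiation)
  stopifnot(length(species) >= 1, length(species) <= 5, noiseFraction >= 0)
  .fixtureSeed(seed, {
    sites <- lapply(seq_along(species), function(i) {
      atomSite(paste0(species[i], i), species[i], stats::runif(3, 0.05, 0.95),
               occupancy = 1, uIso = stats::runif(1, 0.01, 0.03))
    })
    symops <- if (spaceGroup == "P1") list(list(R = diag(3), t = c(0, 0, 0)))
              else .p21cSymops()
    model <- crystalModel(cell, sites, symops)
    H <- hklSphere(cell, dMin)
    Fc <- structureFactor(model, H, slaterProvider(table, radiation))
    Fc2 <- Mod(Fc)^2
    ## merged data: Friedel mates share one noise draw, as after averaging
    key <- apply(H, 1, paste, collapse = ",")
    negKey <- apply(-H, 1, paste, collapse = ",")
    canon <- pmin(key, negKey)
    eps <- stats::rnorm(length(Fc2), 0, noiseFraction)
    eps <- eps[match(canon, key)]
    eps[is.na(eps)] <- 0
    Fo2 <- Fc2 * (1 + eps)
    sig <- pmax(noiseFraction, 1e-3) * pmax(Fc2, 1e-6)
    records <- reflectionRecords(H, Fo2, sig, Fc)
    list(model = model, cif = writeCifMinimal(model),
         hklText = writeShelxHkl(records), records = records, hkl = H)
  })
}

## ---- bundled Gaussian tables -----------------------------------------------

#' Bundled Gaussian coefficient tables
#'
#' `xray4GcTable()` loads the four-Gaussian-plus-constant X-ray coefficients
#' bundled for H, C, N, O and Ca (the conventional independent-atom-model
#' parameterization). `pengEdTable()` loads the bundled Peng-style electron
#' Gaussian coefficients (five terms, no constant) for H, C and O. Both are
#' plain CSV under `inst/extdata` with provenance noted in the file headers.
#'
#' @return Named list of [GaussianFFModel-class].
#' @export
xray4GcTable <- function() {
  readGaussianTable(system.file("extdata", "xray_4gc.csv",
                                package = "SlaterSF", mustWork = TRUE))
}

#' @rdname xray4GcTable
#' @export
pengEdTable <- function() {
  readGaussianTable(system.file("extdata", "peng_ed_5g.csv",
                                package = "SlaterSF", mustWork = TRUE))
}

#' Write the synthetic fixture bundle
#'
#' Emits the file bundle used throughout the examples and tests into a
#' directory: a wavefunction table (hydrogen plus Slater-rules atoms), a toy
#' CIF, its simulated HKLF4 reflection file and copies of the bundled
#' Gaussian coefficient tables.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the toy crystal.
#' @return Character vector of the files written, invisibly.
#' @export
writeFixtureBundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- makeToyCrystal(seed = seed)
  paths <- c(file.path(dir, "wavefunctions_synthetic.wft"),
             file.path(dir, "toy.cif"),
             file.path(dir, "toy.hkl"),
             file.path(dir, "xray_4gc.csv"),
             file.path(dir, "peng_ed_5g.csv"))
  writeLines(writeWavefunctionTable(defaultWavefunctionTable()), paths[1], sep = "")
  writeLines(toy$cif, paths[2], sep = "")
  writeLines(toy$hklText, paths[3], sep = "")
  file.copy(system.file("extdata", "xray_4gc.csv", package = "SlaterSF"),
            paths[4], overwrite = TRUE)
  file.copy(system.file("extdata", "peng_ed_5g.csv", package = "SlaterSF"),
            paths[5], overwrite = TRUE)
  invisible(paths)
}
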