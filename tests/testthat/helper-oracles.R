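## Independent numerical oracles used across the suite. These deliberately
## avoid the analytic code paths they check: plain adaptive quadrature and
## direct Fourier summation.

## int_0^inf r^m exp(-a r) kernel(b r) dr by piecewise Gauss-Kronrod between
## kernel zeros, with the integrand scaled to its envelope peak so that all
## piece values are O(1) in double precision.
trigIntegralOracle <- function(m, a, b, kernel = sin) {
  peakLog <- if (m > 0) m * log(m / a) - m else 0
  f <- function(r) exp(m * log(pmax(r, 1e-300)) - a * r - peakLog) * kernel(b * r)
  rmax <- (m + 60) / a
  cuts <- sort(unique(c(seq(0, rmax, by = if (b > 0) pi / (2 * b) else rmax), rmax)))
  tot <- sum(vapply(seq_len(length(cuts) - 1), function(i)
    pracma::quadgk(f, cuts[i], cuts[i + 1], tol = 1e-15), numeric(1)))
  tot * exp(peakLog)
}

## magnitude scale of the trig integrals, |m! (a - ib)^-(m+1)|
trigIntegralScale <- function(m, a, b) factorial(m) * (a^2 + b^2)^(-(m + 1) / 2)

## X-ray form factor by adaptive quadrature of int 4 pi r^2 rho(r) sinc(kr) dr,
## r in bohr, s in 1/Angstrom.
xrayFFOracle <- function(wf, s) {
  vapply(s, function(si) {
    k <- 4 * pi * si * bohrToAngstrom()
    f <- function(r) {
      sinc <- ifelse(k * r < 1e-8, 1, sin(k * r) / (k * r))
      4 * pi * r^2 * radialDensity(wf, r) * sinc
    }
    ## split at a few scales to help the adaptive rule near the nucleus
    cuts <- c(0, 0.1, 1, 5, 20, 60)
    sum(vapply(seq_len(length(cuts) - 1), function(i)
      stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-11,
                       abs.tol = 1e-12, subdivisions = 400L)$value,
      numeric(1)))
  }, numeric(1))
}

## electron count by quadrature of 4 pi r^2 rho
electronCountOracle <- function(wf, rmax = 60) {
  stats::integrate(function(r) 4 * pi * r^2 * radialDensity(wf, r), 0, rmax,
                   rel.tol = 1e-12, subdivisions = 400L)$value
}

## <r^2> by quadrature
meanSquareRadiusOracle <- function(wf, rmax = 80) {
  stats::integrate(function(r) 4 * pi * r^4 * radialDensity(wf, r), 0, rmax,
                   rel.tol = 1e-12, subdivisions = 400L)$value / electronCount(wf)
}

## direct (non-FFT) Fourier synthesis at fractional points x (n x 3)
directSynthesis <- function(hkl, F, volume, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  vapply(seq_len(nrow(X)), function(i)
    Re(sum(F * exp(-2i * pi * as.numeric(hkl %*% X[i, ])))) / volume,
    numeric(1))
}

## small species set exercised by form-factor oracle tests
oracleSpecies <- function() {
  list(H115 = makeHydrogen(1.15),
       H100 = makeHydrogen(1.0),
       C = slaterRulesWavefunction("C"),
       O = slaterRulesWavefunction("O"),
       Om = slaterRulesWavefunction("O", -1L),
       Ca = slaterRulesWavefunction("Ca"),
       Zz = makeSyntheticSpecies(3, 3, 11))
}

## P2_1/c symmetry operation set used by crystal tests
.p21cSymopsForTest <- function() {
  lapply(c("x, y, z", "-x, y+1/2, -z+1/2", "-x, -y, -z", "x, -y+1/2, z+1/2"),
         parseSymop)
}
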