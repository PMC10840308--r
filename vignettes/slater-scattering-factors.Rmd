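---
title: "Analytic Slater-orbital scattering factors: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic Slater-orbital scattering factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
atomic model, the analytic Fourier transform, the Mott–Bethe transformation,
the kinematic structure-factor and map machinery, and — importantly — the
conventions and numerical choices that a user comparing against other
software needs to know. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The atomic model and its Fourier transform

A species is a set of occupied shells; each shell is a contracted
Slater-type orbital $R_i(r) = \sum_j N_j c_j r^{n_j-1} e^{-\zeta_j r}$ with
the closed-form normalization $N = (2\zeta)^{n+1/2}/\sqrt{(2n)!}$. The
spherically averaged density is

$$\rho(r) = \frac{1}{4\pi}\sum_i o_i\,R_i(r)^2 ,$$

with $o_i$ the shell occupation. STOs carry the correct nuclear cusp and
exponential long-range tail; both are lost by any finite Gaussian
expansion, and the difference concentrates at high (cusp) and low (tail)
scattering vectors respectively — the regions where the conventional 4G+c
parameterization is weakest.

**Where the $1/4\pi$ lives.** The product of the spherical-averaging
prefactor in $\rho$ and the volume element of the transform is fixed by the
requirement $f^X(0) = N_e$ (electron count). We place $1/4\pi$ in
`radialDensity()` so the transform is the plain radial integral
$f^X = \int 4\pi r^2 \rho(r)\,\mathrm{sinc}(kr)\,dr$. Only the product is
observable; this split makes every intermediate quantity independently
checkable by quadrature, and the $f^X(0)=N_e$ identity is asserted to
1e−12 in the tests.

**Units.** Wavefunctions (radii, exponents) are in bohr, as STO tables are
conventionally printed; everything the user sees at the scattering-vector
boundary is $s = \sin\theta/\lambda$ in Å⁻¹. The single conversion
$k = 4\pi s \times a_0$, with $a_0 = 0.529177210903$ Å, happens inside
`xrayFormFactor()`. Mixing these units is the classic error mode of STO
form-factor code, which is why the conversion exists in exactly one place.

**Evaluation.** Squaring a contraction expands into cross terms
$w\,r^{m-2}e^{-Zr}$ (`crossTerms()`, cached per species; the cache is
tested identical to naive re-expansion). Each term contributes
$(w/k)\,I_{\sin}(m{-}1; Z, k)$ with
$I_{\sin}(m;a,b) = \int_0^\infty r^m e^{-ar}\sin(br)\,dr$. Two independent
evaluations are exported and tested equal to 1e−12: the closed form
$m!\,\mathrm{Im}[(a-ib)^{-(m+1)}]$ (the production path) and the
partial-integration recursion seeded by $I_{\sin}(0)=b/(a^2+b^2)$,
$I_{\cos}(0)=a/(a^2+b^2)$. Because the closed form could be transcribed
wrongly in either source or code, the implementation is additionally pinned
by an adaptive-quadrature oracle of the full radial integral
(1e−8 absolute over $s \in [0,4]$ Å⁻¹ for every bundled and synthetic
species) rather than by trusting any printed equation.

**The $k \to 0$ guard.** Below $k = 10^{-8}$ bohr⁻¹ the sinc kernel
underflows; the code switches to the analytic limit
$\sum w\, m!/Z^{m+1}$. Continuity across the guard is tested to 1e−9.

## Electron diffraction: Mott–Bethe and its limits

$$f^e(s) = \frac{C\,(Z - f^X(s))}{s^2}, \qquad
  C = \frac{m_0 e^2}{8\pi\varepsilon_0 h^2}\ \text{in Å}^{-1}.$$

The prefactor arrangement ($8\pi$ with $h$, versus $8\pi^2$ with $\hbar$)
is a known source of unit bugs, so `mottBetheConstant()` computes $C$ from
CODATA constants *and* from the identity $C = 1/(8\pi^2 a_0)$ and refuses
to return unless the two agree to 1e−9 relative ($C \approx 0.023934$
Å⁻¹).

Two numerical/physical subtleties:

* **Neutral atoms at small angle.** $Z - f^X$ vanishes as $s^2$, so
  evaluating the quotient directly at $s = 10^{-6}$ loses about six
  significant digits to cancellation. Below $s = 5\times10^{-3}$ Å⁻¹ the
  code evaluates $Z - f^X$ by its radial-moment series
  $q + \sum_{j\ge1} (-1)^{j+1} k^{2j} M_{2j}/(2j{+}1)!$ (with
  $M_{2j} = \int 4\pi r^{2j+2}\rho\,dr$ in closed form), which is the same
  quantity without the cancellation. At exactly $s=0$ the analytic limit
  $f^e(0) = N_e \langle r^2\rangle_{\text{Å}} / (3 a_0)$ is used. Note the
  electron-count factor $N_e$: the limit follows from
  $f^X \approx N_e(1 - k^2\langle r^2\rangle/6)$ with the per-electron
  mean-square radius, and the $s\to0$ continuity test passes only with it.
  For hydrogen this gives $a_0$ ($\zeta=1$) and $a_0/1.3225 \approx
  0.40013$ Å ($\zeta=1.15$).
* **Ions.** A net charge $q$ leaves a Coulomb monopole:
  $f^e \to C q/s^2$. The package treats $s=0$ for an ion as an error
  naming the charge, not as infinity; the `.tsc` builder never requests
  $s=0$ (the 000 reflection is excluded from the resolution sphere), so
  ionic tables are safe in electron mode. An effective-nuclear-charge
  shortcut for ionic electron factors is deliberately not implemented; only
  actual ionic wavefunctions (or neutral fallback) are used.

## Crystal machinery

* **Symmetry.** Models carry explicit symmetry-operation strings
  (`"-x, y+1/2, -z+1/2"`); structure factors are computed by expanding all
  sites to P1 first, de-duplicating positions within 1e−4 fractional
  (periodic distance), so special positions are never double-counted and
  deposited occupancies are trusted verbatim — if a file encodes
  multiplicity in the occupancy, that convention passes through unchanged.
  Anisotropic $U$ matrices transform as $R\,U\,R^{T}$ under the integer
  rotation parts. Non-positive-semidefinite deposited $U$ warns rather than
  fails.
* **ADPs.** CIF $U_{ij}$ convention, Å²; isotropic
  $\exp(-8\pi^2 U s^2)$, anisotropic
  $\exp(-2\pi^2 \sum h_i h_j a^*_i a^*_j U_{ij})$. No $B$-factors anywhere.
* **Weighting and residuals.** The SHELX-type scheme
  $w = 1/[\sigma^2(F_o^2) + (aP)^2 + bP]$, $P = (\max(F_o^2,0)+2F_c^2)/3$;
  $R_1$ uses the conventional $I > 2\sigma$ cutoff; negative intensities
  are preserved on input and clamped only inside $P$.
* **Dispersion.** $f'$/$f''$ are not modelled at all; spherical STO factors
  are strictly real, which is also why every `.tsc` imaginary part is
  exactly zero (asserted in tests).

## Maps and residual analysis

Synthesis convention: $\rho(x) = (1/V)\sum_h F(h)\,e^{-2\pi i\,h\cdot x}$,
validated by the constant-map and cosine closed forms, by direct summation
at random points (1e−8), and by a Parseval identity (1e−6 relative for
band-limited sets). Coefficient sets are completed under Friedel symmetry
($F(-h) = \overline{F(h)}$) before synthesis and the result is required to
be real to 1e−10 — supplying inconsistent mates is an error, not a silent
averaging. A grid too coarse to index some $h$ raises an aliasing error
rather than wrapping silently.

Model-difference maps use complex differences
$F_A(h) - F_B(h)$ on identical positions and ADPs, which avoids assigning
one model's phases to a modulus difference; residual maps use
$(|F_o| - |F_c|)\,e^{i\phi_c}$. $F(000)$ is excluded from both (its scale
is unobservable), making the maps zero-mean.

The residual summary follows the gross-residual/fractal-dimension idea:
$e_{\text{gross}} = (V/2N)\sum_i |\rho_i|$ (electrons) and
$d^f(\rho_0) = 3\ln N(\rho_0)/\ln N_{\text{total}}$ over a 101-bin
(configurable) equal-width histogram, only non-empty bins reported. The
precise binning/normalization of published fractal plots varies between
implementations; this one is recorded here rather than asserted against
any external curve.

**Grid sizes.** Test and acceptance maps use grids of roughly 18–24 points
per axis for identity checks (direct summation, Parseval, peak recovery),
and 48×56×64 vs 96×112×128 for the extrema-convergence check: map extrema
sit between grid points, and only once the grid resolves the point spread
around the heaviest atom does doubling change extrema by less than 0.5%
(measured 0.26% max / 0.01% min on the calcium toy crystal). Coarser grids
can change extrema by a few percent on doubling — worth remembering when
comparing peak heights between programs that default to different grids.

## The `.tsc` interchange and the command line

The dialect is header lines `TITLE:`, `SYMM: expanded`, `SCATTERERS:`
(space-separated atom labels), `DATA:`, then `h k l re,im re,im …` with one
complex pair per scatterer, printed to 8 significant digits; the reader
skips unknown header keys (the official field set is larger) and
round-trips bit-for-bit on the formatted values. Factors are evaluated at
each reflection's exact $s$ from the cell metric — never interpolated from
a grid. Merging requires identical reflection sets (the error lists the
symmetric difference) and resolves duplicate labels later-wins with a
warning.

`tscCli()` (wrapped by `inst/scripts/slater_tsc.R`) mirrors the established
flag set `-cif <file> -xyz <file> -IAM -dmin <float>` plus `-ED`,
`-Cations A B C`, `-Anions A B C`, with `-wft <file>` to supply a
transcribed wavefunction table and `-merge` for combining `.tsc` files;
exit codes 0/2/3 for ok / parse error / species error, log on stderr.

## The synthetic data, and what passing tests do not show

Bundled species are deliberately synthetic:

* hydrogen is exact (single 1s STO; $\zeta = 1.15$ bohr⁻¹ bonded-atom
  default, $\zeta = 1.0$ free atom);
* H–Ca and their ±1 ions come from Slater's screening rules — one primitive
  per subshell, $\zeta = (Z-\sigma)/n^*$. These have correct electron
  counts, cusps, tails and shell structure, but are *not* Hartree–Fock
  quality: absolute form-factor values for multi-electron atoms differ from
  tabulated high-quality STO wavefunctions at the few-percent level;
* `makeSyntheticSpecies()` draws random multi-primitive contractions
  (ζ ∈ [0.3, 40] bohr⁻¹, radial orders 1–3), Gram-matrix-normalized so
  every invariant that should hold for *any* valid wavefunction is
  exercised away from physical special cases.

The toy-crystal generator emulates merged kinematic data:
$F_o^2 = |F_c|^2(1+\varepsilon)$, $\varepsilon \sim N(0,
\text{noiseFraction})$ shared between Friedel mates,
$\sigma(F_o^2) = \max(\text{noiseFraction}, 10^{-3})\,|F_c|^2$ (the floor
keeps weights finite in the noise-free case). Default 6×7×8 Å cell, P1 or
P2₁/c, 1–5 sites, byte-identical under a fixed seed with the global RNG
stream restored afterwards.

What this does **not** emulate: dynamical (multi-beam) electron
diffraction, absorption and extinction, detector artefacts,
resolution-dependent error models, or disorder. Passing tests therefore
demonstrate the correctness of the analytic transforms, conventions and
formats — not that refinement of real (especially dynamical ED) data will
reach any particular residual.

A difference-Fourier caveat encoded in the fixtures: recovering a deleted
atom requires the remaining model to dominate the phases. Deleting an atom
carrying more than half the scattering power puts the peak on the remaining
atoms (phase bias); the deletion fixtures therefore anchor the phases with
a Ca atom and delete the oxygen.

## Parameters at a glance

| Parameter | Where | Default | Why |
|---|---|---|---|
| hydrogen ζ | `makeHydrogen()` | 1.15 bohr⁻¹ | bonded-atom convention; 1.0 = free atom |
| $k\to0$ guard | `xrayFormFactor()` | 1e−8 bohr⁻¹ | sinc underflow; continuity tested |
| small-$s$ series switch | `edFormFactor()` | $s < 5\times10^{-3}$ Å⁻¹ | cancellation in $Z - f^X$ |
| position de-duplication | `expandToP1()` | 1e−4 fractional | special positions vs distinct atoms |
| `.tsc` value precision | `writeTsc()` | 8 significant digits | round-trip stability |
| fractal bins | `residualAnalysis()` | 101 | odd count centres a zero bin; configurable |
| $R_1$ cutoff | `weightsAndRstats()` | $I > 2\sigma$ | reporting convention |
| toy σ floor | `makeToyCrystal()` | 1e−3 relative | finite weights at zero noise |

## Known limitations

* No least-squares refinement engine: positions/ADPs are inputs, residual
  statistics are evaluations, not minimized quantities.
* Bundled wavefunctions are minimal-basis approximations (see above);
  quantitative comparison with published heavy-element curves requires
  importing transcribed STO tables via `readWavefunctionTable()`.
* Spherical atoms only — no multipoles, no Hirshfeld-atom partitioning, no
  anomalous dispersion, no relativistic corrections.
* The CIF reader covers the cell/symmetry/site/aniso subset only, by
  design; it is not a general CIF parser.
* Kinematic intensities only; dynamical diffraction is out of scope.
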