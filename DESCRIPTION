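Package: SlaterSF
Title: Analytical Atomic Scattering Factors from Slater-Type Orbital Wavefunctions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes atomic scattering factors for X-ray and electron
    diffraction analytically from contracted Slater-type orbital atomic
    wavefunctions, with no Gaussian fitting and no interpolation from
    precalculated tables. The Fourier transform of the spherical atomic
    electron density is evaluated in closed form through a recursion of
    sine and cosine integrals; electron-diffraction factors follow by the
    Mott-Bethe transformation with correct small-angle limits for neutral
    atoms and a documented divergence for ions. The package also provides
    conventional four-Gaussian-plus-constant reference models, a minimal
    CIF and SHELX HKLF4 reader, kinematic structure factors with
    Debye-Waller attenuation and SHELX-type weighting statistics, the
    .tsc per-reflection scattering-factor interchange format (writer,
    reader, merger) with a command-line front end, Fourier synthesis of
    difference and residual electron-density maps, and the gross-residual
    and fractal-dimension analysis of residual densities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
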