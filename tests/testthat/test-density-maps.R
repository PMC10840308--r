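cell10 <- unitCell(10, 10, 10)

## random Friedel-half coefficient set on indices up to hmax
randomCoefficients <- function(hmax, seed) {
  set.seed(seed)
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax))
  half <- H[H[, 1] > 0 | (H[, 1] == 0 & H[, 2] > 0) |
              (H[, 1] == 0 & H[, 2] == 0 & H[, 3] > 0), ]
  list(hkl = half,
       F = complex(real = rnorm(nrow(half)), imaginary = rnorm(nrow(half))))
}

test_that("Fourier synthesis reproduces closed-form maps", {
  ## F(000) = V*c alone gives a constant map c
  g <- fourierMap(matrix(c(0, 0, 0), 1), complex(real = 1000 * 0.37),
                  cell10, c(4, 4, 4))
  expect_equal(as.numeric(g@values), rep(0.37, 64), tolerance = 1e-12)
  ## single Friedel pair at V/2 gives cos(2 pi x)
  g2 <- fourierMap(matrix(c(1, 0, 0), 1), complex(real = 500), cell10,
                   c(8, 6, 5))
  x <- (0:7) / 8
  expect_equal(g2@values[, 1, 1], cos(2 * pi * x), tolerance = 1e-12)
  expect_equal(max(g2@values), 1, tolerance = 1e-12)
  ## the mean is the DC term / V
  cf <- randomCoefficients(2, 1)
  hkl <- rbind(c(0, 0, 0), cf$hkl)
  F <- c(complex(real = 123), cf$F)
  g3 <- fourierMap(hkl, F, cell10, c(10, 10, 10))
  expect_equal(mean(g3@values), 123 / 1000, tolerance = 1e-12)
})

test_that("FFT synthesis agrees with direct summation and Parseval", {
  cf <- randomCoefficients(3, 7)
  dims <- c(9, 8, 10)
  g <- fourierMap(cf$hkl, cf$F, cell10, dims)
  full <- friedelComplete(cf$hkl, cf$F)
  ## 10 random grid points
  set.seed(3)
  idx <- cbind(sample(dims[1], 10, TRUE), sample(dims[2], 10, TRUE),
               sample(dims[3], 10, TRUE))
  x <- sweep(idx - 1, 2, dims, `/`)
  expect_equal(g@values[idx], directSynthesis(full$hkl, full$F, 1000, x),
               tolerance = 1e-8)
  ## Parseval for a band-limited set fully resolved by the grid
  lhs <- sum(g@values^2) * (1000 / prod(dims))
  rhs <- sum(Mod(full$F)^2) / 1000
  expect_equal(lhs, rhs, tolerance = 1e-6)
  ## aliasing guard
  expect_error(fourierMap(cf$hkl, cf$F, cell10, c(6, 6, 6)), "aliasing")
})

test_that("map extrema converge as the grid is refined", {
  ## atom-like band-limited map: once the grid is fine enough to resolve the
  ## point spread around the heavy atom, doubling changes extrema by < 0.5%
  toy <- makeToyCrystal(seed = 4, species = c("Ca", "O"), dMin = 1.0)
  provA <- slaterProvider(defaultWavefunctionTable())
  provB <- gaussianProvider(xray4GcTable())
  g1 <- differenceMap(toy$model, provA, provB, toy$hkl, c(48, 56, 64))
  g2 <- differenceMap(toy$model, provA, provB, toy$hkl, c(96, 112, 128))
  expect_lt(abs(max(g2@values) - max(g1@values)) / abs(max(g2@values)), 0.005)
  expect_lt(abs(min(g2@values) - min(g1@values)) / abs(min(g2@values)), 0.005)
})

test_that("model-difference maps vanish for identical providers and antisymmetrize", {
  toy <- makeToyCrystal(seed = 4, species = c("O", "C"))
  provA <- slaterProvider(defaultWavefunctionTable())
  provB <- gaussianProvider(xray4GcTable())
  H <- toy$hkl
  dims <- c(16, 18, 22)
  z <- differenceMap(toy$model, provA, provA, H, dims)
  expect_equal(max(abs(z@values)), 0, tolerance = 1e-12)
  ab <- differenceMap(toy$model, provA, provB, H, dims)
  ba <- differenceMap(toy$model, provB, provA, H, dims)
  expect_equal(ab@values, -ba@values, tolerance = 1e-12)
  expect_gt(max(abs(ab@values)), 0)
  ## zero mean: F(000) excluded
  expect_equal(mean(ab@values), 0, tolerance = 1e-12)
})

test_that("difference map of constant-f providers matches the direct point-spread sum", {
  ## one atom, providers f = Z and f = Z - 1: coefficients DW * exp(2 pi i h.x)
  cell <- unitCell(8, 9, 10)
  site <- atomSite("C1", "C", c(0.3, 0.6, 0.1), uIso = 0.02)
  model <- crystalModel(cell, list(site))
  H <- hklSphere(cell, 1.1)
  pa <- constantProvider(c(C = 6))
  pb <- constantProvider(c(C = 5))
  dims <- c(16, 18, 20)
  g <- differenceMap(model, pa, pb, H, dims)
  dw <- debyeWaller(site, cell, H)
  F <- dw * exp(2i * pi * as.numeric(H %*% site@xyz))
  set.seed(9)
  idx <- cbind(sample(dims[1], 10, TRUE), sample(dims[2], 10, TRUE),
               sample(dims[3], 10, TRUE))
  pts <- sweep(idx - 1, 2, dims, `/`)
  expect_equal(g@values[idx], directSynthesis(H, F, cell@volume, pts),
               tolerance = 1e-8)
  ## the point spread is centred on the atom
  peak <- which(g@values == max(g@values), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric((peak - 1) / dims), site@xyz, tolerance = 0.06)
})

test_that("residual maps are zero for perfect data, scale linearly, and recover a deleted atom", {
  toy <- makeToyCrystal(seed = 6, species = c("Ca", "C", "O"), noiseFraction = 0)
  rec <- toy$records
  dims <- c(18, 20, 24)
  z <- residualMap(rec, toy$model@cell, dims)
  expect_equal(max(abs(z@values)), 0, tolerance = 1e-10)

  ## doubling |Fo| - |Fc| doubles the map (noisy observations)
  noisy <- makeToyCrystal(seed = 6, species = c("Ca", "C", "O"),
                          noiseFraction = 0.05)
  delta <- sqrt(pmax(noisy$records$Fo2, 0)) - Mod(noisy$records$Fc)
  r1 <- noisy$records
  r2 <- noisy$records
  r2$Fo2 <- (Mod(r2$Fc) + 2 * delta)^2
  g1 <- residualMap(r1, noisy$model@cell, dims)
  g2 <- residualMap(r2, noisy$model@cell, dims)
  expect_equal(g2@values, 2 * g1@values, tolerance = 1e-8)

  ## delete one atom from the refinement model: Fo from the full structure,
  ## Fc from the depleted one -> positive peak at the deleted site (the Ca
  ## anchor keeps the partial-model phases close to the true ones)
  prov <- slaterProvider(defaultWavefunctionTable())
  depleted <- toy$model
  deleted <- depleted@sites[[3]]            # the oxygen
  depleted@sites <- depleted@sites[-3]
  FcDep <- structureFactor(depleted, toy$hkl, prov)
  recDel <- reflectionRecords(toy$hkl, toy$records$Fo2, toy$records$sigFo2, FcDep)
  gDel <- residualMap(recDel, toy$model@cell, dims)
  peakIdx <- which(gDel@values == max(gDel@values), arr.ind = TRUE)[1, ]
  frac <- (peakIdx - 1) / dims
  d <- abs(frac - deleted@xyz); d <- pmin(d, 1 - d)
  expect_lt(sqrt(sum((d * c(6, 7, 8))^2)), 0.5)   # within 0.5 A of the site
  expect_gt(max(gDel@values), abs(min(gDel@values)))  # positive peak dominates
})

test_that("residual analysis: gross electrons and fractal curve behave by definition", {
  z <- densityGrid(array(0, c(4, 4, 4)), 1000)
  ra0 <- residualAnalysis(z)
  expect_equal(ra0$eGross, 0)
  expect_equal(ra0$rms, 0)

  cgrid <- densityGrid(array(-0.2, c(5, 5, 5)), 730)
  rac <- residualAnalysis(cgrid)
  expect_equal(rac$eGross, 730 * 0.2 / 2)
  expect_equal(rac$min, -0.2); expect_equal(rac$max, -0.2)

  ## near-constant map: the modal bin's fractal dimension approaches 3
  set.seed(2)
  vals <- array(1 + rnorm(8000, 0, 1e-6), c(20, 20, 20))
  vals[1, 1, 1] <- 1.5   # one outlier so the histogram has width
  ran <- residualAnalysis(densityGrid(vals, 500), nBins = 11)
  expect_gt(max(ran$dfCurve$df), 2.99)
  expect_true(all(ran$dfCurve$df >= 0 & ran$dfCurve$df <= 3))
})

test_that("residual analysis exports its curve and summary as CSV", {
  set.seed(14)
  g <- densityGrid(array(rnorm(125, 0, 0.1), c(5, 5, 5)), 300)
  ra <- residualAnalysis(g, nBins = 7)
  f <- tempfile(fileext = ".csv")
  writeResidualAnalysisCSV(ra, f)
  lines <- readLines(f)
  expect_match(lines[1], "eGross_e")
  back <- utils::read.csv(f, comment.char = "#")
  expect_equal(back$df, ra$dfCurve$df, tolerance = 1e-7)
})

test_that("grid text export round-trips", {
  cf <- randomCoefficients(2, 5)
  g <- fourierMap(cf$hkl, cf$F, cell10, c(6, 7, 8))
  txt <- writeGridText(g)
  back <- readGridText(txt)
  expect_identical(back@dims, g@dims)
  expect_equal(back@values, g@values, tolerance = 1e-7)
  expect_equal(back@cellVolume, g@cellVolume)
})
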