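cubic10 <- unitCell(10, 10, 10)

test_that("stol follows the reciprocal metric", {
  expect_equal(stol(cubic10, c(2, 0, 0)), 0.1)
  expect_equal(stol(cubic10, c(0, 0, 0)), 0)
  expect_equal(stol(cubic10, c(0, 2, 0)), stol(cubic10, c(0, 0, 2)))
  ## triclinic cross-check against the explicit 1/d^2 formula
  tric <- unitCell(5.2, 6.3, 7.1, 91, 103, 119)
  h <- c(1, -2, 3)
  d2inv <- as.numeric(t(h) %*% tric@reciprocalMetric %*% h)
  expect_equal(stol(tric, h), sqrt(d2inv) / 2)
})

test_that("hklSphere matches brute-force enumeration and keeps Friedel mates", {
  H <- hklSphere(cubic10, 5)
  ## cubic a=10, d >= 5  <=>  h^2+k^2+l^2 <= 4, excluding 000
  brute <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -3:3))
  brute <- brute[rowSums(brute^2) <= 4 & rowSums(brute^2) > 0, ]
  expect_identical(nrow(H), nrow(brute))
  expect_setequal(apply(H, 1, paste, collapse = ","),
                  apply(brute, 1, paste, collapse = ","))
  expect_identical(nrow(H) %% 2L, 0L)     # Friedel pairing
  key <- apply(H, 1, paste, collapse = ",")
  expect_true(all(apply(-H, 1, paste, collapse = ",") %in% key))
  expect_equal(attr(H, "s"), stol(cubic10, H), ignore_attr = TRUE)
  expect_identical(nrow(hklSphere(cubic10, 11)), 0L)
  expect_error(hklSphere(cubic10, -1), "positive")
})

test_that("Debye-Waller factors: isotropic values and cubic aniso equivalence", {
  site <- atomSite("X1", "C", c(0, 0, 0), uIso = 0)
  expect_equal(debyeWaller(site, cubic10, c(3, 1, 2)), 1.0)
  site2 <- atomSite("X2", "C", c(0, 0, 0), uIso = 0.015)
  h <- c(5, 0, 0)   # s = 0.25? no: 5/(2*10) = 0.25 -> use s = 0.5 via (10,0,0)
  expect_equal(debyeWaller(site2, cubic10, c(10, 0, 0)),
               exp(-8 * pi^2 * 0.015 * 0.25), tolerance = 1e-12)
  ## isotropic U matrix in a cubic cell equals the U_iso formula
  site3 <- atomSite("X3", "C", c(0, 0, 0), uAniso = diag(3) * 0.015)
  H <- matrix(c(1, 2, 3, -2, 0, 5, 3, 3, 3), ncol = 3, byrow = TRUE)
  expect_equal(debyeWaller(site3, cubic10, H), debyeWaller(site2, cubic10, H),
               tolerance = 1e-12)
  expect_true(all(debyeWaller(site3, cubic10, H) <= 1))
  expect_warning(atomSite("X4", "C", c(0, 0, 0),
                          uAniso = diag(c(-0.02, 0.01, 0.01))),
                 "positive-semidefinite")
})

test_that("structure factors obey the basic phase laws", {
  tab <- wavefunctionTable(list(slaterRulesWavefunction("C")))
  prov <- slaterProvider(tab)
  H <- matrix(c(1, 0, 0, 2, 1, 0, 3, -1, 2), ncol = 3, byrow = TRUE)

  origin <- crystalModel(cubic10, list(atomSite("C1", "C", c(0, 0, 0))))
  Fo <- structureFactor(origin, H, prov)
  f <- xrayFormFactor(slaterRulesWavefunction("C"), stol(cubic10, H))
  expect_equal(Fo, complex(real = f), tolerance = 1e-12)
  expect_true(all(Re(Fo) > 0) && all(abs(Im(Fo)) < 1e-12))

  shifted <- crystalModel(cubic10, list(atomSite("C1", "C", c(0.5, 0, 0))))
  Fs <- structureFactor(shifted, H, prov)
  expect_equal(Fs, complex(real = f * (-1)^H[, 1]), tolerance = 1e-10)

  x <- 0.137
  pair <- crystalModel(cubic10, list(
    atomSite("C1", "C", c(x, 0, 0), occupancy = 0.5),
    atomSite("C2", "C", c(-x %% 1, 0, 0), occupancy = 0.5)))
  Fp <- structureFactor(pair, H, prov)
  expect_equal(Fp, complex(real = f * cos(2 * pi * H[, 1] * x)),
               tolerance = 1e-10)
})

test_that("Friedel symmetry and the F(000) electron sum hold", {
  toy <- makeToyCrystal(seed = 8, species = c("O", "C", "H"), spaceGroup = "P21/c",
                        noiseFraction = 0)
  prov <- slaterProvider(defaultWavefunctionTable())
  H <- toy$hkl[1:20, ]
  expect_equal(structureFactor(toy$model, -H, prov),
               Conj(structureFactor(toy$model, H, prov)), tolerance = 1e-10)
  ## F(000) with U = 0: strip ADPs
  m0 <- toy$model
  m0@sites <- lapply(m0@sites, function(st) { st@uIso <- 0; st })
  F000 <- structureFactor(m0, c(0, 0, 0), prov)
  nsym <- length(m0@symops)
  expect_equal(Re(F000), nsym * (8 + 6 + 1), tolerance = 1e-9)
  expect_equal(Im(F000), 0, tolerance = 1e-12)
})

test_that("symmetry expansion equals an explicit P1 listing for P2_1/c", {
  cell <- unitCell(7, 8, 9, beta = 101)
  site <- atomSite("O1", "O", c(0.21, 0.33, 0.41), uIso = 0.02)
  symops <- lapply(c("x, y, z", "-x, y+1/2, -z+1/2", "-x, -y, -z",
                     "x, -y+1/2, z+1/2"), parseSymop)
  model <- crystalModel(cell, list(site), symops)
  ## explicit listing of the four equivalents as a P1 model
  eq <- list(c(0.21, 0.33, 0.41), c(-0.21, 0.83, 0.09) %% 1,
             c(-0.21, -0.33, -0.41) %% 1, c(0.21, 0.17, 0.91) %% 1)
  p1 <- crystalModel(cell, lapply(seq_along(eq), function(i)
    atomSite(paste0("O", i), "O", eq[[i]], uIso = 0.02)))
  tabO <- wavefunctionTable(list(slaterRulesWavefunction("O")))
  H <- hklSphere(cell, 1.5)
  expect_equal(structureFactor(model, H, slaterProvider(tabO)),
               structureFactor(p1, H, slaterProvider(tabO)), tolerance = 1e-9)
  ## special position: atom on the inversion centre is not double counted
  inv <- crystalModel(cell, list(atomSite("O1", "O", c(0, 0, 0))), symops)
  expect_length(expandToP1(inv), 2)   # 000 and the screw image at (0,1/2,1/2)
})

test_that("missing species in the provider is reported by name", {
  model <- crystalModel(cubic10, list(atomSite("Xx1", "Xx", c(0, 0, 0))))
  prov <- slaterProvider(wavefunctionTable(list(slaterRulesWavefunction("C"))))
  expect_error(structureFactor(model, c(1, 0, 0), prov), "Xx")
})

test_that("weights and R statistics follow the SHELX-type scheme", {
  toy <- makeToyCrystal(seed = 5, noiseFraction = 0)
  st <- weightsAndRstats(toy$records, a = 0, b = 0)
  expect_equal(st$R1, 0)
  expect_equal(st$wR2, 0)
  expect_equal(st$weights, 1 / toy$records$sigFo2^2)

  ## independent spreadsheet-style recomputation on a perturbed set
  rec <- toy$records
  set.seed(77)
  rec$Fo2 <- rec$Fo2 * (1 + rnorm(nrow(rec), 0, 0.05))
  rec$Fo2[1] <- -abs(rec$Fo2[1])          # negative intensity stays negative
  a <- 0.2; b <- 0.3
  st2 <- weightsAndRstats(rec, a, b)
  Fc2 <- Mod(rec$Fc)^2
  P <- (pmax(rec$Fo2, 0) + 2 * Fc2) / 3
  w <- 1 / (rec$sigFo2^2 + (a * P)^2 + b * P)
  expect_equal(st2$weights, w)
  expect_equal(st2$wR2, sqrt(sum(w * (rec$Fo2 - Fc2)^2) / sum(w * rec$Fo2^2)))
  strong <- rec$Fo2 > 2 * rec$sigFo2
  expect_equal(st2$R1, sum(abs(sqrt(pmax(rec$Fo2[strong], 0)) - sqrt(Fc2[strong]))) /
                 sum(sqrt(pmax(rec$Fo2[strong], 0))))
  expect_identical(st2$nR1, sum(strong))
  expect_error(weightsAndRstats(rec[0, ], 0, 0), "empty")
})

test_that("the CIF subset round-trips models including aniso ADPs", {
  cell <- unitCell(7, 8, 9, beta = 101)
  sites <- list(
    atomSite("O1", "O", c(0.21, 0.33, 0.41), uIso = 0.02),
    atomSite("Ca1", "Ca", c(0.5, 0.25, 0.125), occupancy = 0.5, charge = 2L,
             uAniso = matrix(c(0.02, 0.003, 0, 0.003, 0.015, 0.001,
                               0, 0.001, 0.011), 3, 3)))
  model <- crystalModel(cell, sites, .p21cSymopsForTest())
  txt <- writeCifMinimal(model)
  back <- readCifMinimal(txt)
  expect_length(back@sites, 2)
  expect_length(back@symops, 4)
  for (i in 1:2) {
    expect_equal(back@sites[[i]]@xyz, model@sites[[i]]@xyz, tolerance = 1e-6)
    expect_identical(back@sites[[i]]@element, model@sites[[i]]@element)
    expect_identical(back@sites[[i]]@charge, model@sites[[i]]@charge)
  }
  expect_equal(back@sites[[2]]@uAniso, sites[[2]]@uAniso, tolerance = 1e-6)
  expect_equal(back@cell@volume, cell@volume, tolerance = 1e-4)
  ## second round trip is exact (canonical form)
  expect_identical(writeCifMinimal(back), txt)
  expect_error(readCifMinimal("data_x\n_cell_length_a 5\n"), "missing")
})

test_that("HKLF4 parsing is fixed-format with terminator handling", {
  rec <- readShelxHkl(c("   1   0   0  100.00    2.00",
                        "  -1   2  -3   -4.50    1.25",
                        "   0   0   0    0.00    0.00",
                        "   9   9   9  999.00    9.00"))
  expect_identical(nrow(rec), 2L)        # terminator drops the tail
  expect_identical(rec$h, c(1L, -1L))
  expect_equal(rec$Fo2[2], -4.5)         # negative intensities preserved
  expect_error(readShelxHkl("   1   0   0  1x0.00    2.00"), "line 1")
  ## write/read round trip
  txt <- writeShelxHkl(rec)
  expect_equal(readShelxHkl(txt), rec)
})
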