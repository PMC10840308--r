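test_that("buildTsc covers the resolution sphere with constant-per-shell values", {
  cell <- unitCell(10, 10, 10)
  model <- crystalModel(cell, list(atomSite("H1", "H", c(0.1, 0.2, 0.3))))
  tab <- buildTsc(model, defaultWavefunctionTable(), 5)
  expect_identical(nrow(tab@hkl), 32L)     # h^2+k^2+l^2 <= 4, 000 excluded
  expect_identical(tab@labels, "H1")
  expect_true(all(Im(tab@values) == 0))
  ## symmetry-equivalent reflections (equal s in a cubic cell) share values
  s <- stol(cell, tab@hkl)
  for (sv in unique(s)) {
    v <- Re(tab@values[abs(s - sv) < 1e-12, 1])
    expect_equal(max(v) - min(v), 0)
  }
  ## X-ray factors decrease with s for hydrogen and stay below the count
  ord <- order(s)
  expect_true(all(diff(Re(tab@values[ord, 1])) <= 1e-12))
  expect_lt(max(Re(tab@values)), 1)
})

test_that("electron-mode tables use Mott-Bethe factors and ion overrides fall back with a warning", {
  cell <- unitCell(8, 8, 8)
  model <- crystalModel(cell, list(atomSite("C1", "C", c(0, 0, 0)),
                                   atomSite("Ca1", "Ca", c(0.5, 0.5, 0.5))))
  wtab <- defaultWavefunctionTable()
  tabE <- buildTsc(model, wtab, 1.0, radiation = "electron")
  s <- stol(cell, tabE@hkl)
  expect_equal(Re(tabE@values[, 1]),
               edFormFactor(lookupWavefunction(wtab, "C"), s), tolerance = 1e-12)
  ## Ca+ has a tabulated configuration; Ca- does not -> neutral fallback
  expect_warning(
    tabI <- buildTsc(model, wtab, 1.0, ionOverrides = c(Ca1 = -1L)),
    "falling back")
  tabN <- buildTsc(model, wtab, 1.0)
  expect_equal(tabI@values[, 2], tabN@values[, 2])
  tabP <- buildTsc(model, wtab, 1.0, ionOverrides = c(Ca1 = 1L))
  expect_false(isTRUE(all.equal(tabP@values[, 2], tabN@values[, 2])))
})

test_that(".tsc files round-trip bit-for-bit and tolerate unknown headers", {
  toy <- makeToyCrystal(seed = 3, species = c("O", "H"))
  tab <- buildTsc(toy$model, defaultWavefunctionTable(), 1.2)
  txt <- writeTsc(tab)
  back <- readTsc(txt)
  expect_identical(writeTsc(back), txt)
  expect_identical(back@labels, tab@labels)
  expect_identical(back@hkl, tab@hkl)

  ## empty-row table round-trips
  empty <- tscTable(c("A", "B"), matrix(integer(0), 0, 3),
                    matrix(complex(0), 0, 2))
  expect_identical(nrow(readTsc(writeTsc(empty))@hkl), 0L)

  ## unknown header keys are skipped; missing DATA: is an error
  extra <- sub("DATA:", "AD: FALSE\nDATA:", txt, fixed = TRUE)
  expect_identical(readTsc(extra)@hkl, tab@hkl)
  expect_error(readTsc("TITLE: x\nSCATTERERS: A\n"), "DATA")
  ragged <- paste0(txt, "1 2 3 0.5,0\n")
  expect_error(readTsc(sub("SCATTERERS: O1 H2", "SCATTERERS: O1", txt, fixed = TRUE)),
               "expected")
})

test_that("merging .tsc tables concatenates columns with later-wins on duplicates", {
  hkl <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  t1 <- tscTable("A", hkl, matrix(complex(real = 1:3), 3, 1))
  t2 <- tscTable("B", hkl[c(2, 3, 1), ], matrix(complex(real = 4:6), 3, 1))
  m <- mergeTsc(list(t1, t2))
  expect_identical(m@labels, c("A", "B"))
  ## rows realigned to t1's hkl order
  expect_equal(Re(m@values[, 2]), c(6, 4, 5))

  empty <- tscTable(character(0), matrix(integer(0), 0, 3),
                    matrix(complex(0), 0, 0))
  expect_identical(mergeTsc(list(t1, empty))@values, t1@values)

  t3 <- tscTable("A", hkl, matrix(complex(real = 7:9), 3, 1))
  expect_warning(m2 <- mergeTsc(list(t1, t3)), "later table wins")
  expect_equal(Re(m2@values[, 1]), 7:9)

  t4 <- tscTable("C", hkl[1:2, ], matrix(complex(real = 1:2), 2, 1))
  expect_error(mergeTsc(list(t1, t4)), "symmetric difference")
})

test_that("the command line builds, merges and reports errors with documented exit codes", {
  dir <- withr::local_tempdir()
  toy <- makeToyCrystal(seed = 3, species = c("O", "H"))
  cif <- file.path(dir, "toy.cif")
  writeLines(toy$cif, cif)

  expect_identical(suppressMessages(
    tscCli(c("-cif", cif, "-IAM", "-dmin", "1.2"), outDir = dir)), 0L)
  out <- file.path(dir, "toy.tsc")
  expect_true(file.exists(out))
  tab <- readTsc(out)
  ref <- buildTsc(toy$model, defaultWavefunctionTable(), 1.2)
  expect_identical(writeTsc(tab), writeTsc(ref))

  ## ED mode and ion flags
  expect_identical(suppressMessages(
    tscCli(c("-cif", cif, "-IAM", "-dmin", "1.2", "-ED", "-Anions", "O1"),
           outDir = dir)), 0L)
  tabED <- readTsc(out)
  expect_false(isTRUE(all.equal(tabED@values, tab@values)))

  ## merge subcommand
  f1 <- file.path(dir, "a.tsc"); f2 <- file.path(dir, "b.tsc")
  writeTsc(tscTable("A", matrix(c(1, 0, 0), 1), matrix(complex(real = 1), 1, 1)), f1)
  writeTsc(tscTable("B", matrix(c(1, 0, 0), 1), matrix(complex(real = 2), 1, 1)), f2)
  expect_identical(suppressMessages(tscCli(c("-merge", f1, f2), outDir = dir)), 0L)
  merged <- readTsc(file.path(dir, "merged.tsc"))
  expect_identical(merged@labels, c("A", "B"))

  ## parse error -> 2; unknown species -> 3
  badCif <- file.path(dir, "bad.cif")
  writeLines("data_x\n_cell_length_a 5\n", badCif)
  expect_identical(suppressMessages(tscCli(c("-cif", badCif, "-IAM", "-dmin", "1"),
                                           outDir = dir)), 2L)
  xeCif <- file.path(dir, "xe.cif")
  m <- crystalModel(unitCell(8, 8, 8), list(atomSite("Xe1", "Xe", c(0, 0, 0))))
  writeLines(writeCifMinimal(m), xeCif)
  expect_identical(suppressMessages(tscCli(c("-cif", xeCif, "-IAM", "-dmin", "1"),
                                           outDir = dir)), 3L)
  ## missing arguments -> usage, exit 1
  expect_identical(suppressMessages(tscCli(character(0), outDir = dir)), 1L)

  ## fixtures subcommand emits the bundle
  fdir <- file.path(dir, "fx")
  expect_identical(suppressMessages(tscCli(c("-fixtures", fdir, "-seed", "3"))), 0L)
  expect_true(file.exists(file.path(fdir, "toy.cif")))
  expect_true(file.exists(file.path(fdir, "wavefunctions_synthetic.wft")))
})
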