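test_that("generation is reproducible from the seed and varies across seeds", {
  a <- makeToyComplexEnsemble(0.4, nFrames = 50, seed = 11)
  b <- makeToyComplexEnsemble(0.4, nFrames = 50, seed = 11)
  c <- makeToyComplexEnsemble(0.4, nFrames = 50, seed = 12)
  expect_identical(a@coords, b@coords)
  expect_false(identical(a@coords, c@coords))

  r1 <- makeSpotReplicates(substrate = "H3K4", noiseSd = 0.05, seed = 5)
  r2 <- makeSpotReplicates(substrate = "H3K4", noiseSd = 0.05, seed = 5)
  expect_identical(intensities(r1[[1]]), intensities(r2[[1]]))
  expect_false(identical(intensities(r1[[1]]), intensities(r1[[2]])))

  p1 <- makeProgressCurves(noiseSd = 0.05, seed = 9)
  p2 <- makeProgressCurves(noiseSd = 0.05, seed = 9)
  expect_identical(p1$H3K4$signal, p2$H3K4$signal)
})

test_that("planted TS fractions 0 and 1 are honoured exactly by construction", {
  none <- makeToyComplexEnsemble(0, nFrames = 200, seed = 1)
  all <- makeToyComplexEnsemble(1, nFrames = 100, seed = 2)
  expect_identical(countTSFrames(none)$ts_frames, 0L)
  expect_identical(countTSFrames(all)$ts_frames, 100L)
})

test_that("planted TS fraction is recovered within 3 binomial SEs at n = 5000", {
  ens <- makeToyComplexEnsemble(0.3, nFrames = 5000, seed = 42)
  rec <- countTSFrames(ens)
  emp <- rec$ts_frames / rec$total_frames
  expect_lt(abs(emp - 0.3), 3 * binomialSE(0.3, 5000))
  # brute-force per-frame classification agrees with the count
  geo <- ensembleGeometry(ens)
  manual <- sum(geo$d < 4 & abs(geo$thetaAttack - 109) <= 30 &
                  abs(geo$thetaLinear - 180) <= 30)
  expect_identical(rec$ts_frames, as.integer(manual))
})

test_that("non-TS frames violate a criterion with a clear margin", {
  ens <- makeToyComplexEnsemble(0, nFrames = 400, seed = 3,
                                geometryNoise = 5)
  geo <- ensembleGeometry(ens)
  crit <- tsCriteria()
  distOK <- geo$d < crit$dMax
  attackOK <- abs(geo$thetaAttack - 109) <= 30
  linearOK <- abs(geo$thetaLinear - 180) <= 30
  # exactly one criterion violated per frame
  expect_true(all(distOK + attackOK + linearOK == 2))
  # no frame sits near a boundary
  expect_true(all(geo$d[!distOK] > crit$dMax + 0.25))
  expect_true(all(abs(geo$thetaAttack[!attackOK] - 109) > 30 + 4.9))
  expect_true(all(abs(geo$thetaLinear[!linearOK] - 180) > 30 + 4.9))
})

test_that("planted contacts are recovered and invalid plants rejected", {
  plant <- contactPlant(c("P:R2", "P:G34"), c("E:Y361", "E:E364"),
                        fraction = c(0.7, 0.2))
  ens <- makeToyComplexEnsemble(0.1, nFrames = 2000, seed = 8,
                                contacts = plant)
  cp <- contactFractionMap(ens, c("P:R2", "P:G34"), c("E:Y361", "E:E364"))
  fr <- contactFractions(cp)
  expect_lt(abs(fr["P:R2", "E:Y361"] - 0.7), 3 * binomialSE(0.7, 2000))
  expect_lt(abs(fr["P:G34", "E:E364"] - 0.2), 3 * binomialSE(0.2, 2000))
  # non-planted cross pairs never touch
  expect_identical(fr["P:R2", "E:E364"], 0)
  expect_identical(fr["P:G34", "E:Y361"], 0)

  expect_error(contactPlant("P:R2", "E:Y361", 1.2), "fraction")
  expect_error(contactPlant("P:R2", "E:Y361", 0.5, in_distance = 5),
               "in_distance")
  expect_error(makeToyComplexEnsemble(0.5, nFrames = 0), "nFrames")
  expect_error(makeToyComplexEnsemble(-0.1, nFrames = 10), "tsFraction")
})

test_that("noiseless spot replicates are identical and uniform weights give flat DF", {
  w <- defaultSpotWeights("H3K4")
  reps <- makeSpotReplicates(w, substrate = "H3K4", noiseSd = 0, seed = 1)
  prof <- averageReplicates(lapply(reps, normalizeMinmax))
  expect_true(all(spotErrors(prof) == 0))

  # a constant grid cannot be min-max normalized; feed it through the
  # averaging path as already-normalized values instead
  uni <- matrix(0.5, nrow(w), ncol(w), dimnames = dimnames(w))
  upr <- lapply(makeSpotReplicates(uni, substrate = "H3K4", noiseSd = 0,
                                   seed = 1),
                function(a) { a@normalized <- TRUE; a })
  df <- discriminationFactors(averageReplicates(upr))
  expect_true(all(abs(discriminationGrid(df) - 1) < 1e-12))

  expect_error(makeSpotReplicates(uni - 0.5, substrate = "H3K4"),
               "positive")
})

test_that("a doubled weight becomes the per-position argmax after averaging", {
  w <- matrix(0.4, 18, 9,
              dimnames = dimnames(defaultSpotWeights("H3K4")))
  w["L", "-1"] <- 0.8
  w["R", "-2"] <- 0.8
  reps <- makeSpotReplicates(w, substrate = "H3K4", noiseSd = 0, seed = 2)
  prof <- averageReplicates(lapply(reps, normalizeMinmax))
  m <- intensities(prof)
  expect_identical(rownames(m)[which.max(m[, "-1"])], "L")
  expect_identical(rownames(m)[which.max(m[, "-2"])], "R")
})

test_that("progress curves follow the shared model at the endpoints", {
  pc <- makeProgressCurves(A = 0.2, B = 2, k4 = 0.5, k36 = 0.1,
                           times = c(0, 5, 50, 200), noiseSd = 0,
                           nExperiments = 1)
  expect_equal(pc$H3K4$signal[1], 0.2)          # t = 0 -> A
  expect_equal(pc$H3K36$signal[1], 0.2)
  # k * t = 100 and 20: at the asymptote within 1e-8
  expect_lt(abs(pc$H3K4$signal[4] - 2.2), 1e-8)
  expect_lt(abs(pc$H3K36$signal[4] - 2.2), 1e-8)
  expect_error(makeProgressCurves(k4 = -1), "rates")
  expect_error(makeProgressCurves(B = 0), "B must")
  expect_error(makeProgressCurves(times = c(-1, 2)), "non-negative")
})

test_that("generated ensembles round-trip through the frame-table dialect", {
  ens <- makeToyComplexEnsemble(0.5, nFrames = 20, seed = 4,
                                contacts = contactPlant("P:R2", "E:Y361",
                                                        0.5))
  path <- withr::local_tempfile(fileext = ".frames")
  writeFrameTable(ens, path)
  back <- readEnsemble(path, format = "frametable", substrate = "H3K4")
  expect_equal(back@coords, ens@coords, tolerance = 1e-8)
  expect_identical(atomTable(back)$residueLabel,
                   atomTable(ens)$residueLabel)
  # loaded ensembles feed every downstream stage without special cases
  expect_s4_class(selectAtoms(back, "P:R2"), "AtomSelection")
  expect_identical(countTSFrames(back)$total_frames, 20L)
})
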