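# Four-atom ensemble with explicitly placed reaction atoms.
geometryEnsemble <- function(frames) {
  atoms <- data.frame(atomId = 1:4, atomName = c("CD", "NZ", "CE", "SD"),
                      chain = c("P", "P", "X", "X"),
                      resname = c("K", "K", "SAM", "SAM"),
                      resno = c(4L, 4L, 900L, 900L),
                      stringsAsFactors = FALSE)
  buildEnsemble(atoms, frames)
}

test_that("reaction geometry matches hand-constructed configurations", {
  # collinear: Cd opposite the methyl carbon along z
  collinear <- rbind(c(0, 0, -1.5),   # CD
                     c(0, 0, 0),      # NZ
                     c(0, 0, 3),      # methyl C
                     c(0, 0, 6))      # S
  # orthogonal attack: CD on x, methyl C on z
  ortho <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 3), c(0, 0, 6))
  ens <- geometryEnsemble(list(collinear, ortho))
  g1 <- frameGeometry(ens, 1)
  expect_equal(g1$d, 3)
  expect_equal(g1$thetaAttack, 180)
  expect_equal(g1$thetaLinear, 180)
  g2 <- frameGeometry(ens, 2)
  expect_equal(g2$thetaAttack, 90)
  expect_equal(g2$thetaLinear, 180)
})

test_that("angles agree with the law-of-cosines oracle on random frames", {
  set.seed(71)
  frames <- lapply(1:1000, function(i) matrix(runif(12, -5, 5), 4, 3))
  ens <- geometryEnsemble(frames)
  map <- resolveAtomMap(ens)
  geo <- ensembleGeometry(ens, map)
  ora <- oracleGeometry(ens, map)
  expect_lt(max(abs(geo$thetaAttack - ora$thetaAttack)), 1e-9)
  expect_lt(max(abs(geo$thetaLinear - ora$thetaLinear)), 1e-9)
  expect_lt(max(abs(geo$d - ora$d)), 1e-12)
})

test_that("the TS classifier enforces strict distance and inclusive angle bounds", {
  crit <- tsCriteria()
  g <- function(d, a, l) list(d = d, thetaAttack = a, thetaLinear = l)
  expect_true(isTSLike(g(3.5, 109, 180), crit))
  expect_false(isTSLike(g(4.0, 109, 180), crit))   # strict < 4 A
  expect_false(isTSLike(g(3.5, 109, 149), crit))   # outside 180 +/- 30
  expect_true(isTSLike(g(3.5, 139, 150), crit))    # inclusive bounds
  expect_true(isTSLike(g(3.5, 79, 180), crit))
  expect_false(isTSLike(g(3.5, 139.001, 180), crit))
  expect_error(tsCriteria(dMax = -1), "dMax")
})

test_that("TS counting equals the brute-force per-frame loop and is monotone in the criteria", {
  ens <- makeToyComplexEnsemble(0.4, nFrames = 800, seed = 19)
  rec <- countTSFrames(ens)
  geo <- ensembleGeometry(ens)
  brute <- 0L
  for (f in seq_len(nFrames(ens))) {
    g <- geo[f, ]
    if (g$d < 4 && abs(g$thetaAttack - 109) <= 30 &&
        abs(g$thetaLinear - 180) <= 30) brute <- brute + 1L
  }
  expect_identical(rec$ts_frames, brute)

  # planted deterministic pattern
  pat <- rep(FALSE, 100); pat[1:10] <- TRUE
  pens <- makeToyComplexEnsemble(0, nFrames = 100, seed = 2,
                                 tsPattern = pat)
  expect_identical(countTSFrames(pens)$ts_frames, 10L)

  # relaxing any criterion never decreases the count
  for (relaxed in list(tsCriteria(dMax = 5),
                       tsCriteria(attackTol = 45),
                       tsCriteria(linearTol = 45))) {
    expect_gte(countTSFrames(ens, criteria = relaxed)$ts_frames,
               rec$ts_frames)
  }

  # rigid-motion invariance of the classification
  moved <- applyRigidMotion(ens, seed = 3)
  expect_identical(countTSFrames(moved)$ts_frames, rec$ts_frames)
})

test_that("binning assigns high strictly above the threshold with ties low", {
  recA <- data.frame(simulation_id = paste0("a", 1:3), substrate = "H3K4",
                     ts_frames = c(10L, 10L, 10L), total_frames = 100L)
  recB <- data.frame(simulation_id = paste0("b", 1:3), substrate = "H3K36",
                     ts_frames = c(0L, 0L, 0L), total_frames = 100L)
  tab <- binSimulations(recA, recB)       # pooled median = 5
  expect_identical(as.vector(tab), c(3L, 0L, 0L, 3L))
  expect_equal(attr(tab, "threshold"), 5)
  expect_equal(fisherExactTwoSided(tab), 0.1)

  # identical records: one all-zero column, p = 1
  same <- binSimulations(recA, recA)
  expect_true(any(colSums(same) == 0))
  expect_equal(fisherExactTwoSided(same), 1)

  # fixed threshold matches hand enumeration, ties -> low
  recC <- data.frame(simulation_id = paste0("c", 1:4), substrate = "H3K36",
                     ts_frames = c(5L, 6L, 2L, 9L), total_frames = 100L)
  tabF <- binSimulations(recA, recC, thresholdRule = "fixed",
                         threshold = 5)
  expect_identical(as.vector(tabF), c(3L, 2L, 0L, 2L))
  expect_error(binSimulations(recA[0, ], recB), "at least one")
})

test_that("the exact test matches full enumeration and is swap-invariant", {
  expect_equal(fisherExactTwoSided(matrix(5, 2, 2)), 1)
  set.seed(5)
  worst <- 0
  for (r1 in 0:12) for (r2 in 0:12) {
    for (a in 0:r1) {
      # sample one c per (r1, r2, a) to keep the sweep quick while the
      # acceptance suite does the exhaustive margin scan
      c <- sample(0:r2, 1)
      tab <- matrix(c(a, r1 - a, c, r2 - c), 2, byrow = TRUE)
      if (sum(tab) == 0) next
      p <- fisherExactTwoSided(tab)
      worst <- max(worst, abs(p - oracleFisher(tab)))
      swapped <- tab[2:1, 2:1]
      expect_equal(fisherExactTwoSided(swapped), p, tolerance = 1e-12)
    }
  }
  expect_lt(worst, 1e-12)
  # agreement with the reference implementation on a non-trivial table
  tab <- matrix(c(14L, 7L, 4L, 17L), 2, byrow = TRUE)
  expect_equal(fisherExactTwoSided(tab),
               stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  expect_error(fisherExactTwoSided(matrix(c(-1, 0, 0, 1), 2)),
               "non-negative")
})

test_that("pooled TS ratios follow frame-weighted arithmetic and flag zero denominators", {
  recA <- data.frame(simulation_id = "a", substrate = "H3K4",
                     ts_frames = 40L, total_frames = 100L)
  recB <- data.frame(simulation_id = "b", substrate = "H3K36",
                     ts_frames = 10L, total_frames = 100L)
  expect_equal(pooledTSRatio(recA, recB)$ratio, 4)
  expect_equal(pooledTSRatio(recA, recA)$ratio, 1)
  zero <- transform(recB, ts_frames = 0L)
  res <- pooledTSRatio(recA, zero)
  expect_true(res$infinite)
  expect_identical(res$ratio, Inf)

  # frame-pooled vs mean-of-fractions differ when totals are unequal
  recA2 <- data.frame(simulation_id = c("a1", "a2"), substrate = "H3K4",
                      ts_frames = c(90L, 0L),
                      total_frames = c(100L, 900L))
  pooled <- pooledTSRatio(recA2, recB, basis = "pooled")
  mof <- pooledTSRatio(recA2, recB, basis = "mean_of_fractions")
  expect_equal(pooled$freqA, 0.09)
  expect_equal(mof$freqA, 0.45)
})

test_that("planted fraction ratios are recovered within propagated binomial error", {
  fa <- 0.3; fb <- 0.1; n <- 4000
  ea <- makeToyComplexEnsemble(fa, nFrames = n, seed = 101)
  eb <- makeToyComplexEnsemble(fb, nFrames = n, seed = 102,
                               substrate = "H3K36")
  res <- pooledTSRatio(countTSFrames(ea), countTSFrames(eb))
  relSE <- sqrt(binomialSE(fa, n)^2 / fa^2 + binomialSE(fb, n)^2 / fb^2)
  expect_lt(abs(res$ratio - fa / fb), 3 * relSE * (fa / fb))
})
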