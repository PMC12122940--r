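# Two residues, one atom each, at a controlled distance in every frame.
pairEnsemble <- function(distances, chainB = "E", resnoB = 300L) {
  atoms <- data.frame(atomId = 1:2, atomName = c("CB", "CB"),
                      chain = c("P", chainB), resname = c("A", "L"),
                      resno = c(1L, resnoB), stringsAsFactors = FALSE)
  frames <- lapply(distances, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  buildEnsemble(atoms, frames)
}

test_that("the contact definition is strict at the cutoff and existential over pairs", {
  ens <- pairEnsemble(c(4.4, 4.5, 4.6))
  selA <- selectAtoms(ens, "P:A1")
  selB <- selectAtoms(ens, "E:L300")
  expect_true(residuesInContact(ens, 1, selA, selB))    # 4.4 < 4.5
  expect_false(residuesInContact(ens, 2, selA, selB))   # exactly 4.5
  expect_false(residuesInContact(ens, 3, selA, selB))

  # many distant pairs plus one close pair -> contact
  n <- 101
  atoms <- data.frame(atomId = 1:(n + 1),
                      atomName = paste0("C", 1:(n + 1)),
                      chain = c(rep("P", n), "E"),
                      resname = c(rep("F", n), "L"),
                      resno = c(rep(1L, n), 300L), stringsAsFactors = FALSE)
  xyz <- rbind(cbind(6 + seq_len(n - 1), 50, 0),  # >= 6 A away
               c(2.0, 0, 0),                      # the one close atom
               c(0, 0, 0))
  big <- buildEnsemble(atoms, list(xyz))
  expect_true(residuesInContact(big, 1,
                                selectAtoms(big, "P:F1", "all_heavy"),
                                selectAtoms(big, "E:L300", "all_heavy")))
  expect_error(residuesInContact(big, 1,
                                 selectAtoms(big, "P:F1", "all_heavy"),
                                 selectAtoms(big, "P:F1", "all_heavy")),
               "overlapping")
})

test_that("sequence neighbours on one chain are excluded, inter-chain pairs never", {
  sameChain <- pairEnsemble(3.0, chainB = "P", resnoB = 2L)
  a <- selectAtoms(sameChain, "P:A1")
  b <- selectAtoms(sameChain, "P:L2")
  expect_false(residuesInContact(sameChain, 1, a, b))
  cfg0 <- contactConfig(neighborExclusion = 0)
  expect_true(residuesInContact(sameChain, 1, a, b, cfg0))

  interChain <- pairEnsemble(3.0, chainB = "E", resnoB = 2L)
  expect_true(residuesInContact(interChain, 1,
                                selectAtoms(interChain, "P:A1"),
                                selectAtoms(interChain, "E:L2")))
})

test_that("fractions are exact frame counts and match the brute-force oracle", {
  pattern <- rep(FALSE, 1000)
  pattern[sample.int(1000, 620)] <- TRUE
  ens <- makeToyComplexEnsemble(
    0.2, nFrames = 1000, seed = 13,
    contacts = contactPlant("P:R2", "E:Y361", 0.62),
    contactPattern = list(pattern))
  cp <- contactFractionMap(ens, "P:R2", "E:Y361")
  expect_identical(contactFractions(cp)["P:R2", "E:Y361"], 0.62)
  selA <- selectAtoms(ens, "P:R2")
  selB <- selectAtoms(ens, "E:Y361")
  expect_identical(oracleContactFraction(ens, selA, selB), 0.62)

  # all-in / never-in plants
  always <- makeToyComplexEnsemble(0, nFrames = 50, seed = 2,
                                   contacts = contactPlant("P:R2",
                                                           "E:Y361", 1))
  never <- makeToyComplexEnsemble(0, nFrames = 50, seed = 2,
                                  contacts = contactPlant("P:R2",
                                                          "E:Y361", 0))
  expect_identical(contactFractions(contactFractionMap(
    always, "P:R2", "E:Y361"))[1, 1], 1)
  expect_identical(contactFractions(contactFractionMap(
    never, "P:R2", "E:Y361"))[1, 1], 0)
})

test_that("random small ensembles agree exactly with the naive all-pairs scan", {
  set.seed(31)
  for (rep in 1:3) {
    nres <- 4
    atoms <- data.frame(
      atomId = 1:(3 * nres),
      atomName = rep(c("CB", "CG", "CD1"), nres),
      chain = rep(c("P", "P", "E", "E"), each = 3),
      resname = rep(c("L", "F", "I", "L"), each = 3),
      resno = rep(c(1L, 2L, 101L, 102L), each = 3),
      stringsAsFactors = FALSE)
    frames <- lapply(1:40, function(f) matrix(runif(9 * nres, 0, 12),
                                              3 * nres, 3))
    ens <- buildEnsemble(atoms, frames)
    cp <- contactFractionMap(ens, c("P:L1", "P:F2"),
                             c("E:I101", "E:L102"))
    fr <- contactFractions(cp)
    for (p in rownames(fr))
      for (e in colnames(fr))
        expect_identical(fr[p, e],
                         oracleContactFraction(ens, selectAtoms(ens, p),
                                               selectAtoms(ens, e)))
    expect_true(all(fr * cp@nFrames == round(fr * cp@nFrames)))
  }
})

test_that("profiles are frame-permutation and rigid-motion invariant, monotone in cutoff", {
  ens <- makeToyComplexEnsemble(
    0.3, nFrames = 120, seed = 17,
    contacts = contactPlant(c("P:R2", "P:T3"), c("E:Y361", "E:A287"),
                            fraction = c(0.5, 0.25),
                            in_distance = c(3.2, 4.2)))
  pep <- c("P:R2", "P:T3"); enz <- c("E:Y361", "E:A287")
  base <- contactFractions(contactFractionMap(ens, pep, enz))

  shuffled <- ens
  perm <- sample(nFrames(ens))
  shuffled@coords <- ens@coords[, , perm, drop = FALSE]
  expect_identical(contactFractions(contactFractionMap(shuffled, pep, enz)),
                   base)

  moved <- applyRigidMotion(ens, seed = 5)
  expect_equal(contactFractions(contactFractionMap(moved, pep, enz)),
               base, tolerance = 1e-9)

  for (cut in c(3.0, 4.0, 4.5, 5.0, 7.0, 10.0)) {
    wide <- contactFractions(contactFractionMap(
      ens, pep, enz, contactConfig(cutoff = cut + 1)))
    narrow <- contactFractions(contactFractionMap(
      ens, pep, enz, contactConfig(cutoff = cut)))
    expect_true(all(wide >= narrow))
  }
})

test_that("merging pools counts frame-weighted and matches concatenation", {
  mk <- function(frac, n, seed)
    contactFractionMap(
      makeToyComplexEnsemble(0, nFrames = n, seed = seed,
                             contacts = contactPlant("P:R2", "E:Y361",
                                                     frac)),
      "P:R2", "E:Y361")
  one <- mk(1, 100, 1)
  zero <- mk(0, 300, 2)
  pooled <- mergeProfiles(list(one, zero))
  expect_identical(contactFractions(pooled)[1, 1], 0.25)
  expect_identical(pooled@nFrames, 400L)
  # idempotence on identical inputs
  expect_identical(contactFractions(mergeProfiles(list(one, one))),
                   contactFractions(one))

  # concatenation oracle on random profiles
  e1 <- makeToyComplexEnsemble(0, nFrames = 60, seed = 21,
                               contacts = contactPlant("P:R2", "E:Y361",
                                                       0.4))
  e2 <- makeToyComplexEnsemble(0, nFrames = 90, seed = 22,
                               contacts = contactPlant("P:R2", "E:Y361",
                                                       0.8))
  merged <- mergeProfiles(list(contactFractionMap(e1, "P:R2", "E:Y361"),
                               contactFractionMap(e2, "P:R2", "E:Y361")))
  concat <- e1
  concat@coords <- array(c(e1@coords, e2@coords),
                         dim = c(nAtoms(e1), 3, 150))
  direct <- contactFractionMap(concat, "P:R2", "E:Y361")
  expect_identical(contactCounts(merged), contactCounts(direct))

  # mismatched labels rejected
  other <- contactFractionMap(
    makeToyComplexEnsemble(0, nFrames = 10, seed = 1,
                           contacts = contactPlant("P:T3", "E:Y361", 1)),
    "P:T3", "E:Y361")
  expect_error(mergeProfiles(list(one, other)), "mismatched")
})
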