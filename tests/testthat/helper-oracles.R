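# Independent oracles used across the suite. These deliberately avoid
# the package's own computation paths: plain double loops, sqrt'd
# distances, the law of cosines instead of vector dot products, and
# stats::dhyper for hypergeometric probabilities.

# Brute-force contact scan: per frame, loop over every inter-selection
# atom pair and compare the sqrt'd Euclidean distance with the cutoff.
oracleContactFraction <- function(ensemble, selA, selB, cutoff = 4.5) {
  rowsA <- match(selA@atomIds, atomTable(ensemble)$atomId)
  rowsB <- match(selB@atomIds, atomTable(ensemble)$atomId)
  hits <- 0L
  for (f in seq_len(nFrames(ensemble))) {
    xyz <- frameCoords(ensemble, f)
    found <- FALSE
    for (i in rowsA) {
      for (j in rowsB) {
        dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dd < cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- hits + 1L
  }
  hits / nFrames(ensemble)
}

# Law-of-cosines geometry: angles from the three pairwise distances
# only, never from vectors.
oracleGeometry <- function(ensemble, map) {
  ang <- function(p, vertex, q) {
    b <- sqrt(sum((p - vertex)^2))
    c <- sqrt(sum((q - vertex)^2))
    a <- sqrt(sum((p - q)^2))
    acos(min(1, max(-1, (b^2 + c^2 - a^2) / (2 * b * c)))) * 180 / pi
  }
  out <- data.frame(frame = seq_len(nFrames(ensemble)), d = NA_real_,
                    thetaAttack = NA_real_, thetaLinear = NA_real_)
  for (f in seq_len(nFrames(ensemble))) {
    xyz <- frameCoords(ensemble, f)
    cd <- xyz[map$cd, ]; nz <- xyz[map$nz, ]
    mc <- xyz[map$methylC, ]; s <- xyz[map$sulfur, ]
    out$d[f] <- sqrt(sum((mc - nz)^2))
    out$thetaAttack[f] <- ang(cd, nz, mc)
    out$thetaLinear[f] <- ang(nz, mc, s)
  }
  out
}

# Full hypergeometric enumeration via stats::dhyper.
oracleFisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 + r2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Apply one random rigid motion (proper rotation + translation) to
# every frame of an ensemble.
applyRigidMotion <- function(ensemble, seed = 1) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- runif(3, -30, 30)
  for (f in seq_len(nFrames(ensemble)))
    ensemble@coords[, , f] <- frameCoords(ensemble, f) %*% t(rot) +
      rep(shift, each = nAtoms(ensemble))
  ensemble
}

# Hand-built two-chain ensemble for selection/contact unit tests:
# coordinates supplied as a list of nAtoms x 3 matrices.
buildEnsemble <- function(atoms, frames, stride = 20, substrate = "H3K4") {
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectoryEnsemble(coords, atoms, stride = stride,
                     substrate = substrate)
}

binomialSE <- function(p, n) sqrt(p * (1 - p) / n)
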