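# Internal helpers shared across modules.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# 18 proteinogenic residues used on specificity-scan arrays (no W, no C)
SCAN_RESIDUES <- c("A", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "Y")

aaShort <- function(resname) {
  resname <- toupper(resname)
  out <- AA3[resname]
  ifelse(is.na(out), resname, unname(out))
}

# Residue label: <chain>:<short residue name><residue number>, e.g. "P:R2",
# "E:Y361", "X:SAM900". Peptide residues keep H3 numbering, enzyme residues
# keep PRDM9 numbering; no 0-based re-indexing anywhere user-visible.
makeResidueLabel <- function(chain, resname, resno) {
  paste0(chain, ":", aaShort(resname), resno)
}

parseResidueLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z0-9]+):([A-Za-z]+?)(-?[0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed residue label(s): ", paste(label[bad], collapse = ", "))
  data.frame(chain = vapply(m, `[`, "", 2L),
             resname = vapply(m, `[`, "", 3L),
             resno = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

# Element from an atom name by PDB conventions: strip leading digits, take
# the first letter; known monatomic ions kept as-is.
guessElement <- function(atomName) {
  nm <- toupper(gsub("^[0-9']+", "", atomName))
  ions <- c("ZN", "FE", "MG", "MN", "CU", "NA", "CL", "BR")
  ifelse(nm %in% ions, nm, substr(nm, 1L, 1L))
}

# Deterministic sub-stream seed derivation: one sub-stream per replicate,
# kept inside 32-bit integer range.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(index)) %% 2147483647)
}

# Uniform random proper rotation (QR with positive diagonal, det corrected).
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
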