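#' Construct a TrajectoryEnsemble
#'
#' Low-level constructor used by the readers and the synthetic generator.
#'
#' @param coords numeric array \code{nAtoms x 3 x nFrames} (Angstrom).
#' @param atoms atom table; missing \code{element} and \code{residueLabel}
#'   columns are derived from atom names and chain/resname/resno.
#' @param stride frame spacing in ps (default 20, i.e. trajectory frames
#'   written every 20 ps).
#' @param simulationId,replicateGroup,substrate identifiers attached to
#'   downstream per-simulation statistics.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
trajectoryEnsemble <- function(coords, atoms, stride = 20,
                               simulationId = "sim1",
                               replicateGroup = "batch1",
                               substrate = "H3K4") {
  if (length(dim(coords)) == 2L)          # single frame convenience
    coords <- array(coords, dim = c(dim(coords), 1L))
  atoms$atomId <- as.integer(atoms$atomId %||% seq_len(nrow(atoms)))
  if (is.null(atoms$element))
    atoms$element <- guessElement(atoms$atomName)
  if (is.null(atoms$residueLabel))
    atoms$residueLabel <- makeResidueLabel(atoms$chain, atoms$resname,
                                           atoms$resno)
  atoms$resname <- aaShort(atoms$resname)
  new("TrajectoryEnsemble", coords = coords, atoms = atoms,
      stride = as.numeric(stride), simulationId = simulationId,
      replicateGroup = replicateGroup, substrate = substrate)
}

#' @describeIn nFrames frame count of an ensemble
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@coords)[3L])

#' @describeIn nAtoms atom count of an ensemble
#' @export
setMethod("nAtoms", "TrajectoryEnsemble", function(x) dim(x@coords)[1L])

#' @describeIn atomTable atom metadata of an ensemble
#' @export
setMethod("atomTable", "TrajectoryEnsemble", function(x) x@atoms)

#' @describeIn residueLabels unique residue labels of an ensemble, in
#'   atom-table order
#' @export
setMethod("residueLabels", "TrajectoryEnsemble",
          function(x, ...) unique(x@atoms$residueLabel))

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble", object@simulationId,
      sprintf("(%s, group %s)\n", object@substrate, object@replicateGroup))
  cat(sprintf("  %d atoms x %d frames, stride %g ps (%g ns total)\n",
              nAtoms(object), nFrames(object), object@stride,
              nFrames(object) * object@stride / 1000))
  cat("  residues:", paste(utils::head(residueLabels(object), 8L),
                           collapse = " "),
      if (length(residueLabels(object)) > 8L) "..." else "", "\n")
})

#' Coordinates of one frame
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param frame 1-based frame index.
#' @return numeric \code{nAtoms x 3} matrix (Angstrom).
#' @export
frameCoords <- function(ensemble, frame) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  if (frame < 1L || frame > nFrames(ensemble))
    stop("frame index out of range")
  ensemble@coords[, , frame, drop = FALSE][, , 1L]
}

## ------------------------------------------------------------------
## Plain frame-table dialect: one row per atom per frame with columns
## frame_index, atom_id, residue_label, atom_name, x, y, z (Angstrom).
## ------------------------------------------------------------------

#' Write an ensemble in the plain frame-table dialect
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFrameTable <- function(ensemble, path) {
  nf <- nFrames(ensemble)
  na <- nAtoms(ensemble)
  at <- atomTable(ensemble)
  xyz <- aperm(ensemble@coords, c(1L, 3L, 2L))  # atoms x frames x 3
  df <- data.frame(
    frame_index = rep(seq_len(nf), each = na),
    atom_id = rep(at$atomId, nf),
    residue_label = rep(at$residueLabel, nf),
    atom_name = rep(at$atomName, nf),
    x = sprintf("%.9f", as.vector(xyz[, , 1L])),
    y = sprintf("%.9f", as.vector(xyz[, , 2L])),
    z = sprintf("%.9f", as.vector(xyz[, , 3L])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readFrameTable <- function(path, stride = 20, simulationId = NULL,
                           substrate = "H3K4") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("frame_index", "atom_id", "residue_label", "atom_name",
            "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("frame table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty trajectory")
  frames <- sort(unique(df$frame_index))
  counts <- table(df$frame_index)
  if (length(unique(counts)) != 1L)
    stop("mismatched atom counts across frames")
  df <- df[order(df$frame_index, df$atom_id), ]
  na <- as.integer(counts[1L])
  nf <- length(frames)
  first <- df[df$frame_index == frames[1L], ]
  parsed <- parseResidueLabel(first$residue_label)
  atoms <- data.frame(atomId = first$atom_id, atomName = first$atom_name,
                      chain = parsed$chain, resname = parsed$resname,
                      resno = parsed$resno,
                      element = guessElement(first$atom_name),
                      residueLabel = first$residue_label,
                      stringsAsFactors = FALSE)
  same <- vapply(frames, function(f)
    identical(df$atom_id[df$frame_index == f], first$atom_id), TRUE)
  if (!all(same)) stop("atom ids differ between frames")
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  coords[, 1L, ] <- df$x
  coords[, 2L, ] <- df$y
  coords[, 3L, ] <- df$z
  trajectoryEnsemble(coords, atoms, stride = stride,
                     simulationId = simulationId %||%
                       sub("\\.[^.]*$", "", basename(path)),
                     substrate = substrate)
}

## ------------------------------------------------------------------
## Standard-format readers (PDB topology, multi-model PDB or DCD
## coordinates) via bio3d.
## ------------------------------------------------------------------

bio3dAtoms <- function(pdb) {
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  data.frame(atomId = at$eleno, atomName = at$elety, chain = chain,
             resname = aaShort(at$resid), resno = at$resno,
             element = guessElement(at$elety),
             residueLabel = makeResidueLabel(chain, at$resid, at$resno),
             stringsAsFactors = FALSE)
}

#' Load a trajectory ensemble from files
#'
#' Supported inputs: the plain frame-table dialect (self-contained),
#' a PDB file (single- or multi-model; doubles as topology), or a DCD
#' binary trajectory together with a PDB topology.
#'
#' @param coordinates path to the coordinate source (frame table, PDB,
#'   or DCD file).
#' @param topology path to a PDB topology; required for DCD input,
#'   ignored for the other formats.
#' @param format one of \code{"auto"}, \code{"frametable"}, \code{"pdb"},
#'   \code{"dcd"}; \code{"auto"} dispatches on the file extension.
#' @param stride frame spacing in ps attached as metadata.
#' @param simulationId,substrate metadata carried through the analysis.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
readEnsemble <- function(coordinates, topology = NULL,
                         format = c("auto", "frametable", "pdb", "dcd"),
                         stride = 20, simulationId = NULL,
                         substrate = "H3K4") {
  format <- match.arg(format)
  if (!file.exists(coordinates)) stop("no such file: ", coordinates)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", coordinates))
    format <- switch(ext, pdb = "pdb", dcd = "dcd",
                     tsv = "frametable", txt = "frametable",
                     frames = "frametable",
                     stop("unknown trajectory format: .", ext))
  }
  simulationId <- simulationId %||% sub("\\.[^.]*$", "", basename(coordinates))
  if (format == "frametable")
    return(readFrameTable(coordinates, stride = stride,
                          simulationId = simulationId, substrate = substrate))
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(coordinates, multi = TRUE, verbose = FALSE)
    atoms <- bio3dAtoms(pdb)
    xyz <- pdb$xyz                       # frames x 3*nAtoms
    nf <- nrow(xyz)
    na <- nrow(atoms)
    coords <- array(NA_real_, dim = c(na, 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  } else {                               # dcd
    if (is.null(topology)) stop("DCD input requires a PDB topology")
    pdb <- bio3d::read.pdb(topology, verbose = FALSE)
    atoms <- bio3dAtoms(pdb)
    xyz <- bio3d::read.dcd(coordinates, verbose = FALSE)
    if (ncol(xyz) != 3L * nrow(atoms))
      stop("mismatched atom counts between topology and trajectory")
    nf <- nrow(xyz)
    coords <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  if (dim(coords)[3L] == 0L) stop("empty trajectory")
  trajectoryEnsemble(coords, atoms, stride = stride,
                     simulationId = simulationId, substrate = substrate)
}

## ------------------------------------------------------------------
## Atom selections
## ------------------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Select the heavy atoms of one residue
#'
#' \code{side_chain_heavy} drops the backbone (N, CA, C, O, OXT) and all
#' hydrogens; \code{all_heavy} drops only hydrogens. Glycine has no heavy
#' side-chain atom and is automatically promoted to \code{all_heavy},
#' matching the convention of determining glycine contacts over all its
#' atoms.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param residueLabel residue label, e.g. \code{"P:R2"}.
#' @param mode \code{"side_chain_heavy"} (default) or \code{"all_heavy"}.
#' @param promoteGlycine promote glycine to \code{all_heavy} instead of
#'   failing on an empty side-chain selection.
#' @return an \linkS4class{AtomSelection}.
#' @export
selectAtoms <- function(ensemble, residueLabel,
                        mode = c("side_chain_heavy", "all_heavy"),
                        promoteGlycine = TRUE) {
  mode <- match.arg(mode)
  at <- atomTable(ensemble)
  rows <- at[at$residueLabel == residueLabel, ]
  if (nrow(rows) == 0L) stop("residue not found: ", residueLabel)
  heavy <- rows[rows$element != "H", ]
  isGly <- any(heavy$resname == "G")
  applied <- mode
  if (mode == "side_chain_heavy") {
    if (isGly && promoteGlycine) {
      applied <- "all_heavy"
    } else {
      heavy <- heavy[!toupper(heavy$atomName) %in% BACKBONE_NAMES, ]
    }
  }
  if (nrow(heavy) == 0L)
    stop("empty selection for ", residueLabel, " in mode ", mode)
  new("AtomSelection", residueLabel = residueLabel, mode = applied,
      atomIds = as.integer(heavy$atomId))
}

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection %s [%s]: %d atoms\n", object@residueLabel,
              object@mode, length(object@atomIds)))
})

# Row indices in the coords array for an AtomSelection.
selectionRows <- function(ensemble, selection) {
  idx <- match(selection@atomIds, atomTable(ensemble)$atomId)
  if (anyNA(idx))
    stop("selection refers to atoms absent from the ensemble")
  idx
}

#' Resolve the reaction-geometry atom map
#'
#' Locates the four atoms defining the methyl-transfer geometry: the
#' target-lysine Cdelta and Nepsilon (atom names CD, NZ) and the cofactor
#' methyl carbon and sulfur (atom names CE, SD on AdoMet). Cofactor atom
#' naming varies between dialects, so every piece can be overridden.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param overrides optional named list with any of \code{lysine},
#'   \code{cofactor} (residue labels), \code{cd}, \code{nz},
#'   \code{methylC}, \code{sulfur} (atom names).
#' @return named list of coords-array row indices: \code{cd}, \code{nz},
#'   \code{methylC}, \code{sulfur}.
#' @export
resolveAtomMap <- function(ensemble, overrides = list()) {
  at <- atomTable(ensemble)
  nms <- list(cd = overrides$cd %||% "CD", nz = overrides$nz %||% "NZ",
              methylC = overrides$methylC %||% "CE",
              sulfur = overrides$sulfur %||% "SD")
  findRes <- function(label, needed) {
    if (!is.null(label)) {
      cand <- at[at$residueLabel == label, ]
      if (nrow(cand) == 0L) stop("residue not found: ", label)
      return(cand)
    }
    has <- vapply(split(at, at$residueLabel), function(r)
      all(needed %in% toupper(r$atomName)), TRUE)
    # lysine side chains also carry CD+NZ only when resname is K
    hit <- names(has)[has]
    if (length(hit) == 0L)
      stop("no residue carries atoms ", paste(needed, collapse = "+"))
    at[at$residueLabel == hit[1L], ]
  }
  lysRows <- if (!is.null(overrides$lysine)) {
    findRes(overrides$lysine, c(nms$cd, nms$nz))
  } else {
    lys <- at[at$resname == "K", ]
    byRes <- split(lys, lys$residueLabel)
    ok <- vapply(byRes, function(r)
      all(toupper(c(nms$cd, nms$nz)) %in% toupper(r$atomName)), TRUE)
    if (!any(ok)) stop("no lysine residue with ", nms$cd, "/", nms$nz,
                       " atoms found; supply overrides$lysine")
    byRes[[names(ok)[ok][1L]]]
  }
  cofRows <- if (!is.null(overrides$cofactor)) {
    findRes(overrides$cofactor, c(nms$methylC, nms$sulfur))
  } else {
    nonStd <- at[!at$resname %in% AA3 & !(at$residueLabel %in%
                                            lysRows$residueLabel), ]
    byRes <- split(nonStd, nonStd$residueLabel)
    ok <- vapply(byRes, function(r)
      all(toupper(c(nms$methylC, nms$sulfur)) %in% toupper(r$atomName)), TRUE)
    if (!any(ok)) stop("no cofactor residue with ", nms$methylC, "/",
                       nms$sulfur, " atoms found; supply overrides$cofactor")
    byRes[[names(ok)[ok][1L]]]
  }
  pick <- function(rows, name) {
    id <- rows$atomId[toupper(rows$atomName) == toupper(name)]
    if (length(id) != 1L)
      stop("atom ", name, " not uniquely found in ", rows$residueLabel[1L])
    match(id, at$atomId)
  }
  list(cd = pick(lysRows, nms$cd), nz = pick(lysRows, nms$nz),
       methylC = pick(cofRows, nms$methylC),
       sulfur = pick(cofRows, nms$sulfur))
}
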