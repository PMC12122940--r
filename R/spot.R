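#' Template definitions for the two specificity-scan arrays
#'
#' H3 1-15 with target K4 (scanned positions -3..+5) and H3 29-43 with
#' target K36 (scanned positions -4..+4). Eighteen substituting residues
#' (all proteinogenic amino acids except tryptophan and cysteine).
#'
#' @param substrate \code{"H3K4"} or \code{"H3K36"}.
#' @return list with \code{template}, \code{templateStart},
#'   \code{targetPosition} (index within the template),
#'   \code{positions} (labels relative to the target K) and
#'   \code{residues}.
#' @export
scanTemplate <- function(substrate = c("H3K4", "H3K36")) {
  substrate <- match.arg(substrate)
  if (substrate == "H3K4")
    list(template = "ARTKQTARKSTGGKA", templateStart = 1L,
         targetPosition = 4L,
         positions = positionLabels(-3:5), residues = SCAN_RESIDUES)
  else
    list(template = "APATGGVKKPHRYRP", templateStart = 29L,
         targetPosition = 8L,
         positions = positionLabels(-4:4), residues = SCAN_RESIDUES)
}

positionLabels <- function(x) {
  ifelse(as.integer(x) > 0, paste0("+", x), as.character(x))
}

#' Construct a SpecificityArray
#'
#' @param intensities numeric matrix, rows = the 18 scan residues,
#'   columns = positions relative to the target K.
#' @param substrate \code{"H3K4"} or \code{"H3K36"} (sets the template).
#' @param replicateId replicate identifier.
#' @param normalized whether the grid is already min-max normalized.
#' @return a \linkS4class{SpecificityArray}.
#' @export
specificityArray <- function(intensities, substrate = "H3K4",
                             replicateId = "rep1", normalized = FALSE) {
  tpl <- scanTemplate(substrate)
  new("SpecificityArray", intensities = intensities,
      template = tpl$template, templateStart = tpl$templateStart,
      targetPosition = tpl$targetPosition, replicateId = replicateId,
      substrate = substrate, normalized = normalized)
}

#' @describeIn intensities intensity grid of one replicate array
#' @export
setMethod("intensities", "SpecificityArray", function(x) x@intensities)

#' @describeIn intensities mean normalized grid of an averaged profile
#' @export
setMethod("intensities", "SpotProfile", function(x) x@mean)

#' @describeIn spotErrors per-spot replicate error grid
#' @export
setMethod("spotErrors", "SpotProfile", function(x) x@error)

#' @describeIn discriminationGrid discrimination-factor grid
#' @export
setMethod("discriminationGrid", "DiscriminationProfile", function(x) x@df)

setMethod("show", "SpecificityArray", function(object) {
  cat(sprintf("SpecificityArray %s replicate %s (%s)\n", object@substrate,
              object@replicateId,
              if (object@normalized) "normalized" else "raw"))
  cat(sprintf("  template %s (H3 %d-), target K at template index %d\n",
              object@template, object@templateStart, object@targetPosition))
  cat(sprintf("  %d residues x %d positions [%s]\n",
              nrow(object@intensities), ncol(object@intensities),
              paste(range(colnames(object@intensities)), collapse = " .. ")))
})

setMethod("show", "SpotProfile", function(object) {
  cat(sprintf("SpotProfile %s: mean of %d replicates, error type %s\n",
              object@substrate, object@nReplicates, object@errorType))
  cat(sprintf("  max per-spot error %.1f%%\n", 100 * max(object@error)))
})

setMethod("show", "DiscriminationProfile", function(object) {
  cat(sprintf("DiscriminationProfile (%s, epsilon %g): %d residues x %d positions, DF range %.3g .. %.3g\n",
              object@reference, object@epsilon, nrow(object@df),
              ncol(object@df), min(object@df), max(object@df)))
})

#' Min-max normalize a specificity array
#'
#' Each spot intensity is mapped to (x - min) / (max - min) using the
#' total intensity extrema of that array, so the dimmest spot maps to 0
#' and the brightest to 1. Applied per replicate before averaging.
#'
#' @param array a \linkS4class{SpecificityArray}.
#' @return the normalized \linkS4class{SpecificityArray}.
#' @export
normalizeMinmax <- function(array) {
  x <- array@intensities
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("constant array: min-max normalization undefined")
  array@intensities <- (x - rng[1L]) / (rng[2L] - rng[1L])
  array@normalized <- TRUE
  array
}

#' Average normalized replicate arrays
#'
#' Per-spot mean and replicate error on the normalized 0-1 scale. The
#' default error is the mean absolute deviation from the replicate mean
#' (|a - b| / 2 for duplicates); \code{errorType = "range"} gives the
#' full spread (|a - b| for duplicates) instead.
#'
#' @param replicates list of at least two normalized
#'   \linkS4class{SpecificityArray}s with identical grids.
#' @param errorType \code{"mad_from_mean"} or \code{"range"}.
#' @return a \linkS4class{SpotProfile}.
#' @export
averageReplicates <- function(replicates,
                              errorType = c("mad_from_mean", "range")) {
  errorType <- match.arg(errorType)
  if (length(replicates) < 2L) stop("need at least two replicates")
  dn <- dimnames(replicates[[1L]]@intensities)
  for (r in replicates) {
    if (!r@normalized)
      stop("replicates must be min-max normalized before averaging")
    if (!identical(dimnames(r@intensities), dn))
      stop("replicate grids do not match")
  }
  arr <- simplify2array(lapply(replicates, slot, "intensities"))
  m <- apply(arr, c(1L, 2L), mean)
  err <- switch(errorType,
                mad_from_mean = apply(arr, c(1L, 2L),
                                      function(v) mean(abs(v - mean(v)))),
                range = apply(arr, c(1L, 2L),
                              function(v) max(v) - min(v)))
  new("SpotProfile", mean = m, error = err,
      nReplicates = length(replicates), errorType = errorType,
      substrate = replicates[[1L]]@substrate)
}

#' Count spots whose replicate error exceeds a threshold
#'
#' @param profile a \linkS4class{SpotProfile}.
#' @param thresholdPercent threshold in percent of the normalized scale,
#'   in (0, 100); spots count when strictly above it.
#' @return integer count.
#' @export
countErrorExceedance <- function(profile, thresholdPercent) {
  if (thresholdPercent <= 0 || thresholdPercent >= 100)
    stop("threshold must be in (0, 100) percent")
  sum(100 * profile@error > thresholdPercent)
}

#' Discrimination factors per position
#'
#' DF(position, a) = (mean(position, a) + epsilon) divided by the average
#' of (mean(position, b) + epsilon) over all other residues b at that
#' position: the preference for residue a relative to all alternatives.
#' The epsilon guard (on the 0-1 scale) keeps factors finite on empty
#' rows. If all residues at a position are equally methylated all its
#' factors are 1.
#'
#' @param profile a \linkS4class{SpotProfile}.
#' @param epsilon additive guard, default 1e-6.
#' @return a \linkS4class{DiscriminationProfile}.
#' @export
discriminationFactors <- function(profile, epsilon = 1e-6) {
  m <- profile@mean + epsilon
  nres <- nrow(m)
  colTot <- matrix(colSums(m), nrow = nres, ncol = ncol(m), byrow = TRUE)
  others <- (colTot - m) / (nres - 1L)
  df <- m / others
  dimnames(df) <- dimnames(profile@mean)
  new("DiscriminationProfile", df = df, epsilon = epsilon,
      reference = "mean_of_others")
}

#' Rank residues per position by discrimination factor
#'
#' @param df a \linkS4class{DiscriminationProfile}.
#' @param topK how many residues to report per position.
#' @return data.frame with columns \code{position}, \code{rank},
#'   \code{residue}, \code{df}; ties broken alphabetically.
#' @export
rankPreferences <- function(df, topK = 3L) {
  if (topK < 1L) stop("topK must be >= 1")
  g <- df@df
  out <- lapply(colnames(g), function(pos) {
    ord <- order(-g[, pos], rownames(g))
    k <- min(topK, nrow(g))
    data.frame(position = pos, rank = seq_len(k),
               residue = rownames(g)[ord][seq_len(k)],
               df = g[ord, pos][seq_len(k)], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ------------------------------------------------------------------
## Delimited I/O: rows = substituted residue, cols = position labels,
## header row and column mandatory.
## ------------------------------------------------------------------

#' Write a specificity grid as a delimited table
#'
#' @param x a \linkS4class{SpecificityArray}, \linkS4class{SpotProfile}
#'   (mean grid) or plain matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSpotGrid <- function(x, path) {
  g <- if (is.matrix(x)) x else intensities(x)
  utils::write.table(data.frame(residue = rownames(g), g,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a specificity grid from a delimited table
#'
#' @param path input file: first column residue letters, remaining
#'   columns one per position label, header row mandatory.
#' @param substrate,replicateId passed to
#'   \code{\link{specificityArray}}.
#' @return a \linkS4class{SpecificityArray}.
#' @export
readSpotGrid <- function(path, substrate = "H3K4", replicateId = "rep1") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1L, drop = FALSE])
  rownames(g) <- df[[1L]]
  specificityArray(g, substrate = substrate, replicateId = replicateId)
}
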