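#' Number of frames in an ensemble
#' @param x a \linkS4class{TrajectoryEnsemble}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in an ensemble
#' @param x a \linkS4class{TrajectoryEnsemble}.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom metadata table
#' @param x a \linkS4class{TrajectoryEnsemble}.
#' @return data.frame of per-atom metadata.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Residue labels present in an object
#' @param x an object carrying residue labels.
#' @param ... passed to methods.
#' @return character vector of residue labels.
#' @export
setGeneric("residueLabels", function(x, ...) standardGeneric("residueLabels"))

#' Contact fractions of a profile
#' @param x a \linkS4class{ContactProfile}.
#' @return numeric matrix of fractions in [0, 1].
#' @export
setGeneric("contactFractions", function(x) standardGeneric("contactFractions"))

#' Contact counts of a profile
#' @param x a \linkS4class{ContactProfile}.
#' @return integer matrix of frame counts.
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' Intensity grid of a specificity array
#' @param x a \linkS4class{SpecificityArray} or \linkS4class{SpotProfile}.
#' @return numeric matrix, residue x position.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Per-spot replicate errors of an averaged profile
#' @param x a \linkS4class{SpotProfile}.
#' @return numeric matrix on the normalized 0-1 scale.
#' @export
setGeneric("spotErrors", function(x) standardGeneric("spotErrors"))

#' Discrimination-factor grid
#' @param x a \linkS4class{DiscriminationProfile}.
#' @return positive numeric matrix, residue x position.
#' @export
setGeneric("discriminationGrid",
           function(x) standardGeneric("discriminationGrid"))

#' Fitted rate-constant ratio
#' @param x a \linkS4class{SharedFitResult}.
#' @return list with components \code{ratio} and \code{se}.
#' @export
setGeneric("rateRatio", function(x) standardGeneric("rateRatio"))

#' Fitted coefficients
#' @param object a \linkS4class{SharedFitResult}.
#' @param ... ignored.
#' @return named numeric vector A, B, kH3K4, kH3K36.
#' @export
setGeneric("coef")
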