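#' Number of specimens and landmarks
#'
#' @param x a [LandmarkSet-class] or [AlignedShapes-class].
#' @return integer.
#' @export
setGeneric("nSpecimens", function(x) standardGeneric("nSpecimens"))

#' @rdname nSpecimens
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))

#' Accessors for landmark containers
#'
#' \code{landmarkCoords} returns the \code{k x 2 x n} coordinate array,
#' \code{taxa} the per-specimen taxon labels, \code{landmarkRoles} the
#' per-landmark role vector, and \code{specimenSide} the body side.
#'
#' @param x a [LandmarkSet-class] (or subclass).
#' @return see description.
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @rdname landmarkCoords
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname landmarkCoords
#' @export
setGeneric("landmarkRoles", function(x) standardGeneric("landmarkRoles"))

#' @rdname landmarkCoords
#' @export
setGeneric("specimenSide", function(x) standardGeneric("specimenSide"))

#' Accessors for aligned shapes
#'
#' @param x an [AlignedShapes-class].
#' @return \code{consensusShape}: the \code{k x 2} mean shape;
#'   \code{centroidSizes}: the pre-scaling centroid sizes.
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))

#' @rdname consensusShape
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))

#' Accessors for morphospaces
#'
#' @param x a [Morphospace-class].
#' @return \code{pcScores}: the centred \code{n x m} score matrix;
#'   \code{eigenvalues}: the PC variances; \code{varianceFraction}: their
#'   normalized fractions.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname pcScores
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname pcScores
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))
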