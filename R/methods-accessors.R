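#' @rdname nSpecimens
setMethod("nSpecimens", "LandmarkSet", function(x) dim(x@coords)[3])

#' @rdname nSpecimens
setMethod("nLandmarks", "LandmarkSet", function(x) dim(x@coords)[1])

#' @rdname landmarkCoords
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' @rdname landmarkCoords
setMethod("taxa", "LandmarkSet", function(x) x@taxon)

#' @rdname landmarkCoords
setMethod("taxa", "Morphospace", function(x) x@taxonOrder)

#' @rdname landmarkCoords
setMethod("landmarkRoles", "LandmarkSet", function(x) x@roles)

#' @rdname landmarkCoords
setMethod("specimenSide", "LandmarkSet", function(x) x@side)

#' @rdname consensusShape
setMethod("consensusShape", "AlignedShapes", function(x) x@consensus)

#' @rdname consensusShape
setMethod("centroidSizes", "AlignedShapes", function(x) x@centroidSizes)

#' @rdname pcScores
setMethod("pcScores", "Morphospace", function(x) x@scores)

#' @rdname pcScores
setMethod("eigenvalues", "Morphospace", function(x) x@eigenvalues)

#' @rdname pcScores
setMethod("varianceFraction", "Morphospace", function(x) x@varianceFraction)

#' Subset a landmark set by specimen
#'
#' @param x a [LandmarkSet-class] or [AlignedShapes-class].
#' @param i integer, logical or character (specimen IDs) index.
#' @param j,...,drop ignored.
#' @return an object of the same class.
#' @export
setMethod("[", "LandmarkSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@specimenID)
  initialize(x,
    coords = x@coords[, , i, drop = FALSE],
    specimenID = x@specimenID[i],
    taxon = x@taxon[i],
    side = x@side[i])
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nSpecimens(object), "specimens,",
      nLandmarks(object), "landmarks (",
      sum(object@roles == "fixed"), "fixed +",
      sum(object@roles == "semilandmark"), "semilandmarks )\n")
  cat("  taxa:", length(unique(object@taxon)), "unique\n")
})

setMethod("show", "AlignedShapes", function(object) {
  cat("AlignedShapes:", nSpecimens(object), "specimens,",
      nLandmarks(object), "landmarks\n")
  cat("  GPA iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  centroid size range:",
      sprintf("%.4g - %.4g", min(object@centroidSizes),
              max(object@centroidSizes)), "\n")
})

setMethod("show", "Morphospace", function(object) {
  m <- length(object@eigenvalues)
  cat("Morphospace:", nrow(object@scores), "taxa,", m, "components\n")
  vf <- object@varianceFraction
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
              100 * vf[1], if (m > 1) 100 * vf[2] else 0,
              100 * sum(vf[seq_len(min(2, m))])))
})

setMethod("show", "DensityLandscape", function(object) {
  cat("DensityLandscape:", length(object@x), "x", length(object@y),
      "grid; bandwidth", sprintf("(%.4g, %.4g)", object@bandwidth[1],
                                 object@bandwidth[2]), "\n")
})

setMethod("show", "FocalRegion", function(object) {
  if (object@type == "ellipse")
    cat(sprintf("FocalRegion '%s': ellipse centre (%.3g, %.3g), semi-axes (%.3g, %.3g), angle %.3g rad\n",
                object@label, object@center[1], object@center[2],
                object@semiAxes[1], object@semiAxes[2], object@angle))
  else
    cat(sprintf("FocalRegion '%s': %d taxa\n", object@label,
                length(object@taxa)))
})

setMethod("show", "PhylomorphospaceLayout", function(object) {
  cat("PhylomorphospaceLayout:", nrow(object@tipPoints), "tips,",
      nrow(object@nodePoints), "internal nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "KResult", function(object) {
  cat(sprintf("Phylogenetic signal Kmult = %.4g, p = %.4g (%d permutations)\n",
              object@K, object@p, object@nPermutations))
})

setMethod("show", "DisparityResult", function(object) {
  cat("Procrustes variance (disparity) by group:\n")
  print(round(object@variances, 5))
  cat(sprintf("  fold difference = %.3g, p = %.4g (%d permutations)\n",
              object@foldDifference, object@p, object@nPermutations))
})

setMethod("show", "RateResult", function(object) {
  cat("Multivariate Brownian rate (sigma^2 mult) by group:\n")
  print(signif(object@rates, 4))
  cat(sprintf("  fold difference = %.3g, p = %.4g (%d simulations)\n",
              object@foldDifference, object@p, object@nSims))
})

setMethod("show", "ModelFitTable", function(object) {
  cat("Evolutionary model comparison for", object@trait, "\n")
  print(object@table, digits = 4)
})

setMethod("show", "ConvergenceResult", function(object) {
  lab <- if (is(object@focal, "FocalRegion")) object@focal@label
         else paste(length(object@focal), "focal taxa")
  cat("Convergence metrics (", lab, "):\n", sep = "")
  print(data.frame(value = signif(object@C, 4), p = signif(object@p, 4)))
  cat("  ", object@nSims, "Brownian-motion simulations\n")
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport (seed", object@seed, ")\n")
  cat(" stages:",
      paste(c("gpa", "pca",
              if (!is.null(object@landscape)) "landscape",
              if (!is.null(object@layout)) "phylomorphospace",
              if (!is.null(object@signal)) "signal",
              if (!is.null(object@disparity)) "disparity",
              if (!is.null(object@rates)) "rates",
              if (length(object@models)) "models",
              if (length(object@convergence)) "convergence"),
            collapse = ", "), "\n")
  if (length(object@droppedTaxa))
    cat(" dropped taxa (absent from tree):",
        paste(object@droppedTaxa, collapse = ", "), "\n")
})
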