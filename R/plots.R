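#' Plot a morphospace scatter
#'
#' @param x a [Morphospace-class].
#' @param y ignored.
#' @param components which two components to draw.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("Morphospace", "missing"),
  function(x, y, components = c(1L, 2L), ...) {
    sc <- x@scores[, components, drop = FALSE]
    vf <- 100 * x@varianceFraction[components]
    graphics::plot(sc, xlab = sprintf("PC%d (%.1f%%)", components[1], vf[1]),
                   ylab = sprintf("PC%d (%.1f%%)", components[2], vf[2]),
                   pch = 19, ...)
    invisible(x)
  })

#' Plot a density landscape with contours
#'
#' @param x a [DensityLandscape-class].
#' @param y ignored.
#' @param ... passed to [graphics::contour()].
#' @export
setMethod("plot", signature("DensityLandscape", "missing"),
  function(x, y, ...) {
    graphics::image(x@x, x@y, x@density, xlab = "PC1", ylab = "PC2",
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE))
    graphics::contour(x@x, x@y, x@density, levels = x@contourLevels,
                      add = TRUE, drawlabels = FALSE, ...)
    invisible(x)
  })

#' Plot a phylomorphospace
#'
#' Tips as large points, squared-change-parsimony ancestors as small
#' points, edges as the inferred evolutionary trajectories.
#'
#' @param x a [PhylomorphospaceLayout-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("PhylomorphospaceLayout", "missing"),
  function(x, y, ...) {
    pts <- rbind(x@tipPoints, x@nodePoints)
    graphics::plot(pts, type = "n", xlab = "PC1", ylab = "PC2", ...)
    graphics::segments(pts[x@edges[, 1], 1], pts[x@edges[, 1], 2],
                       pts[x@edges[, 2], 1], pts[x@edges[, 2], 2],
                       col = "grey60")
    graphics::points(x@nodePoints, pch = 19, cex = 0.5, col = "grey40")
    graphics::points(x@tipPoints, pch = 19, cex = 1)
    invisible(x)
  })
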