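## covariance PCA over a flat variable block; shared by landmark and EFA
## morphospaces. Sign convention: each eigenvector is oriented so that its
## largest-magnitude loading is positive (axis polarity is arbitrary).
pcaCore <- function(mat, taxa, consensus = matrix(0, 0, 2)) {
  n <- nrow(mat)
  if (n < 2L) stop("PCA requires at least 2 configurations")
  ctr <- colMeans(mat)
  xc <- sweep(mat, 2, ctr)
  pr <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  m <- min(n - 1L, ncol(mat))
  rot <- pr$rotation[, seq_len(m), drop = FALSE]
  scores <- pr$x[, seq_len(m), drop = FALSE]
  ev <- pr$sdev[seq_len(m)]^2
  for (j in seq_len(m)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(m))
  rownames(scores) <- taxa
  ## degenerate case: identical configurations have zero total variance
  vf <- if (sum(ev) > 0) ev / sum(ev) else c(1, rep(0, m - 1L))
  new("Morphospace", scores = scores, rotation = rot, eigenvalues = ev,
      varianceFraction = vf, center = ctr, consensus = consensus,
      taxonOrder = taxa)
}

#' Principal-component morphospace of aligned shapes
#'
#' Covariance PCA of the flattened Procrustes-aligned coordinates
#' (\code{x1, y1, ..., xk, yk}). Aligned coordinates are used directly,
#' without a separate tangent-space projection; at the small Procrustes
#' distances typical of a single bone the difference is negligible.
#'
#' @param aligned an [AlignedShapes-class].
#' @return a [Morphospace-class].
#' @export
shapePCA <- function(aligned) {
  stopifnot(is(aligned, "AlignedShapes"))
  pcaCore(flattenShapes(aligned@coords), aligned@taxon,
          consensus = aligned@consensus)
}

#' Cumulative variance explained by leading components
#'
#' @param ms a [Morphospace-class].
#' @param nComponents how many leading components to sum.
#' @return fraction in \code{[0, 1]}.
#' @export
varianceExplained <- function(ms, nComponents) {
  stopifnot(nComponents <= length(ms@varianceFraction))
  sum(ms@varianceFraction[seq_len(nComponents)])
}

#' Model shape along a principal component
#'
#' The consensus displaced by \code{score} times the (reshaped) component
#' eigenvector -- the overlay configurations drawn beside morphospace axes.
#'
#' @param ms a [Morphospace-class] built from landmarks.
#' @param component component index.
#' @param score position along the component.
#' @return \code{k x 2} coordinate matrix.
#' @export
shapeAt <- function(ms, component, score) {
  stopifnot(component <= ncol(ms@rotation), nrow(ms@consensus) > 0)
  ms@consensus + score * unflattenShape(ms@rotation[, component])
}

#' Reconstruct a shape from a full score vector
#'
#' @param ms a [Morphospace-class] built from landmarks.
#' @param scores numeric vector of length m (one value per component).
#' @return \code{k x 2} coordinate matrix.
#' @export
reconstructShape <- function(ms, scores) {
  stopifnot(length(scores) == ncol(ms@rotation), nrow(ms@consensus) > 0)
  ms@consensus + unflattenShape(as.vector(ms@rotation %*% scores))
}

#' Gaussian kernel density landscape over (PC1, PC2)
#'
#' Nonparametric occupancy density of the morphospace: a product-Gaussian
#' kernel estimate on a regular grid spanning the scores plus 3 bandwidths,
#' with default per-axis bandwidth by Silverman's rule. Contour levels are
#' placed at 10 quantiles of the density evaluated at the data points, so
#' the highest contour encloses roughly the densest tenth of the sample.
#'
#' @param scores \code{n x 2} matrix (or a [Morphospace-class], whose first
#'   two score columns are used).
#' @param bandwidth optional numeric length-2 kernel SDs.
#' @param gridResolution grid points per axis (default 200).
#' @return a [DensityLandscape-class].
#' @export
kdeLandscape <- function(scores, bandwidth = NULL, gridResolution = 200L) {
  if (is(scores, "Morphospace")) scores <- scores@scores[, 1:2, drop = FALSE]
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L)
  n <- nrow(scores)
  if (is.null(bandwidth)) {
    if (n < 2L) stop("need n >= 2 for automatic bandwidth; give `bandwidth`")
    bandwidth <- vapply(1:2, function(j) {
      s <- stats::sd(scores[, j])
      iqr <- stats::IQR(scores[, j]) / 1.34
      h <- 0.9 * min(s, if (iqr > 0) iqr else s) * n^(-1 / 5)
      if (!is.finite(h) || h <= 0)
        stop("zero variance in dimension ", j,
             " - supply an explicit `bandwidth`")
      h
    }, numeric(1))
  }
  stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
  gx <- seq(min(scores[, 1]) - 3 * bandwidth[1],
            max(scores[, 1]) + 3 * bandwidth[1], length.out = gridResolution)
  gy <- seq(min(scores[, 2]) - 3 * bandwidth[2],
            max(scores[, 2]) + 3 * bandwidth[2], length.out = gridResolution)
  dx <- stats::dnorm(outer(gx, scores[, 1], "-") / bandwidth[1]) / bandwidth[1]
  dy <- stats::dnorm(outer(gy, scores[, 2], "-") / bandwidth[2]) / bandwidth[2]
  dens <- (dx %*% t(dy)) / n
  atPoints <- vapply(seq_len(n), function(i) {
    mean(stats::dnorm(scores[, 1], scores[i, 1], bandwidth[1]) *
         stats::dnorm(scores[, 2], scores[i, 2], bandwidth[2]))
  }, numeric(1))
  levels <- unname(stats::quantile(atPoints, probs = seq(0.1, 1, by = 0.1)))
  new("DensityLandscape", x = gx, y = gy, density = dens,
      bandwidth = unname(bandwidth), contourLevels = levels)
}

#' Define a focal morphospace region
#'
#' @param center,semiAxes,angle ellipse geometry in the (PC1, PC2) plane;
#'   \code{angle} rotates the first semi-axis counter-clockwise (radians).
#' @param taxa alternatively, an explicit taxon set.
#' @param label display label, e.g. \code{"peak 1"}.
#' @return a [FocalRegion-class].
#' @export
focalRegion <- function(center = NULL, semiAxes = NULL, angle = 0,
                        taxa = NULL, label = "region") {
  if (!is.null(taxa)) {
    new("FocalRegion", type = "taxa", center = numeric(0),
        semiAxes = numeric(0), angle = 0, taxa = as.character(taxa),
        label = label)
  } else {
    new("FocalRegion", type = "ellipse", center = as.numeric(center),
        semiAxes = as.numeric(semiAxes), angle = as.numeric(angle),
        taxa = character(0), label = label)
  }
}

## boundary-inclusive test of (x, y) points against an ellipse region
insideEllipse <- function(pts, region, tol = 1e-12) {
  d <- sweep(pts, 2, region@center)
  ca <- cos(-region@angle); sa <- sin(-region@angle)
  u <- (d[, 1] * ca - d[, 2] * sa) / region@semiAxes[1]
  v <- (d[, 1] * sa + d[, 2] * ca) / region@semiAxes[2]
  u^2 + v^2 <= 1 + tol
}

#' Taxa falling inside a focal region
#'
#' @param scores \code{n x 2} (PC1, PC2) matrix or a [Morphospace-class].
#' @param taxa taxon labels matching the score rows (defaults to the
#'   morphospace taxon order).
#' @param region a [FocalRegion-class]; ellipse membership is boundary
#'   inclusive.
#' @return character vector of member taxa.
#' @export
regionMembers <- function(scores, taxa = NULL, region) {
  if (is(scores, "Morphospace")) {
    if (is.null(taxa)) taxa <- scores@taxonOrder
    scores <- scores@scores[, 1:2, drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (is.null(taxa)) taxa <- rownames(scores)
  if (region@type == "taxa") return(intersect(taxa, region@taxa))
  taxa[insideEllipse(scores, region)]
}
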