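#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the size measure removed by Procrustes scaling.
#'
#' @param config a \code{k x 2} coordinate matrix.
#' @return positive scalar.
#' @examples
#' centroidSize(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)) # sqrt(2)
#' @export
centroidSize <- function(config) {
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2, ctr)^2))
}

## centre at the origin and scale to unit centroid size
centerScale <- function(config, id = "configuration") {
  ctr <- colMeans(config)
  c0 <- sweep(config, 2, ctr)
  cs <- sqrt(sum(c0^2))
  if (cs <= .Machine$double.eps * nrow(config))
    stop("degenerate configuration (zero centroid size): ", id)
  list(coords = c0 / cs, size = cs)
}

## optimal rotation of `mov` onto `ref` (both centred): returns 2x2 matrix R
## such that mov %*% R best matches ref in least squares.
optimalRotation <- function(ref, mov, allowReflection = FALSE) {
  m <- crossprod(mov, ref)
  sv <- svd(m)
  r <- sv$u %*% t(sv$v)
  if (!allowReflection && det(r) < 0) {
    u <- sv$u
    u[, 2] <- -u[, 2]
    r <- u %*% t(sv$v)
  }
  r
}

#' Partial Procrustes distance between two shapes
#'
#' Root summed squared coordinate differences after optimally rotating
#' \code{b} onto \code{a}. Both shapes must already be centred and scaled
#' to unit centroid size.
#'
#' @param a,b \code{k x 2} centred, unit-size coordinate matrices.
#' @param allowReflection logical; permit improper rotations.
#' @return non-negative scalar; 0 iff the shapes are identical up to the
#'   allowed transforms.
#' @export
procrustesDistance <- function(a, b, allowReflection = FALSE) {
  if (!all(dim(a) == dim(b)))
    stop("shapes have mismatched landmark counts: ",
         nrow(a), " vs ", nrow(b))
  r <- optimalRotation(a, b, allowReflection)
  sqrt(sum((a - b %*% r)^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition removing translation, scale and rotation:
#' each configuration is centred, scaled to unit centroid size, and
#' rotated onto the running consensus; the consensus is re-estimated and
#' the loop repeats until its root-mean-square displacement falls below
#' \code{tol} or \code{maxIter} is reached. Configurations labelled
#' \code{side == "left"} are mirrored to the right side before alignment
#' (pairwise shape distances are unaffected), after which reflections are
#' disallowed during fitting unless \code{allowReflection = TRUE}.
#' Semilandmarks are treated as fixed points (no sliding).
#'
#' @param x a [LandmarkSet-class].
#' @param allowReflection logical, allow improper rotations when fitting.
#' @param tol convergence tolerance on consensus RMS displacement.
#' @param maxIter maximum number of iterations.
#' @param reflectLeft logical; mirror left-side configurations first.
#' @return an [AlignedShapes-class].
#' @examples
#' set.seed(1)
#' shp <- matrix(rnorm(36), 18, 2)
#' rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
#' arr <- array(c(shp, 3 * shp %*% rot(0.6) + 5), c(18, 2, 2))
#' aligned <- gpa(landmarkSet(arr))
#' procrustesDistance(landmarkCoords(aligned)[, , 1],
#'                    landmarkCoords(aligned)[, , 2])  # ~0
#' @export
gpa <- function(x, allowReflection = FALSE, tol = 1e-10, maxIter = 100L,
                reflectLeft = TRUE) {
  stopifnot(is(x, "LandmarkSet"))
  n <- nSpecimens(x); k <- nLandmarks(x)
  coords <- x@coords
  if (reflectLeft && any(x@side == "left")) {
    left <- which(x@side == "left")
    coords[, 1, left] <- -coords[, 1, left]
  }
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- centerScale(coords[, , i], x@specimenID[i])
    coords[, , i] <- cs$coords
    sizes[i] <- cs$size
  }
  if (n == 1L) {
    return(new("AlignedShapes", coords = coords,
               specimenID = x@specimenID, taxon = x@taxon, roles = x@roles,
               side = rep("right", n), consensus = coords[, , 1],
               centroidSizes = sizes, iterations = 0L, converged = TRUE))
  }
  consensus <- coords[, , 1]
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      r <- optimalRotation(consensus, coords[, , i], allowReflection)
      coords[, , i] <- coords[, , i] %*% r
    }
    newCons <- apply(coords, c(1, 2), mean)
    newCons <- sweep(newCons, 2, colMeans(newCons))
    newCons <- newCons / sqrt(sum(newCons^2))
    delta <- sqrt(mean((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ## final pass so every configuration is rotated to the final consensus
  for (i in seq_len(n)) {
    r <- optimalRotation(consensus, coords[, , i], allowReflection)
    coords[, , i] <- coords[, , i] %*% r
  }
  consensus <- apply(coords, c(1, 2), mean)
  new("AlignedShapes", coords = coords, specimenID = x@specimenID,
      taxon = x@taxon, roles = x@roles,
      side = if (reflectLeft) rep("right", n) else x@side,
      consensus = consensus, centroidSizes = sizes,
      iterations = iter, converged = converged)
}

#' Average replicate specimens of a single taxon
#'
#' Coordinate-wise mean of configurations that have already been
#' superimposed together (e.g. a subset of an [AlignedShapes-class]).
#'
#' @param x a [LandmarkSet-class] whose specimens all share one taxon.
#' @return a one-specimen [LandmarkSet-class] carrying the taxon name.
#' @export
averageSpecimens <- function(x) {
  tx <- unique(x@taxon)
  if (length(tx) != 1L)
    stop("averageSpecimens() requires a single taxon, got: ",
         paste(tx, collapse = ", "))
  avg <- apply(x@coords, c(1, 2), mean)
  landmarkSet(avg, specimenID = tx, taxon = tx, roles = x@roles)
}

#' Average aligned specimens within each taxon
#'
#' Reduces a superimposed multi-specimen dataset to one mean configuration
#' per taxon (the per-species averaging step preceding taxon-level
#' analyses).
#'
#' @param aligned an [AlignedShapes-class].
#' @return a [LandmarkSet-class] with one configuration per taxon, in the
#'   order of first appearance.
#' @export
averageByTaxon <- function(aligned) {
  tx <- unique(aligned@taxon)
  k <- nLandmarks(aligned)
  coords <- array(0, c(k, 2L, length(tx)))
  for (i in seq_along(tx)) {
    idx <- which(aligned@taxon == tx[i])
    coords[, , i] <- apply(aligned@coords[, , idx, drop = FALSE],
                           c(1, 2), mean)
  }
  landmarkSet(coords, specimenID = tx, taxon = tx, roles = aligned@roles)
}

## flatten k x 2 x n -> n x 2k (x1 y1 x2 y2 ...)
flattenShapes <- function(coords) {
  n <- dim(coords)[3]
  t(vapply(seq_len(n), function(i) as.vector(t(coords[, , i])),
           numeric(dim(coords)[1] * 2L)))
}

## inverse of flattenShapes for a single row
unflattenShape <- function(v) matrix(v, ncol = 2L, byrow = TRUE)
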