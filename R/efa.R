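#' Elliptical-Fourier coefficients
#'
#' @slot coef numeric \code{H x 4} matrix with columns \code{a, b, c, d}.
#' @slot center numeric length-2 outline centroid (the zeroth harmonic).
#' @slot scale numeric, the first-ellipse magnitude removed by
#'   normalization (1 when unnormalized).
#' @slot normalized logical; when TRUE size, orientation, starting-point
#'   phase and traversal direction have been removed (first harmonic in the
#'   canonical form a1 = 1, b1 = 0, c1 = 0, d1 >= 0).
#' @slot taxon character label.
#'
#' @seealso [efa()], [efaReconstruct()], [efaMorphospace()]
#' @export
setClass("EFACoefficients",
  representation(coef = "matrix", center = "numeric", scale = "numeric",
                 normalized = "logical", taxon = "character"))

setMethod("show", "EFACoefficients", function(object) {
  cat("EFACoefficients:", nrow(object@coef), "harmonics",
      if (object@normalized) "(normalized)" else "(raw)", "\n")
})

## closed-polyline segment lengths with wrap-around
outlineSteps <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  d <- nxt - pts
  list(d = d, len = sqrt(rowSums(d^2)))
}

#' Resample a closed outline to equal arc-length spacing
#'
#' @param points \code{q0 x 2} matrix of ordered outline points (closure
#'   implicit: the first point is not repeated).
#' @param q number of output points (default 400).
#' @return \code{q x 2} matrix.
#' @export
resampleOutline <- function(points, q = 400L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3L)
  st <- outlineSteps(points)
  keep <- st$len > 0
  if (!any(keep)) stop("degenerate outline: zero perimeter")
  pts <- points[keep, , drop = FALSE]
  st <- outlineSteps(pts)
  cum <- c(0, cumsum(st$len))
  per <- cum[length(cum)]
  target <- per * (seq_len(q) - 1L) / q
  seg <- findInterval(target, cum, rightmost.closed = TRUE)
  frac <- (target - cum[seg]) / st$len[seg]
  pts[seg, , drop = FALSE] + st$d[seg, , drop = FALSE] * frac
}

## 2x2 rotation used in the first-harmonic normalization
rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Elliptical-Fourier analysis of a closed outline
#'
#' Standard Kuhl-Giardina coefficients of the closed polyline, optionally
#' normalized by the first-harmonic convention: the starting-point phase is
#' rotated so the start lies on the first ellipse's semi-major axis, the
#' coefficient pairs are rotated so that axis lies along x, all harmonics
#' are divided by the semi-major magnitude (removing size), and traversal
#' direction is fixed by requiring d1 >= 0.
#'
#' The traversal parameter advances uniformly per input point
#' (\code{parameter = "uniform"}, the default): outlines resampled to equal
#' arc spacing with [resampleOutline()] are then parameterized by arc
#' length, and a uniformly sampled ellipse reduces exactly to its first
#' harmonic. \code{parameter = "arc"} instead advances by chord length, for
#' outlines with uneven point spacing that cannot be resampled first.
#'
#' @param outline \code{q x 2} matrix of ordered points (first point not
#'   repeated at the end).
#' @param H number of harmonics (default 30); must satisfy \code{H <= q/2}.
#' @param normalize logical, apply the first-harmonic normalization.
#' @param taxon label carried through to morphospaces.
#' @param parameter \code{"uniform"} or \code{"arc"} (see above).
#' @return an [EFACoefficients-class].
#' @export
efa <- function(outline, H = 30L, normalize = TRUE, taxon = "",
                parameter = c("uniform", "arc")) {
  parameter <- match.arg(parameter)
  outline <- as.matrix(outline)
  q <- nrow(outline)
  if (H > q / 2) stop("H must not exceed q/2 (aliasing)")
  st <- outlineSteps(outline)
  keep <- st$len > 0
  dx <- st$d[keep, 1]; dy <- st$d[keep, 2]
  dt <- if (parameter == "arc") st$len[keep] else rep(1, sum(keep))
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  Tper <- t1[length(t1)]
  coef <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(H)) {
    w <- 2 * pi * h / Tper
    cc <- cos(w * t1) - cos(w * t0)
    ss <- sin(w * t1) - sin(w * t0)
    f <- Tper / (2 * pi^2 * h^2)
    coef[h, ] <- f * c(sum(dx / dt * cc), sum(dx / dt * ss),
                       sum(dy / dt * cc), sum(dy / dt * ss))
  }
  center <- colMeans(resampleOutline(outline, max(q, 64L)))
  scale <- 1
  if (normalize) {
    a1 <- coef[1, 1]; b1 <- coef[1, 2]; c1 <- coef[1, 3]; d1 <- coef[1, 4]
    theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                         a1^2 + c1^2 - b1^2 - d1^2)
    for (h in seq_len(H))
      coef[h, ] <- as.vector(matrix(coef[h, ], 2, 2, byrow = TRUE) %*%
                               rot2(h * theta))[c(1, 3, 2, 4)]
    psi <- atan2(coef[1, 3], coef[1, 1])
    rpsi <- rot2(-psi)
    for (h in seq_len(H)) {
      m <- rpsi %*% matrix(coef[h, ], 2, 2, byrow = TRUE)
      coef[h, ] <- c(m[1, ], m[2, ])
    }
    scale <- coef[1, 1]
    coef <- coef / scale
    if (coef[1, 4] < 0) {           # fix traversal direction
      coef[, 2] <- -coef[, 2]
      coef[, 4] <- -coef[, 4]
    }
  }
  new("EFACoefficients", coef = coef, center = center, scale = scale,
      normalized = normalize, taxon = taxon)
}

#' Reconstruct an outline from elliptical-Fourier coefficients
#'
#' @param ef an [EFACoefficients-class].
#' @param q number of points to evaluate.
#' @param H number of leading harmonics to use (default all).
#' @return \code{q x 2} matrix.
#' @export
efaReconstruct <- function(ef, q = 400L, H = nrow(ef@coef)) {
  stopifnot(H <= nrow(ef@coef))
  t <- seq(0, 1, length.out = q + 1L)[-(q + 1L)]
  x <- rep(if (ef@normalized) 0 else ef@center[1], q)
  y <- rep(if (ef@normalized) 0 else ef@center[2], q)
  for (h in seq_len(H)) {
    cw <- cos(2 * pi * h * t); sw <- sin(2 * pi * h * t)
    x <- x + ef@coef[h, 1] * cw + ef@coef[h, 2] * sw
    y <- y + ef@coef[h, 3] * cw + ef@coef[h, 4] * sw
  }
  cbind(x, y)
}

#' Morphospace of elliptical-Fourier coefficients
#'
#' Covariance PCA over the flattened normalized coefficient blocks; the
#' outline-based cross-check of the landmark morphospace.
#'
#' @param efs list of [EFACoefficients-class] with equal harmonic counts.
#' @return a [Morphospace-class] (no landmark consensus attached).
#' @export
efaMorphospace <- function(efs) {
  stopifnot(length(efs) >= 2L)
  Hs <- vapply(efs, function(e) nrow(e@coef), integer(1))
  if (length(unique(Hs)) != 1L) stop("harmonic counts differ across taxa")
  mat <- t(vapply(efs, function(e) as.vector(t(e@coef)),
                  numeric(4L * Hs[1])))
  taxa <- vapply(efs, function(e) e@taxon, character(1))
  if (any(taxa == "")) taxa <- paste0("outline", seq_along(efs))
  pcaCore(mat, taxa)
}

#' Read outlines from CSV
#'
#' Long format with columns \code{taxon, x, y}; rows of one taxon are the
#' ordered outline points.
#'
#' @param path CSV path.
#' @return named list of \code{q x 2} matrices.
#' @export
readOutlineCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "x", "y") %in% names(df)))
  lapply(split(df[, c("x", "y")], factor(df$taxon, unique(df$taxon))),
         as.matrix)
}

#' @rdname readOutlineCSV
#' @param outlines named list of \code{q x 2} matrices.
#' @export
writeOutlineCSV <- function(outlines, path) {
  df <- do.call(rbind, lapply(names(outlines), function(tx)
    data.frame(taxon = tx, x = outlines[[tx]][, 1], y = outlines[[tx]][, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
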