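## Independent oracles and small fixtures shared across test files.
## These deliberately re-derive quantities from first principles rather
## than calling the package's own implementation paths.

rotMat <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

## brute-force partial Procrustes distance: grid search over the rotation
## angle (and optionally reflection) on a 0.001-rad grid
gridProcrustesDistance <- function(a, b, allowReflection = FALSE,
                                   step = 0.001) {
  angles <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (ang in angles) {
    d <- sum((a - b %*% rotMat(ang))^2)
    if (d < best) best <- d
    if (allowReflection) {
      br <- b %*% diag(c(-1, 1))
      d <- sum((a - br %*% rotMat(ang))^2)
      if (d < best) best <- d
    }
  }
  sqrt(best)
}

## Blomberg's K, coded directly from the definition (univariate)
blombergK <- function(x, tree) {
  C <- ape::vcv(tree)[names(x), names(x)]
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Cinv %*% x) / (t(one) %*% Cinv %*% one))
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

## weighted squared-change objective, evaluated from the edge list
scpObjective <- function(tree, tipValues, nodeValues) {
  n <- length(tree$tip.label)
  states <- c(tipValues[tree$tip.label], nodeValues)
  sum((states[tree$edge[, 1]] - states[tree$edge[, 2]])^2 /
        tree$edge.length)
}

## deterministic BM tip data on a tree through the phylo covariance
simBMTips <- function(tree, sigma2 = 1, p = 1) {
  C <- ape::vcv(tree)
  U <- chol(C)
  x <- t(U) %*% matrix(rnorm(nrow(C) * p), nrow(C), p) * sqrt(sigma2)
  rownames(x) <- rownames(C)
  x
}

balancedTree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

## two disjoint small clades whose most recent common ancestors are as far
## apart as possible: the "two distant clades" of the convergent scenarios
pickDistantClades <- function(tree, minSize = 3, maxSize = 6) {
  subs <- ape::subtrees(tree)
  sizes <- vapply(subs, function(s) length(s$tip.label), integer(1))
  keep <- sizes >= minSize & sizes <= maxSize
  if (sum(keep) < 2) return(NULL)
  sets <- lapply(subs[keep], function(s) s$tip.label)
  mrcas <- vapply(sets, function(s) ape::getMRCA(tree, s), integer(1))
  dn <- ape::dist.nodes(tree)
  best <- NULL; bestD <- -1
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j && !length(intersect(sets[[i]], sets[[j]])) &&
        dn[mrcas[i], mrcas[j]] > bestD) {
      bestD <- dn[mrcas[i], mrcas[j]]
      best <- c(i, j)
    }
  }
  if (is.null(best)) return(NULL)
  list(sets[[best[1]]], sets[[best[2]]])
}

## a fixed 5-tip phylomorphospace layout used for the C5 counting cases:
## root 6 -> {7, E}; 7 -> {8, 9}; 8 -> {A, B}; 9 -> {C, D}
c5Layout <- function(tipXY, nodeXY) {
  edges <- cbind(c(6L, 6L, 7L, 7L, 8L, 8L, 9L, 9L),
                 c(7L, 5L, 8L, 9L, 1L, 2L, 3L, 4L))
  new("PhylomorphospaceLayout",
      tipPoints = matrix(tipXY, 5, 2, byrow = TRUE,
                         dimnames = list(c("A", "B", "C", "D", "E"), NULL)),
      nodePoints = matrix(nodeXY, 4, 2, byrow = TRUE),
      edges = edges)
}

## aligned-shapes container built directly from a flat score block: the
## first landmark carries the signal, the remaining two pin the triangle
fakeAligned <- function(xy) {
  n <- nrow(xy)
  coords <- array(0, c(3, 2, n))
  for (i in seq_len(n)) {
    coords[1, , i] <- xy[i, ]
    coords[2, , i] <- c(1, 0)
    coords[3, , i] <- c(0, 1)
  }
  new("AlignedShapes", coords = coords,
      specimenID = paste0("s", seq_len(n)),
      taxon = paste0("s", seq_len(n)),
      roles = rep("fixed", 3), side = rep("unknown", n),
      consensus = apply(coords, c(1, 2), mean),
      centroidSizes = rep(1, n), iterations = 1L, converged = TRUE)
}
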