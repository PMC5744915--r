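## parent lookup: parent[i] is the parent node of node i (0 for the root)
parentVector <- function(tree) {
  np <- length(tree$tip.label) + tree$Nnode
  par <- integer(np)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

## node path from a tip back to (and including) an ancestor node
pathToAncestor <- function(par, tip, anc) {
  path <- tip
  nd <- tip
  while (nd != anc) {
    nd <- par[nd]
    if (nd == 0L) stop("ancestor not on path to root")
    path <- c(path, nd)
  }
  path
}

## precompute, per focal pair, the lineage paths and clade edge set so the
## C1-C4 metrics can be re-evaluated cheaply on simulated states
convergencePrep <- function(tree, focalTaxa) {
  n <- length(tree$tip.label)
  tipIdx <- match(focalTaxa, tree$tip.label)
  if (any(is.na(tipIdx)))
    stop("focal taxa absent from tree: ",
         paste(focalTaxa[is.na(tipIdx)], collapse = ", "))
  par <- parentVector(tree)
  pairs <- utils::combn(tipIdx, 2)
  prep <- lapply(seq_len(ncol(pairs)), function(j) {
    t1 <- pairs[1, j]; t2 <- pairs[2, j]
    mrca <- ape::getMRCA(tree, c(t1, t2))
    p1 <- pathToAncestor(par, t1, mrca)
    p2 <- pathToAncestor(par, t2, mrca)
    ## edges within the clade descending from the mrca
    desc <- mrca
    repeat {
      kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
      newDesc <- union(desc, kids)
      if (length(newDesc) == length(desc)) break
      desc <- newDesc
    }
    cladeEdges <- tree$edge[tree$edge[, 1] %in% desc, , drop = FALSE]
    list(t1 = t1, t2 = t2, p1 = p1, p2 = p2, cladeEdges = cladeEdges)
  })
  prep
}

## evaluate C1-C4 for one pair given the full (tips + nodes) state matrix
cPairFromStates <- function(pp, states) {
  dtip <- sqrt(sum((states[pp$t1, ] - states[pp$t2, ])^2))
  s1 <- states[pp$p1, , drop = FALSE]
  s2 <- states[pp$p2, , drop = FALSE]
  cross <- outer(rowSums(s1^2), rowSums(s2^2), "+") -
    2 * s1 %*% t(s2)
  dmax <- sqrt(max(pmax(cross, 0)))
  if (dmax <= 0) return(c(C1 = 0, C2 = 0, C3 = 0, C4 = 0))
  c2 <- dmax - dtip
  lineEvol <- function(p) sum(sqrt(rowSums(
    (states[p[-length(p)], , drop = FALSE] -
     states[p[-1], , drop = FALSE])^2)))
  tot12 <- lineEvol(pp$p1) + lineEvol(pp$p2)
  totClade <- sum(sqrt(rowSums(
    (states[pp$cladeEdges[, 1], , drop = FALSE] -
     states[pp$cladeEdges[, 2], , drop = FALSE])^2)))
  c(C1 = 1 - dtip / dmax, C2 = c2,
    C3 = if (tot12 > 0) c2 / tot12 else 0,
    C4 = if (totClade > 0) c2 / totClade else 0)
}

cMetricsFromStates <- function(prep, states, aggregate = "mean") {
  vals <- vapply(prep, cPairFromStates, numeric(4), states = states)
  agg <- switch(aggregate,
                mean = rowMeans(vals),
                min = apply(vals, 1, min),
                max = apply(vals, 1, max),
                stop("aggregate must be mean, min or max"))
  agg
}

#' Similarity-based convergence metrics C1-C4
#'
#' For each focal pair, let Dtip be the morphospace distance between the
#' two tips and Dmax the maximum distance between any two states -- tips or
#' squared-change-parsimony ancestors, one from each lineage traced back to
#' the common ancestor. Then C1 = 1 - Dtip/Dmax (the fraction of the
#' maximum past dissimilarity closed by subsequent evolution),
#' C2 = Dmax - Dtip (the same in morphospace distance units),
#' C3 = C2 / (total evolution along both lineages) and
#' C4 = C2 / (total evolution in the clade descending from the common
#' ancestor). Multi-taxon focal sets aggregate pairwise values by
#' \code{aggregate} (mean by default).
#'
#' @param tree a \code{phylo}.
#' @param scores matrix of tip positions (taxon rownames; typically the
#'   PC1-PC2 scores) or a [Morphospace-class].
#' @param focalTaxa character, at least two taxa.
#' @param aggregate \code{"mean"}, \code{"min"} or \code{"max"}.
#' @param weighted logical, SCP weighting for the ancestors.
#' @return named numeric vector \code{c(C1, C2, C3, C4)}.
#' @export
cSimilarity <- function(tree, scores, focalTaxa, aggregate = "mean",
                        weighted = TRUE) {
  if (is(scores, "Morphospace")) {
    s <- scores@scores[, 1:2, drop = FALSE]
    rownames(s) <- scores@taxonOrder
    scores <- s
  }
  scores <- as.matrix(scores)
  if (length(focalTaxa) < 2L) stop("need at least two focal taxa")
  missing <- setdiff(focalTaxa, rownames(scores))
  if (length(missing))
    stop("focal taxa absent from scores: ", paste(missing, collapse = ", "))
  tips <- matchToTree(scores, tree)
  anc <- ancestralSCP(tree, tips, weighted = weighted)
  states <- rbind(tips, anc)
  prep <- convergencePrep(tree, focalTaxa)
  cMetricsFromStates(prep, states, aggregate)
}

#' Frequency-based convergence count C5
#'
#' The number of independent entries into a morphospace region: edges of
#' the phylomorphospace whose parent point lies outside the region and
#' whose child point lies inside. An edge passing fully through the region
#' (both endpoints outside) is not counted, so coarse trees can miss brief
#' transits. \code{count = "lineages"} instead counts entering edges whose
#' descendant subtree still has at least one tip inside the region.
#'
#' @param layout a [PhylomorphospaceLayout-class].
#' @param region an ellipse [FocalRegion-class] in the same (PC1, PC2)
#'   plane.
#' @param count \code{"edges"} (default) or \code{"lineages"}.
#' @return non-negative integer.
#' @export
c5Count <- function(layout, region, count = c("edges", "lineages")) {
  count <- match.arg(count)
  if (region@type != "ellipse")
    stop("C5 requires an ellipse region")
  pts <- rbind(layout@tipPoints, layout@nodePoints)
  inside <- insideEllipse(pts, region)
  entering <- !inside[layout@edges[, 1]] & inside[layout@edges[, 2]]
  if (count == "edges") return(sum(entering))
  n <- nrow(layout@tipPoints)
  kids <- split(layout@edges[, 2], layout@edges[, 1])
  hasInsideTip <- function(nd) {
    stack <- nd; found <- FALSE
    while (length(stack) && !found) {
      v <- stack[1]; stack <- stack[-1]
      if (v <= n) {
        if (inside[v]) found <- TRUE
      } else {
        stack <- c(stack, kids[[as.character(v)]])
      }
    }
    found
  }
  sum(vapply(layout@edges[entering, 2], hasInsideTip, logical(1)))
}

#' Simulation test of phenotypic convergence
#'
#' Computes C1-C4 for the focal taxa (and C5 when an ellipse region is
#' given, whose members then define the focal set unless \code{focalTaxa}
#' is supplied) and compares each against \code{nSims} Brownian-motion
#' simulations on the tree. The null rate is the per-axis maximum
#' likelihood Brownian rate of the observed scores with zero trait
#' correlation, rooted at the GLS estimate; each simulated dataset is
#' re-scored with freshly reconstructed ancestors (for region tests, C5 is
#' re-evaluated against the fixed region). Convergence p-values use the
#' bare count / nSims convention, so p = 0 means no simulation reached the
#' empirical value.
#'
#' @param tree a \code{phylo}.
#' @param scores tip (PC1, PC2) matrix with taxon rownames, or a
#'   [Morphospace-class].
#' @param focal a character vector of focal taxa, or an ellipse
#'   [FocalRegion-class].
#' @param nSims number of Brownian simulations (default 1000).
#' @param seed optional integer seed.
#' @param aggregate pairwise aggregation for C1-C4.
#' @param weighted logical, SCP weighting.
#' @return a [ConvergenceResult-class].
#' @export
convergenceTest <- function(tree, scores, focal, nSims = 1000L, seed = NULL,
                            aggregate = "mean", weighted = TRUE) {
  if (nSims < 100L) warning("fewer than 100 simulations: p-values are coarse")
  if (is(scores, "Morphospace")) {
    s <- scores@scores[, 1:2, drop = FALSE]
    rownames(s) <- scores@taxonOrder
    scores <- s
  }
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  region <- NULL
  if (is(focal, "FocalRegion")) {
    region <- focal
    focalTaxa <- regionMembers(scores, rownames(scores), region)
    if (length(focalTaxa) < 2L)
      stop("region contains fewer than two focal taxa")
  } else {
    focalTaxa <- as.character(focal)
  }
  tips <- matchToTree(scores, tree)
  n <- nrow(tips)
  op <- scpOperator(tree, weighted = weighted)
  prep <- convergencePrep(tree, focalTaxa)
  ancObs <- op %*% tips
  statesObs <- rbind(tips, ancObs)
  obs <- cMetricsFromStates(prep, statesObs, aggregate)
  edges <- tree$edge
  if (!is.null(region)) {
    layoutObs <- new("PhylomorphospaceLayout", tipPoints = tips,
                     nodePoints = ancObs, edges = edges)
    obs <- c(obs, C5 = c5Count(layoutObs, region))
  }
  ## per-axis ML Brownian rate and GLS root of the observed scores
  C <- phyloCovariance(tree)[rownames(tips), rownames(tips)]
  U <- chol(C)
  tU <- t(U)
  fits <- apply(tips, 2, function(x) unlist(glsProfile(x, C)[c("sig2", "z0")]))
  if (!is.null(seed)) set.seed(seed)
  count <- stats::setNames(numeric(length(obs)), names(obs))
  for (i in seq_len(nSims)) {
    sim <- tU %*% matrix(stats::rnorm(n * 2), n, 2)
    sim <- sweep(sim, 2, sqrt(fits["sig2", ]), "*")
    sim <- sweep(sim, 2, fits["z0", ], "+")
    rownames(sim) <- rownames(tips)
    ancSim <- op %*% sim
    statesSim <- rbind(sim, ancSim)
    v <- cMetricsFromStates(prep, statesSim, aggregate)
    if (!is.null(region)) {
      insideSim <- insideEllipse(rbind(sim, ancSim), region)
      v <- c(v, C5 = sum(!insideSim[edges[, 1]] & insideSim[edges[, 2]]))
    }
    count <- count + (v >= obs)
  }
  res <- new("ConvergenceResult",
             focal = if (is.null(region)) focalTaxa else region,
             p = count / nSims, nSims = as.integer(nSims),
             seed = as.integer(if (is.null(seed)) NA else seed))
  res@C <- obs   # slot name 'C' would partially match new()'s Class argument
  res
}
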