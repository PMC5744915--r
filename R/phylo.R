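#' Read and prune time trees
#'
#' Thin wrappers around \pkg{ape}: \code{readNewick} reads a rooted tree
#' with branch lengths; \code{pruneTo} drops all tips outside \code{taxa},
#' collapsing unbranched internal nodes (root-to-tip path lengths of the
#' retained tips are preserved).
#'
#' @param path Newick file path.
#' @return an \pkg{ape} \code{phylo}.
#' @export
readNewick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  tree
}

#' @rdname readNewick
#' @param tree a \code{phylo}.
#' @param taxa tips to retain; must all be present in the tree.
#' @export
pruneTo <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, taxa)
}

#' Phylogenetic covariance matrix
#'
#' Shared root-to-MRCA path depths between tips, the Brownian-motion trait
#' covariance (up to the rate). Diagonal entries are root-to-tip depths.
#'
#' @param tree a \code{phylo}.
#' @return symmetric PSD matrix with tip labels as dimnames.
#' @export
phyloCovariance <- function(tree) ape::vcv(tree)

## replace zero-length branches by a small epsilon relative to tree depth
guardBranchLengths <- function(tree) {
  depth <- max(ape::node.depth.edgelength(tree))
  zero <- tree$edge.length <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-length branch(es) replaced by 1e-8 x depth")
    tree$edge.length[zero] <- 1e-8 * depth
  }
  tree
}

#' Linear operator mapping tip values to squared-change-parsimony ancestors
#'
#' Squared-change parsimony minimizes the sum over edges of
#' (state change)^2 / branch length (the Brownian-motion-consistent,
#' branch-length-weighted variant; \code{weighted = FALSE} gives the
#' unweighted form). The minimizer is linear in the tip values, so the
#' internal-node states are \code{M \%*\% tipValues} with \code{M} the
#' matrix returned here (rows ordered as ape internal nodes
#' \code{n+1 .. n+nnode}, columns as \code{tree$tip.label}).
#'
#' @param tree a \code{phylo}.
#' @param weighted logical, divide squared changes by branch length.
#' @return \code{nnode x ntip} matrix.
#' @export
scpOperator <- function(tree, weighted = TRUE) {
  tree <- guardBranchLengths(tree)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  w <- if (weighted) 1 / tree$edge.length else rep(1, nrow(tree$edge))
  a <- matrix(0, nn, nn)
  b <- matrix(0, nn, n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - n
    ch <- tree$edge[e, 2]
    a[p, p] <- a[p, p] + w[e]
    if (ch <= n) {
      b[p, ch] <- b[p, ch] + w[e]
    } else {
      ci <- ch - n
      a[ci, ci] <- a[ci, ci] + w[e]
      a[p, ci] <- a[p, ci] - w[e]
      a[ci, p] <- a[ci, p] - w[e]
    }
  }
  m <- solve(a, b)
  rownames(m) <- as.character(n + seq_len(nn))
  colnames(m) <- tree$tip.label
  m
}

#' Squared-change-parsimony ancestral states
#'
#' Internal-node trait values minimizing the (branch-length-weighted) sum
#' of squared changes along edges, solved exactly as a linear system; each
#' trait dimension is independent.
#'
#' @param tree a \code{phylo}.
#' @param tipValues named numeric vector, or a matrix with one row per
#'   taxon (rownames) and one column per trait.
#' @param weighted logical, see [scpOperator()].
#' @return matrix of internal-node states, \code{nnode x ntraits}, rows
#'   named by ape node number.
#' @export
ancestralSCP <- function(tree, tipValues, weighted = TRUE) {
  if (is.vector(tipValues))
    tipValues <- matrix(tipValues, ncol = 1,
                        dimnames = list(names(tipValues), "trait"))
  missing <- setdiff(tree$tip.label, rownames(tipValues))
  if (length(missing))
    stop("missing tip values for: ", paste(missing, collapse = ", "))
  m <- scpOperator(tree, weighted)
  anc <- m %*% tipValues[tree$tip.label, , drop = FALSE]
  colnames(anc) <- colnames(tipValues)
  anc
}

#' Phylomorphospace layout
#'
#' Tip points are the empirical (PC1, PC2) scores; internal-node points are
#' squared-change-parsimony reconstructions of those scores; edges follow
#' the tree topology.
#'
#' @param tree a \code{phylo} whose tips are all present in the scores.
#' @param ms a [Morphospace-class], or an \code{n x 2} score matrix with
#'   taxon rownames.
#' @param weighted logical, SCP weighting (see [scpOperator()]).
#' @return a [PhylomorphospaceLayout-class].
#' @export
phylomorphospace <- function(tree, ms, weighted = TRUE) {
  scores <- if (is(ms, "Morphospace")) {
    s <- ms@scores[, seq_len(min(2L, ncol(ms@scores))), drop = FALSE]
    if (ncol(s) == 1L) s <- cbind(s, 0)
    rownames(s) <- ms@taxonOrder
    s
  } else as.matrix(ms)
  missing <- setdiff(tree$tip.label, rownames(scores))
  if (length(missing))
    stop("tree tips missing from scores: ", paste(missing, collapse = ", "))
  tips <- scores[tree$tip.label, 1:2, drop = FALSE]
  nodes <- ancestralSCP(tree, tips, weighted = weighted)
  colnames(tips) <- colnames(nodes) <- c("PC1", "PC2")
  new("PhylomorphospaceLayout", tipPoints = tips, nodePoints = nodes,
      edges = tree$edge)
}

#' Write a phylomorphospace layout as CSV
#'
#' @param layout a [PhylomorphospaceLayout-class].
#' @param pointsPath,edgesPath output CSV paths (points: id, type, PC1,
#'   PC2; edges: parent, child point ids).
#' @return invisibly, \code{pointsPath}.
#' @export
writeLayoutCSV <- function(layout, pointsPath, edgesPath) {
  n <- nrow(layout@tipPoints)
  pts <- data.frame(
    id = c(seq_len(n), n + seq_len(nrow(layout@nodePoints))),
    label = c(rownames(layout@tipPoints), rownames(layout@nodePoints)),
    type = rep(c("tip", "node"), c(n, nrow(layout@nodePoints))),
    PC1 = c(layout@tipPoints[, 1], layout@nodePoints[, 1]),
    PC2 = c(layout@tipPoints[, 2], layout@nodePoints[, 2]))
  utils::write.csv(pts, pointsPath, row.names = FALSE)
  utils::write.csv(data.frame(parent = layout@edges[, 1],
                              child = layout@edges[, 2]),
                   edgesPath, row.names = FALSE)
  invisible(pointsPath)
}

#' Simulate Brownian motion on a tree
#'
#' Each edge adds a Gaussian increment with covariance
#' \code{rate x branch length}; traits may be correlated through a full
#' rate matrix. Reproducible under a fixed seed.
#'
#' @param tree a \code{phylo}.
#' @param rate scalar, per-trait variance vector, or full \code{p x p}
#'   symmetric PSD rate matrix (variance per unit branch length).
#' @param rootState numeric length-p root value (default 0).
#' @param nSims number of replicate simulations.
#' @param seed optional integer seed.
#' @param internal logical, also return internal-node states.
#' @return a list with \code{tips}: \code{ntip x p x nSims} array (tip
#'   labels as rownames) and, if requested, \code{nodes}:
#'   \code{nnode x p x nSims}.
#' @export
bmSimulate <- function(tree, rate, rootState = NULL, nSims = 1L,
                       seed = NULL, internal = FALSE) {
  if (!is.matrix(rate)) rate <- diag(as.numeric(rate),
                                     nrow = length(as.numeric(rate)))
  if (any(abs(rate - t(rate)) > 1e-12))
    stop("rate matrix must be symmetric")
  ev <- eigen(rate, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1))
    stop("rate matrix must be positive semi-definite")
  p <- nrow(rate)
  if (is.null(rootState)) rootState <- rep(0, p)
  stopifnot(length(rootState) == p)
  if (!is.null(seed)) set.seed(seed)
  cl <- tryCatch(chol(rate), error = function(e) {
    es <- eigen(rate, symmetric = TRUE)
    t(es$vectors %*% diag(sqrt(pmax(es$values, 0)), p) %*% t(es$vectors))
  })
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  nNodes <- n + tree$Nnode
  states <- array(0, c(nNodes, p, nSims))
  root <- n + 1L
  for (j in seq_len(p)) states[root, j, ] <- rootState[j]
  edgeOrder <- rev(seq_len(nrow(tree$edge)))  # parents before children
  for (e in edgeOrder) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    z <- matrix(stats::rnorm(p * nSims), p, nSims)
    inc <- sqrt(tree$edge.length[e]) * crossprod(cl, z)
    states[ch, , ] <- array(states[par, , , drop = FALSE], c(p, nSims)) + inc
  }
  tips <- states[seq_len(n), , , drop = FALSE]
  dimnames(tips)[[1]] <- tree$tip.label
  out <- list(tips = tips)
  if (internal) out$nodes <- states[(n + 1L):nNodes, , , drop = FALSE]
  out
}
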