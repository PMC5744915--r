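#' Simulation scenario for synthetic opercle-like datasets
#'
#' Bundles every knob of the generator. The defaults mirror the scale of a
#' family-level survey of a large fish clade: 100 taxa on a pure-birth time
#' tree with expected crown depth about 250 My (birth rate 0.0167 / My),
#' two independent shape-deformation axes evolving by Brownian motion at
#' 1e-4 variance per My (tip deformation SD about 0.16 on a unit-centroid-
#' size template), small within-species replicate noise, and one replicate
#' per species.
#'
#' @param nTaxa number of tips.
#' @param birthRate pure-birth speciation rate per My.
#' @param shapeModel \code{"BM"}, \code{"OU_single"} or
#'   \code{"OU_convergent"}.
#' @param rate per-axis trait variance per My.
#' @param ouAlpha OU attraction strength per My (OU models).
#' @param regimes for \code{"OU_convergent"}: list of lists with elements
#'   \code{taxa} (tip labels) and \code{optimum} (numeric, one value per
#'   deformation axis); all other branches are attracted to the origin.
#' @param deformationDims number of independent deformation axes (<= 2k-4).
#' @param noiseSd within-species replicate landmark noise SD.
#' @param replicatesPerSpecies specimens generated per species.
#' @param seed optional integer seed.
#' @return a list with class \code{"SimulationScenario"}.
#' @export
simulationScenario <- function(nTaxa = 100L, birthRate = 0.0167,
                               shapeModel = c("BM", "OU_single",
                                              "OU_convergent"),
                               rate = 1e-4, ouAlpha = 0.01, regimes = NULL,
                               deformationDims = 2L, noiseSd = 0.005,
                               replicatesPerSpecies = 1L, seed = NULL) {
  shapeModel <- match.arg(shapeModel)
  stopifnot(nTaxa >= 2L, birthRate > 0, rate >= 0, noiseSd >= 0,
            deformationDims >= 1L, deformationDims <= 2L * 18L - 4L,
            replicatesPerSpecies >= 1L)
  if (!is.null(regimes) && shapeModel != "OU_convergent")
    stop("regimes are only meaningful with shapeModel = 'OU_convergent'")
  structure(list(nTaxa = as.integer(nTaxa), birthRate = birthRate,
                 shapeModel = shapeModel, rate = rate, ouAlpha = ouAlpha,
                 regimes = regimes,
                 deformationDims = as.integer(deformationDims),
                 noiseSd = noiseSd,
                 replicatesPerSpecies = as.integer(replicatesPerSpecies),
                 seed = seed),
            class = "SimulationScenario")
}

#' Simulate a pure-birth (Yule) time tree
#'
#' Lineages split at rate \code{birthRate} per lineage, starting from two
#' crown lineages; after the n-th lineage appears the process runs for one
#' further full exponential waiting time, so the expected crown depth is
#' \code{sum(1 / (birthRate * 2:n))}. The result is ultrametric with tips
#' labelled \code{t1..tn}.
#'
#' @param nTaxa number of tips (>= 2).
#' @param birthRate speciation rate per unit time.
#' @param seed optional integer seed.
#' @return an \pkg{ape} \code{phylo}.
#' @export
simulateTree <- function(nTaxa, birthRate, seed = NULL) {
  stopifnot(nTaxa >= 2L, birthRate > 0)
  if (!is.null(seed)) set.seed(seed)
  maxNodes <- 2L * nTaxa
  btime <- numeric(maxNodes)     # time the lineage started
  stime <- rep(NA_real_, maxNodes)  # time it split (NA = tip)
  kid1 <- integer(maxNodes); kid2 <- integer(maxNodes)
  nNodes <- 2L
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < nTaxa) {
    t <- t + stats::rexp(1, birthRate * length(active))
    i <- active[sample.int(length(active), 1L)]
    stime[i] <- t
    kid1[i] <- nNodes + 1L; kid2[i] <- nNodes + 2L
    btime[nNodes + 1L] <- btime[nNodes + 2L] <- t
    nNodes <- nNodes + 2L
    active <- c(active[active != i], kid1[i], kid2[i])
  }
  tEnd <- t + stats::rexp(1, birthRate * nTaxa)
  tipCounter <- 0L
  newick <- function(i) {
    if (is.na(stime[i])) {
      tipCounter <<- tipCounter + 1L
      sprintf("t%d:%.12g", tipCounter, tEnd - btime[i])
    } else {
      sprintf("(%s,%s):%.12g", newick(kid1[i]), newick(kid2[i]),
              stime[i] - btime[i])
    }
  }
  ## root joins crown lineages 1 and 2 at time 0
  str <- sprintf("(%s,%s);", newick(1L), newick(2L))
  ape::read.tree(text = str)
}

#' Template opercle configuration
#'
#' A fixed 18-point configuration on a smooth convex fan-shaped outline
#' (a perturbed polar curve, hence simple by construction), with the
#' 4-fixed + 14-semilandmark role scheme of [opercleRoles()], centred at
#' the origin and scaled to centroid size 1.
#'
#' @return a one-specimen [LandmarkSet-class].
#' @export
templateOpercle <- function() {
  phi <- 2 * pi * (0:17) / 18
  r <- 1 + 0.18 * cos(phi - 0.4) + 0.1 * sin(2 * phi)
  pts <- cbind(r * cos(phi), r * sin(phi))
  cs <- centerScale(pts, "template")
  landmarkSet(cs$coords, specimenID = "template", taxon = "template",
              roles = opercleRoles())
}

#' Orthonormal smooth deformation basis
#'
#' Low-order trigonometric radial displacement fields of the template's
#' edge points, orthonormalized (QR) as flattened 2k-vectors so latent
#' traits map near-linearly to Procrustes/PC space.
#'
#' @param template \code{k x 2} template coordinates.
#' @param dims number of basis fields.
#' @return \code{2k x dims} orthonormal matrix (columns are flattened
#'   \code{x1 y1 x2 y2 ...} displacement fields).
#' @export
deformationBasis <- function(template, dims = 2L) {
  k <- nrow(template)
  stopifnot(dims <= 2L * k - 4L)
  ctr <- colMeans(template)
  dirs <- sweep(template, 2, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phi <- 2 * pi * (seq_len(k) - 1L) / k
  fields <- list()
  m <- 2L
  while (length(fields) < dims) {
    for (fun in list(cos, sin)) {
      u <- fun(m * phi)
      fields[[length(fields) + 1L]] <- as.vector(t(dirs * u))
      if (length(fields) >= dims) break
    }
    m <- m + 1L
  }
  b <- qr.Q(qr(do.call(cbind, fields)))[, seq_len(dims), drop = FALSE]
  ## deterministic sign: largest-magnitude entry positive
  for (j in seq_len(dims)) {
    i <- which.max(abs(b[, j]))
    if (b[i, j] < 0) b[, j] <- -b[, j]
  }
  b
}

## simulate OU (or BM when alpha = 0) latent traits edge-by-edge; regimes
## paint an edge when every tip descending from it belongs to one regime set
simulateLatentTraits <- function(tree, scenario) {
  p <- scenario$deformationDims
  n <- length(tree$tip.label)
  nNodes <- n + tree$Nnode
  alpha <- switch(scenario$shapeModel, BM = 0, scenario$ouAlpha)
  ## per-edge optima
  opt <- matrix(0, nrow(tree$edge), p)
  if (!is.null(scenario$regimes)) {
    tipsBelow <- vector("list", nNodes)
    tree2 <- stats::reorder(tree, "postorder")
    for (e in seq_len(nrow(tree2$edge))) {
      ch <- tree2$edge[e, 2]
      if (ch <= n) tipsBelow[[ch]] <- tree$tip.label[ch]
    }
    for (e in seq_len(nrow(tree2$edge))) {
      par <- tree2$edge[e, 1]; ch <- tree2$edge[e, 2]
      tipsBelow[[par]] <- c(tipsBelow[[par]], tipsBelow[[ch]])
    }
    for (rg in scenario$regimes) {
      stopifnot(length(rg$optimum) == p)
      for (e in seq_len(nrow(tree$edge))) {
        below <- tipsBelow[[tree$edge[e, 2]]]
        if (length(below) && all(below %in% rg$taxa))
          opt[e, ] <- rg$optimum
      }
    }
  }
  tree2 <- stats::reorder(tree, "postorder")
  optPost <- opt[match(paste(tree2$edge[, 1], tree2$edge[, 2]),
                       paste(tree$edge[, 1], tree$edge[, 2])), , drop = FALSE]
  states <- matrix(0, nNodes, p)
  for (e in rev(seq_len(nrow(tree2$edge)))) {
    par <- tree2$edge[e, 1]; ch <- tree2$edge[e, 2]
    len <- tree2$edge.length[e]
    th <- optPost[e, ]
    if (alpha > 0) {
      damp <- exp(-alpha * len)
      v <- scenario$rate * (1 - exp(-2 * alpha * len)) / (2 * alpha)
      states[ch, ] <- th + (states[par, ] - th) * damp +
        stats::rnorm(p, 0, sqrt(v))
    } else {
      states[ch, ] <- states[par, ] + stats::rnorm(p, 0,
                                                   sqrt(scenario$rate * len))
    }
  }
  tips <- states[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips, nodes = states[(n + 1L):nNodes, , drop = FALSE],
       edgeOptima = opt)
}

#' Simulate a landmark dataset with known evolutionary ground truth
#'
#' Latent traits evolve on a simulated pure-birth tree under the
#' scenario's model; each tip configuration is the template plus the sum
#' of trait-weighted orthonormal deformation fields, and each replicate
#' specimen adds independent Gaussian landmark noise.
#'
#' @param scenario a [simulationScenario()].
#' @return list with \code{landmarks} (a [LandmarkSet-class]), \code{tree}
#'   (a \code{phylo}) and \code{groundTruth} (template, basis, latent tip
#'   and node traits, edge optima and the scenario) -- sufficient to
#'   recompute every generated coordinate.
#' @export
simulateShapeDataset <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  tree <- simulateTree(scenario$nTaxa, scenario$birthRate)
  traits <- simulateLatentTraits(tree, scenario)
  tmpl <- landmarkCoords(templateOpercle())[, , 1]
  basis <- deformationBasis(tmpl, scenario$deformationDims)
  k <- nrow(tmpl)
  nRep <- scenario$replicatesPerSpecies
  n <- scenario$nTaxa
  coords <- array(0, c(k, 2L, n * nRep))
  ids <- character(n * nRep); taxon <- character(n * nRep)
  noise <- array(stats::rnorm(k * 2L * n * nRep, 0, scenario$noiseSd),
                 c(k, 2L, n * nRep))
  for (i in seq_len(n)) {
    tipShape <- tmpl + unflattenShape(
      as.vector(basis %*% traits$tips[i, ]))
    for (r in seq_len(nRep)) {
      j <- (i - 1L) * nRep + r
      coords[, , j] <- tipShape + noise[, , j]
      ids[j] <- if (nRep == 1L) tree$tip.label[i]
                else paste0(tree$tip.label[i], "_rep", r)
      taxon[j] <- tree$tip.label[i]
    }
  }
  lm <- landmarkSet(coords, specimenID = ids, taxon = taxon,
                    roles = opercleRoles())
  list(landmarks = lm, tree = tree,
       groundTruth = list(template = tmpl, basis = basis,
                          tipTraits = traits$tips,
                          nodeTraits = traits$nodes,
                          edgeOptima = traits$edgeOptima,
                          scenario = scenario))
}

## TRUE when the closed polyline has no self-intersection
isSimpleOutline <- function(pts) {
  q <- nrow(pts)
  nxt <- c(2:q, 1L)
  p1 <- pts; p2 <- pts[nxt, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(q - 2L)) {
    js <- (i + 2L):q
    js <- js[!(i == 1L & js == q)]   # skip adjacent segments
    if (!length(js)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[js, 1], p1[js, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[js, 1], p2[js, 2])
    d3 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                rep(p1[i, 1], length(js)), rep(p1[i, 2], length(js)))
    d4 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                rep(p2[i, 1], length(js)), rep(p2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## periodic spline through the 18 edge points, evaluated at q points
smoothClosedOutline <- function(pts, q = 400L) {
  k <- nrow(pts)
  tt <- seq(0, 1, length.out = k + 1L)
  xs <- c(pts[, 1], pts[1, 1]); ys <- c(pts[, 2], pts[1, 2])
  at <- seq(0, 1, length.out = q + 1L)[-(q + 1L)]
  x <- stats::spline(tt, xs, method = "periodic", xout = at)$y
  y <- stats::spline(tt, ys, method = "periodic", xout = at)$y
  cbind(x, y)
}

#' Simulate closed outlines with known ground truth
#'
#' Deforms the template as in [simulateShapeDataset()] (no replicate noise)
#' and interpolates each tip's 18 edge points with a periodic spline to a
#' closed \code{q}-point outline. Self-intersecting outlines are rejected
#' and the tip's latent traits redrawn (shrunk toward zero if repeatedly
#' degenerate).
#'
#' @param scenario a [simulationScenario()].
#' @param q outline points per taxon (default 400).
#' @return list with \code{outlines} (named list of \code{q x 2} matrices)
#'   and \code{groundTruth} as in [simulateShapeDataset()].
#' @export
simulateOutlines <- function(scenario, q = 400L) {
  ds <- simulateShapeDataset(scenario)
  gt <- ds$groundTruth
  tmpl <- gt$template
  outlines <- vector("list", scenario$nTaxa)
  names(outlines) <- ds$tree$tip.label
  for (i in seq_len(scenario$nTaxa)) {
    tr <- gt$tipTraits[i, ]
    for (try in 0:20) {
      shape <- tmpl + unflattenShape(as.vector(gt$basis %*% tr))
      out <- smoothClosedOutline(shape, q)
      if (isSimpleOutline(out)) break
      tr <- tr * 0.7   # shrink toward the template until simple
    }
    gt$tipTraits[i, ] <- tr
    outlines[[i]] <- out
  }
  list(outlines = outlines, groundTruth = gt)
}
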