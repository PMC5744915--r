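test_that("C1 hits its boundary values in the canonical geometries", {
  tr <- balancedTree4()
  ## coincident tips from lineages whose ancestors differ: full convergence
  sc <- rbind(A = c(0, 0), B = c(4, 0), C = c(0, 0), D = c(-4, 0))
  cs <- cSimilarity(tr, sc, c("A", "C"))
  expect_equal(unname(cs["C1"]), 1, tolerance = 1e-12)
  expect_gt(cs["C2"], 0)
  ## pure divergence: the tips are the most dissimilar cross-lineage states
  sc2 <- rbind(A = c(-1, 0), B = c(0, 0.1), C = c(1, 0), D = c(0, -0.1))
  cs2 <- cSimilarity(tr, sc2, c("A", "C"))
  expect_equal(unname(cs2["C1"]), 0, tolerance = 1e-12)
  expect_equal(unname(cs2["C2"]), 0, tolerance = 1e-12)
})

test_that("C1-C4 match a brute-force enumeration over cross-lineage states", {
  skip_if_not_installed("phytools")
  set.seed(41)
  tr <- ape::read.tree(text = "(((A:1,B:2):1.5,C:0.5):1,(D:2,E:1):2);")
  for (rep in 1:4) {
    sc <- matrix(rnorm(10), 5, 2, dimnames = list(tr$tip.label, NULL))
    got <- cSimilarity(tr, sc, c("A", "D"))
    ## independent reconstruction: phytools ancestors + ape node paths
    anc <- cbind(phytools::fastAnc(tr, stats::setNames(sc[, 1],
                                                       rownames(sc))),
                 phytools::fastAnc(tr, stats::setNames(sc[, 2],
                                                       rownames(sc))))
    states <- rbind(sc[tr$tip.label, ], anc)
    mrca <- ape::getMRCA(tr, c("A", "D"))
    p1 <- ape::nodepath(tr, which(tr$tip.label == "A"), mrca)
    p2 <- ape::nodepath(tr, which(tr$tip.label == "D"), mrca)
    dmax <- 0
    for (i in p1) for (j in p2)
      dmax <- max(dmax, sqrt(sum((states[i, ] - states[j, ])^2)))
    dtip <- sqrt(sum((states[1, ] - states[4, ])^2))
    pathLen <- function(p) sum(vapply(seq_len(length(p) - 1), function(i)
      sqrt(sum((states[p[i], ] - states[p[i + 1], ])^2)), numeric(1)))
    ## total evolution in the clade below the mrca (here: the whole tree)
    totClade <- sum(vapply(seq_len(nrow(tr$edge)), function(e)
      sqrt(sum((states[tr$edge[e, 1], ] - states[tr$edge[e, 2], ])^2)),
      numeric(1)))
    expect_equal(unname(got["C1"]), 1 - dtip / dmax, tolerance = 1e-10)
    expect_equal(unname(got["C2"]), dmax - dtip, tolerance = 1e-10)
    expect_equal(unname(got["C3"]),
                 (dmax - dtip) / (pathLen(p1) + pathLen(p2)),
                 tolerance = 1e-10)
    expect_equal(unname(got["C4"]), (dmax - dtip) / totClade,
                 tolerance = 1e-10)
  }
})

test_that("multi-taxon focal sets aggregate pairwise values", {
  set.seed(42)
  tr <- simulateTree(8, 0.3)
  sc <- matrix(rnorm(16), 8, 2, dimnames = list(tr$tip.label, NULL))
  focal <- tr$tip.label[1:3]
  m <- cSimilarity(tr, sc, focal, aggregate = "mean")
  pairs <- combn(focal, 2)
  vals <- sapply(seq_len(3), function(j)
    cSimilarity(tr, sc, pairs[, j]))
  expect_equal(unname(m), unname(rowMeans(vals)), tolerance = 1e-10)
  mx <- cSimilarity(tr, sc, focal, aggregate = "max")
  expect_equal(unname(mx), unname(apply(vals, 1, max)), tolerance = 1e-10)
  expect_error(cSimilarity(tr, sc, "A1"), "at least two")
})

test_that("C1 is similarity-invariant and C2 scales linearly", {
  set.seed(43)
  tr <- simulateTree(10, 0.3)
  sc <- matrix(rnorm(20), 10, 2, dimnames = list(tr$tip.label, NULL))
  focal <- tr$tip.label[c(2, 7, 9)]
  base <- cSimilarity(tr, sc, focal)
  moved <- sweep(3.5 * sc %*% rotMat(1.2), 2, c(10, -4), "+")
  rownames(moved) <- rownames(sc)
  tr2 <- cSimilarity(tr, moved, focal)
  expect_equal(tr2["C1"], base["C1"], tolerance = 1e-10)
  expect_equal(tr2["C3"], base["C3"], tolerance = 1e-10)
  expect_equal(tr2["C4"], base["C4"], tolerance = 1e-10)
  expect_equal(unname(tr2["C2"]), unname(3.5 * base["C2"]),
               tolerance = 1e-10)
})

test_that("C5 counts independent entries into a region", {
  rg <- focalRegion(center = c(0, 0), semiAxes = c(1, 1), label = "peak")
  ## one monophyletic clade inside, stem ancestor outside -> 1 entry
  lay1 <- c5Layout(c(0.2, 0.2,  -0.2, 0.2,  5, 5,  6, 5,  7, 0),
                   c(4, 4,  3, 3,  0, 0,  5.5, 5))
  expect_equal(c5Count(lay1, rg), 1)
  ## empty region -> 0
  lay0 <- c5Layout(c(3, 3,  4, 3,  5, 5,  6, 5,  7, 0),
                   c(4, 4,  3, 3,  3.5, 3,  5.5, 5))
  expect_equal(c5Count(lay0, rg), 0)
  ## two separate clades inside plus one singleton tip entering -> 3
  lay3 <- c5Layout(c(0.2, 0.2,  -0.2, 0.2,  0.2, -0.2,  -0.2, -0.2,  0, 0.5),
                   c(4, 4,  3, 3,  0.1, 0.1,  -0.1, -0.1))
  expect_equal(c5Count(lay3, rg), 3)
  ## edge-order invariance
  perm <- sample(nrow(lay3@edges))
  lay3b <- new("PhylomorphospaceLayout", tipPoints = lay3@tipPoints,
               nodePoints = lay3@nodePoints,
               edges = lay3@edges[perm, ])
  expect_equal(c5Count(lay3b, rg), 3)
  ## lineage counting collapses entries that leave no tip inside
  expect_equal(c5Count(lay1, rg, count = "lineages"), 1)
  expect_error(c5Count(lay1, focalRegion(taxa = "A")), "ellipse")
})

test_that("subdividing an edge on one side of the boundary keeps C5", {
  rg <- focalRegion(center = c(0, 0), semiAxes = c(1, 1), label = "peak")
  ## 2-tip tree: root 3 -> {A, B}; A inside, B and the root outside
  lay <- new("PhylomorphospaceLayout",
             tipPoints = matrix(c(0.1, 0, 4, 0), 2, 2, byrow = TRUE,
                                dimnames = list(c("A", "B"), NULL)),
             nodePoints = matrix(c(3, 0), 1, 2),
             edges = cbind(c(3L, 3L), c(1L, 2L)))
  expect_equal(c5Count(lay, rg), 1)
  ## subdivide the entering edge with a collinear midpoint still outside
  lay2 <- new("PhylomorphospaceLayout",
              tipPoints = lay@tipPoints,
              nodePoints = matrix(c(3, 0, 2, 0), 2, 2, byrow = TRUE),
              edges = cbind(c(3L, 3L, 4L), c(4L, 2L, 1L)))
  expect_equal(c5Count(lay2, rg), 1)
})

test_that("convergence test is reproducible with calibrated p-values", {
  set.seed(44)
  tr <- simulateTree(16, 0.2)
  sc <- simBMTips(tr, sigma2 = 0.01, p = 2)
  focal <- sample(tr$tip.label, 4)
  r1 <- suppressWarnings(convergenceTest(tr, sc, focal, nSims = 60,
                                         seed = 9))
  r2 <- suppressWarnings(convergenceTest(tr, sc, focal, nSims = 60,
                                         seed = 9))
  expect_identical(r1@C, r2@C)
  expect_identical(r1@p, r2@p)
  expect_true(all(r1@p >= 0 & r1@p <= 1))
  ## bare-count convention: p has resolution 1/nSims and may be exactly 0
  expect_true(all(abs(r1@p * 60 - round(r1@p * 60)) < 1e-12))
  rg <- focalRegion(center = colMeans(sc[focal, ]), semiAxes = c(3, 3),
                    label = "peak")
  rr <- suppressWarnings(convergenceTest(tr, sc, rg, nSims = 60, seed = 9))
  expect_true("C5" %in% names(rr@C))
  expect_error(convergenceTest(tr, sc,
                               focalRegion(center = c(1e6, 1e6),
                                           semiAxes = c(0.1, 0.1)),
                               nSims = 200),
               "fewer than two")
})

test_that("a shared distant optimum is detected as convergence", {
  set.seed(45)
  tr <- simulateTree(24, 0.08)
  depth <- max(ape::node.depth.edgelength(tr))
  ## pick two distant small clades and drive them to one shared optimum
  clades <- pickDistantClades(tr, 3, 6)
  skip_if(is.null(clades), "tree lacks two disjoint small clades")
  regime <- list(list(taxa = c(clades[[1]], clades[[2]]),
                      optimum = c(1, 0)))
  scen <- simulationScenario(nTaxa = 24, birthRate = 0.08,
                             shapeModel = "OU_convergent",
                             rate = 0.02 / depth, ouAlpha = 50 / depth,
                             regimes = regime)
  lat <- opershape:::simulateLatentTraits(tr, scen)
  focal <- regime[[1]]$taxa
  res <- convergenceTest(tr, lat$tips, focal, nSims = 200, seed = 11)
  expect_lte(res@p["C1"], 0.05)
})
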