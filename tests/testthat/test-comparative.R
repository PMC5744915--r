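test_that("univariate Kmult equals directly coded Blomberg K", {
  set.seed(31)
  tr <- simulateTree(24, 0.2)
  x <- stats::setNames(rnorm(24), tr$tip.label)
  res <- kmult(x, tr, nPerm = 19, seed = 1)
  expect_equal(res@K, blombergK(x, tr), tolerance = 1e-8)
  skip_if_not_installed("picante")
  expect_equal(res@K, as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
               tolerance = 1e-8)
})

test_that("Kmult sits near 1 under Brownian motion and detects its absence", {
  set.seed(32)
  tr <- simulateTree(48, 0.2)
  ks <- replicate(60, kmult(simBMTips(tr, p = 4), tr, nPerm = 9)@K)
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
  ## strong signal data give small p, shuffled data do not
  y <- simBMTips(tr, p = 4)
  strong <- kmult(y, tr, nPerm = 499, seed = 5)
  shuffled <- y
  rownames(shuffled) <- sample(rownames(y))
  weak <- kmult(shuffled, tr, nPerm = 499, seed = 5)
  expect_lt(strong@p, 0.05)
  expect_lt(weak@K, strong@K)
  expect_error(kmult(y[-1, ], tr), "missing")
})

test_that("Procrustes variance follows the divisor-n definition", {
  set.seed(33)
  same <- matrix(rnorm(20), 2, 10, byrow = TRUE)
  same[2, ] <- same[1, ]
  expect_equal(procrustesVariance(same), 0)
  ## two members symmetric about their mean, each at residual norm |e|
  m <- rnorm(10); e <- rnorm(10)
  pairY <- rbind(m + e, m - e)
  expect_equal(procrustesVariance(pairY), sum(e^2), tolerance = 1e-12)
  ## equals the direct double-loop identity (1/2n^2) sum_ij d_ij^2
  y <- matrix(rnorm(60), 6, 10)
  dd <- as.matrix(dist(y))^2
  expect_equal(procrustesVariance(y), sum(dd) / (2 * 36), tolerance = 1e-10)
  ## and the explicit loop over members
  ctr <- colMeans(y)
  direct <- mean(apply(y, 1, function(r) sum((r - ctr)^2)))
  expect_equal(procrustesVariance(y), direct, tolerance = 1e-12)
})

test_that("disparity contrast reproduces printed fold ratios and has power", {
  ## arithmetic on the published group variances
  expect_equal(round(foldDifference(c(0.073, 0.111)), 2), 1.52)
  set.seed(34)
  base <- matrix(rnorm(30 * 8, sd = 0.1), 30, 8)
  wide <- matrix(rnorm(30 * 8, sd = 0.3), 30, 8)
  y <- rbind(base, wide)
  rownames(y) <- paste0("t", 1:60)
  groups <- stats::setNames(rep(c("narrow", "wide"), each = 30),
                            rownames(y))
  res <- disparityTest(y, groups, nPerm = 499, seed = 2)
  expect_lte(res@p, 0.01)
  expect_gt(res@foldDifference, 4)
  expect_error(disparityTest(y, groups[c(1, 31)]), "every taxon")
})

test_that("rate comparison reproduces the printed ratio and recovers contrasts", {
  expect_gte(foldDifference(c(0.92, 2.15)), 2.33)
  expect_lte(foldDifference(c(0.92, 2.15)), 2.34)
  set.seed(35)
  tr <- simulateTree(40, 0.2)
  C <- phyloCovariance(tr)
  groups <- stats::setNames(rep(c("slow", "fast"), 20)[order(order(tr$tip.label))],
                            tr$tip.label)
  ## simulate per-tip rates by scaling whitened increments per group
  groups <- stats::setNames(rep("slow", 40), tr$tip.label)
  groups[sample(tr$tip.label, 20)] <- "fast"
  U <- chol(C)
  z <- t(U) %*% matrix(rnorm(40 * 6), 40, 6)
  rownames(z) <- rownames(C)
  y <- z
  y[groups[rownames(y)] == "fast", ] <-
    2 * y[groups[rownames(y)] == "fast", ]   # 4x rate
  res <- compareEvolutionaryRates(tr, y, groups, nSims = 199, seed = 3)
  expect_gt(res@foldDifference, 2)
  expect_lt(res@foldDifference, 8)
  expect_lte(res@p, 0.05)
  expect_equal(names(which.max(res@rates)), "fast")
})

test_that("model selection satisfies its analytic identities", {
  ## BM and WN coincide on a star tree
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2,F:2);")
  set.seed(36)
  x <- stats::setNames(rnorm(6), star$tip.label)
  fit <- fitEvolutionaryModels(star, x, models = c("BM", "WN"))
  expect_equal(fit@table["BM", "lnL"], fit@table["WN", "lnL"],
               tolerance = 1e-6)

  tr <- simulateTree(32, 0.2, seed = 4)
  y <- stats::setNames(simBMTips(tr)[, 1], tr$tip.label)
  full <- fitEvolutionaryModels(tr, y)
  ## EB nests BM at r = 0: on BM data the EB fit falls back to r = 0
  expect_gte(full@table["EB", "lnL"], full@table["BM", "lnL"] - 1e-8)
  if (full@parameters$EB["r"] == 0)
    expect_equal(full@table["EB", "lnL"], full@table["BM", "lnL"],
                 tolerance = 1e-8)
  ## BM ML rate matches the closed-form GLS expression
  C <- phyloCovariance(tr)[names(y), names(y)]
  Cinv <- solve(C)
  one <- rep(1, 32)
  z0 <- as.numeric((t(one) %*% Cinv %*% y) / (t(one) %*% Cinv %*% one))
  sig2 <- as.numeric(t(y - z0) %*% Cinv %*% (y - z0)) / 32
  expect_equal(unname(full@parameters$BM["sig2"]), sig2, tolerance = 1e-8)
  expect_equal(unname(full@parameters$BM["z0"]), z0, tolerance = 1e-8)
  ## AICc bookkeeping
  expect_equal(min(full@table$dAICc), 0)
  k <- full@table["OU", "k"]
  expect_equal(full@table["OU", "AICc"],
               -2 * full@table["OU", "lnL"] + 2 * k +
                 2 * k * (k + 1) / (32 - k - 1), tolerance = 1e-10)
})

test_that("model ranking is invariant to trait shifts and time rescaling", {
  tr <- simulateTree(24, 0.2, seed = 5)
  y <- stats::setNames(simBMTips(tr)[, 1], tr$tip.label)
  f1 <- fitEvolutionaryModels(tr, y)
  f2 <- fitEvolutionaryModels(tr, y + 100)
  expect_equal(f1@table$dAICc, f2@table$dAICc, tolerance = 1e-6)
  tr2 <- tr
  tr2$edge.length <- 2 * tr$edge.length
  f3 <- fitEvolutionaryModels(tr2, y, models = "BM")
  expect_equal(unname(f3@parameters$BM["sig2"]),
               unname(f1@parameters$BM["sig2"]) / 2, tolerance = 1e-8)
  expect_equal(f3@table["BM", "lnL"], f1@table["BM", "lnL"],
               tolerance = 1e-8)
})

test_that("the optional bootstrap adds reproducible dAICc standard errors", {
  tr <- simulateTree(16, 0.2, seed = 6)
  y <- stats::setNames(simBMTips(tr)[, 1], tr$tip.label)
  f1 <- fitEvolutionaryModels(tr, y, bootstrapSE = 10, seed = 8)
  expect_true("dAICc_SE" %in% names(f1@table))
  expect_true(all(is.finite(f1@table$dAICc_SE)))
  expect_true(all(f1@table$dAICc_SE >= 0))
  f2 <- fitEvolutionaryModels(tr, y, bootstrapSE = 10, seed = 8)
  expect_identical(f1@table$dAICc_SE, f2@table$dAICc_SE)
})

test_that("strong OU attraction is identified on an ultrametric tree", {
  set.seed(37)
  tr <- simulateTree(64, 0.2)
  depth <- max(ape::node.depth.edgelength(tr))
  alpha <- 3 / depth
  C <- phyloCovariance(tr)
  D <- outer(diag(C), diag(C), "+") - 2 * C
  V <- (1 - exp(-2 * alpha * C)) * exp(-alpha * D) / (2 * alpha)
  y <- stats::setNames(as.vector(t(chol(V)) %*% rnorm(64)), tr$tip.label)
  fit <- fitEvolutionaryModels(tr, y)
  expect_equal(fit@table["OU", "dAICc"], 0)
  nonUltra <- ape::rtree(10)
  expect_error(
    fitEvolutionaryModels(nonUltra,
                          stats::setNames(rnorm(10), nonUltra$tip.label)),
    "ultrametric")
})
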