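## coerce shape/trait input to an n x p matrix with taxon rownames
asTraitMatrix <- function(x) {
  if (is(x, "AlignedShapes")) {
    m <- flattenShapes(x@coords)
    rownames(m) <- x@taxon
    m
  } else if (is(x, "LandmarkSet")) {
    m <- flattenShapes(x@coords)
    rownames(m) <- x@taxon
    m
  } else if (is.vector(x) && !is.null(names(x))) {
    matrix(x, ncol = 1, dimnames = list(names(x), "trait"))
  } else {
    as.matrix(x)
  }
}

## align trait matrix rows with tree tips; error on mismatch
matchToTree <- function(y, tree) {
  if (anyDuplicated(rownames(y)))
    stop("duplicate taxa in trait data: ",
         paste(unique(rownames(y)[duplicated(rownames(y))]), collapse = ", "))
  missing <- setdiff(tree$tip.label, rownames(y))
  if (length(missing))
    stop("tree tips missing from data: ", paste(missing, collapse = ", "))
  y[tree$tip.label, , drop = FALSE]
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' The multivariate generalization of Blomberg's K: the ratio of the
#' observed mean-centred to phylogenetically transformed generalized sums
#' of squares, divided by its Brownian-motion expectation under the tree.
#' K is about 1 when trait similarity matches Brownian motion on the tree
#' and below 1 when relatives resemble each other less than that.
#' Significance is assessed by permuting taxa across the tips; the p-value
#' uses the \code{(count + 1) / (nPerm + 1)} estimator.
#'
#' @param x an [AlignedShapes-class], a trait matrix with taxon rownames,
#'   or a named vector (univariate K).
#' @param tree a \code{phylo}; tips must match the taxa one-to-one.
#' @param nPerm number of permutations (default 10000).
#' @param seed optional integer seed for the permutations.
#' @return a [KResult-class].
#' @export
kmult <- function(x, tree, nPerm = 10000L, seed = NULL) {
  y <- matchToTree(asTraitMatrix(x), tree)
  n <- nrow(y)
  C <- phyloCovariance(tree)[rownames(y), rownames(y)]
  eig <- eigen(C, symmetric = TRUE)
  E <- diag(1 / sqrt(eig$values)) %*% t(eig$vectors)   # C^{-1/2}
  Cinv <- eig$vectors %*% diag(1 / eig$values) %*% t(eig$vectors)
  w <- as.vector(Cinv %*% rep(1, n)) / sum(Cinv)        # GLS mean weights
  expectation <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  kStat <- function(ym) {
    a <- crossprod(w, ym)                               # 1 x p
    r <- sweep(ym, 2, a)
    (sum(r^2) / sum((E %*% r)^2)) / expectation
  }
  kObs <- kStat(y)
  if (!is.null(seed)) set.seed(seed)
  kPerm <- vapply(seq_len(nPerm),
                  function(i) kStat(y[sample.int(n), , drop = FALSE]),
                  numeric(1))
  p <- (sum(kPerm >= kObs) + 1) / (nPerm + 1)
  new("KResult", K = kObs, p = p, nPermutations = as.integer(nPerm),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

#' Procrustes variance (morphological disparity)
#'
#' Mean squared Procrustes distance of group members from the group mean
#' shape: the sum of coordinate-wise variances with divisor n.
#'
#' @param x an [AlignedShapes-class] (or subclass/subset), a \code{k x 2 x n}
#'   array, or an \code{n x p} matrix of flattened coordinates.
#' @return non-negative scalar.
#' @export
procrustesVariance <- function(x) {
  y <- if (is.array(x) && length(dim(x)) == 3L) flattenShapes(x)
       else asTraitMatrix(x)
  if (nrow(y) == 0L) stop("empty group")
  ctr <- colMeans(y)
  sum(sweep(y, 2, ctr)^2) / nrow(y)
}

#' Fold difference between group statistics
#'
#' @param values numeric vector of per-group variances or rates.
#' @return max / min, always >= 1.
#' @export
foldDifference <- function(values) {
  stopifnot(length(values) >= 2L, all(values > 0))
  max(values) / min(values)
}

#' Group disparity contrast with permutation test
#'
#' Compares per-group Procrustes variances; significance of the absolute
#' pairwise variance difference under random reassignment of group labels,
#' with the \code{(count + 1) / (nPerm + 1)} p-value estimator.
#'
#' @param aligned an [AlignedShapes-class] (or trait matrix with taxon
#'   rownames).
#' @param groups named character/factor mapping taxa to group labels.
#' @param nPerm number of label permutations (default 1000).
#' @param seed optional integer seed.
#' @return a [DisparityResult-class]; \code{p} is the p-value for the
#'   largest pairwise contrast.
#' @export
disparityTest <- function(aligned, groups, nPerm = 1000L, seed = NULL) {
  y <- asTraitMatrix(aligned)
  groups <- groups[rownames(y)]
  if (any(is.na(groups))) stop("groups must cover every taxon")
  g <- as.character(groups)
  labs <- unique(g)
  if (length(labs) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 members")
  pv <- function(gg) vapply(labs, function(l)
    procrustesVariance(y[gg == l, , drop = FALSE]), numeric(1))
  obs <- pv(g)
  dObs <- abs(outer(obs, obs, "-"))
  if (!is.null(seed)) set.seed(seed)
  count <- matrix(0, length(labs), length(labs))
  for (i in seq_len(nPerm)) {
    vp <- pv(sample(g))
    count <- count + (abs(outer(vp, vp, "-")) >= dObs)
  }
  pMat <- (count + 1) / (nPerm + 1)
  dimnames(pMat) <- list(labs, labs)
  imax <- which(dObs == max(dObs), arr.ind = TRUE)[1, ]
  new("DisparityResult", variances = obs,
      foldDifference = foldDifference(obs),
      p = pMat[imax[1], imax[2]], pairwiseP = pMat,
      nPermutations = as.integer(nPerm),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

#' Compare multivariate evolutionary rates between groups
#'
#' Per-group Brownian rates (sigma^2 mult) from phylogenetically
#' transformed data: residuals from the GLS root are whitened by the tree
#' covariance and each group's rate is its mean squared transformed
#' residual per trait dimension. Significance of the max/min rate ratio is
#' assessed by simulating \code{nSims} datasets under a single common rate
#' on the tree (p-value \code{(count + 1) / (nSims + 1)}).
#'
#' @param tree a \code{phylo}.
#' @param aligned an [AlignedShapes-class] or trait matrix with taxon
#'   rownames.
#' @param groups named character/factor mapping tips to group labels; each
#'   group needs at least 2 tips.
#' @param nSims number of common-rate simulations (default 1000).
#' @param seed optional integer seed.
#' @return a [RateResult-class].
#' @export
compareEvolutionaryRates <- function(tree, aligned, groups, nSims = 1000L,
                                     seed = NULL) {
  y <- matchToTree(asTraitMatrix(aligned), tree)
  n <- nrow(y); p <- ncol(y)
  groups <- as.character(groups[rownames(y)])
  if (any(is.na(groups))) stop("groups must cover every tip")
  labs <- unique(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 tips")
  C <- phyloCovariance(tree)[rownames(y), rownames(y)]
  U <- chol(C)                       # C = U'U
  ones <- rep(1, n)
  Cinv1 <- backsolve(U, forwardsolve(t(U), ones))
  rateStat <- function(ym) {
    a <- crossprod(Cinv1, ym) / sum(Cinv1)
    r <- sweep(ym, 2, a)
    z <- forwardsolve(t(U), r)       # whitened residuals
    d <- rowSums(z^2)
    rates <- vapply(labs, function(l) {
      idx <- groups == l
      sum(d[idx]) / (sum(idx) * p)
    }, numeric(1))
    rates
  }
  obs <- rateStat(y)
  obsRatio <- foldDifference(obs)
  ## overall (pooled) rate for the common-rate null
  aAll <- crossprod(Cinv1, y) / sum(Cinv1)
  zAll <- forwardsolve(t(U), sweep(y, 2, aAll))
  sigAll <- sum(zAll^2) / (n * p)
  if (!is.null(seed)) set.seed(seed)
  tU <- t(U)
  count <- 0L
  for (i in seq_len(nSims)) {
    sim <- sqrt(sigAll) * (tU %*% matrix(stats::rnorm(n * p), n, p))
    rownames(sim) <- rownames(y)
    if (foldDifference(rateStat(sim)) >= obsRatio) count <- count + 1L
  }
  new("RateResult", rates = obs, foldDifference = obsRatio,
      p = (count + 1) / (nSims + 1), nSims = as.integer(nSims),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

## profile GLS fit for a unit-rate covariance structure V0:
## concentrates sigma^2 and the root out of the likelihood
glsProfile <- function(x, V0) {
  n <- length(x)
  U <- chol(V0)
  logdet <- 2 * sum(log(diag(U)))
  sx <- forwardsolve(t(U), x)
  s1 <- forwardsolve(t(U), rep(1, n))
  z0 <- sum(s1 * sx) / sum(s1^2)
  q <- sum((sx - z0 * s1)^2)
  sig2 <- q / n
  lnL <- -0.5 * (n * log(2 * pi * sig2) + logdet + n)
  list(lnL = lnL, sig2 = sig2, z0 = z0)
}

#' Fit evolutionary models to a single trait and compare by AICc
#'
#' Maximum-likelihood fits of Brownian motion (BM), white noise (WN),
#' Ornstein-Uhlenbeck (OU) and early burst (EB) under a multivariate-normal
#' tip likelihood with model-specific covariance: BM uses shared path
#' depths; WN an identity (phylogeny-free); OU the fixed-root covariance
#' \code{(1 - exp(-2 a C)) exp(-a d) / (2a)} on an ultrametric tree (the
#' optimum theta equals the root state under this convention); EB a BM
#' whose rate decays as \code{exp(r t)} with \code{r <= 0}. The rate and
#' root are concentrated out; alpha and r are optimized in
#' \code{[1e-8, 50] / depth} and \code{[-10, 0] / depth}. Models are ranked
#' by \code{AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)}; dAICc below 2 is
#' conventionally read as support.
#'
#' @param tree an ultrametric \code{phylo} (required for OU).
#' @param trait named numeric vector of tip values (e.g. one PC).
#' @param models subset of \code{c("BM", "WN", "OU", "EB")}.
#' @param traitName label for the result table.
#' @param bootstrapSE integer; when positive, a parametric bootstrap of
#'   this many replicates (data re-simulated from the best-fitting model,
#'   all models refitted) adds a \code{dAICc_SE} column to the table.
#' @param seed optional integer seed for the bootstrap.
#' @return a [ModelFitTable-class].
#' @export
fitEvolutionaryModels <- function(tree, trait,
                                  models = c("BM", "WN", "OU", "EB"),
                                  traitName = "trait", bootstrapSE = 0L,
                                  seed = NULL) {
  y <- matchToTree(asTraitMatrix(trait), tree)
  x <- y[, 1]
  n <- length(x)
  if (n < 5L) stop("need at least 5 tips")
  C <- phyloCovariance(tree)[names(x), names(x)]
  depth <- max(diag(C))
  if ("OU" %in% models &&
      diff(range(diag(C))) > 1e-6 * depth)
    stop("OU requires an ultrametric tree")
  D <- outer(diag(C), diag(C), "+") - 2 * C   # patristic distances
  fits <- list(); conv <- logical(0)
  if ("BM" %in% models) {
    f <- glsProfile(x, C)
    fits$BM <- list(lnL = f$lnL, k = 2L,
                    par = c(sig2 = f$sig2, z0 = f$z0))
    conv["BM"] <- TRUE
  }
  if ("WN" %in% models) {
    f <- glsProfile(x, diag(n))
    fits$WN <- list(lnL = f$lnL, k = 2L,
                    par = c(sig2 = f$sig2, mean = f$z0))
    conv["WN"] <- TRUE
  }
  if ("OU" %in% models) {
    ouV <- function(alpha) -expm1(-2 * alpha * C) / (2 * alpha) * exp(-alpha * D)
    negll <- function(a) -glsProfile(x, ouV(a))$lnL
    opt <- stats::optimize(negll, c(1e-8 / depth, 50 / depth), tol = 1e-10)
    f <- glsProfile(x, ouV(opt$minimum))
    fits$OU <- list(lnL = f$lnL, k = 3L,
                    par = c(sig2 = f$sig2, alpha = opt$minimum,
                            theta = f$z0, z0 = f$z0))
    conv["OU"] <- is.finite(f$lnL)
  }
  if ("EB" %in% models) {
    ebV <- function(r) if (abs(r) < 1e-12) C else expm1(r * C) / r
    negll <- function(r) -glsProfile(x, ebV(r))$lnL
    opt <- stats::optimize(negll, c(-10 / depth, 0), tol = 1e-10)
    bmL <- glsProfile(x, C)
    rhat <- if (-opt$objective >= bmL$lnL) opt$minimum else 0
    f <- glsProfile(x, ebV(rhat))
    fits$EB <- list(lnL = f$lnL, k = 3L,
                    par = c(sig2 = f$sig2, r = rhat, z0 = f$z0))
    conv["EB"] <- is.finite(f$lnL)
  }
  lnL <- vapply(fits, `[[`, numeric(1), "lnL")
  k <- vapply(fits, `[[`, integer(1), "k")
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  tab <- data.frame(model = names(fits), lnL = lnL, k = k, AICc = aicc,
                    dAICc = aicc - min(aicc), row.names = names(fits))
  if (bootstrapSE > 0L) {
    best <- rownames(tab)[which.min(tab$AICc)]
    par <- fits[[best]]$par
    V <- par["sig2"] * switch(best,
      BM = C,
      WN = diag(n),
      OU = -expm1(-2 * par["alpha"] * C) / (2 * par["alpha"]) *
        exp(-par["alpha"] * D),
      EB = if (abs(par["r"]) < 1e-12) C else expm1(par["r"] * C) / par["r"])
    mu <- par[[if (best == "WN") "mean" else "z0"]]
    tU <- t(chol(V))
    if (!is.null(seed)) set.seed(seed)
    boot <- replicate(bootstrapSE, {
      yb <- stats::setNames(mu + as.vector(tU %*% stats::rnorm(n)), names(x))
      fitEvolutionaryModels(tree, yb, models = models)@table$dAICc
    })
    tab$dAICc_SE <- apply(matrix(boot, nrow = nrow(tab)), 1, stats::sd)
  }
  new("ModelFitTable", trait = traitName, table = tab,
      parameters = lapply(fits, `[[`, "par"), converged = conv)
}
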