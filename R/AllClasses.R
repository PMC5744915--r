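#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Landmark dataset
#'
#' A set of 2-D landmark configurations, one or more specimens per taxon.
#' Coordinates are stored as a \code{k x 2 x n} array (landmarks x
#' dimensions x specimens), the layout used throughout 2-D geometric
#' morphometrics. Each landmark carries a role, either \code{"fixed"}
#' (a biologically homologous point) or \code{"semilandmark"} (an
#' edge-sampling point placed at intervals along an outline segment).
#'
#' @slot coords numeric array, \code{k x 2 x n}.
#' @slot specimenID character vector of length n, unique specimen labels.
#' @slot taxon character vector of length n; several specimens may share a
#'   taxon before averaging.
#' @slot roles character vector of length k, values in
#'   \code{c("fixed", "semilandmark")}.
#' @slot side character vector of length n, values in
#'   \code{c("left", "right", "unknown")}.
#'
#' @seealso [readTPS()], [gpa()], [averageSpecimens()]
#' @export
setClass("LandmarkSet",
  representation(
    coords = "array",
    specimenID = "character",
    taxon = "character",
    roles = "character",
    side = "character"
  )
)

setValidity("LandmarkSet", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 2L)
    return("coords must be a k x 2 x n array")
  k <- d[1]; n <- d[3]
  if (k < 3L) return("at least 3 landmarks are required")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@specimenID) != n) return("specimenID length must equal n")
  if (anyDuplicated(object@specimenID)) return("specimenID must be unique")
  if (length(object@taxon) != n) return("taxon length must equal n")
  if (length(object@roles) != k) return("roles length must equal k")
  if (!all(object@roles %in% c("fixed", "semilandmark")))
    return("roles must be 'fixed' or 'semilandmark'")
  if (length(object@side) != n) return("side length must equal n")
  if (!all(object@side %in% c("left", "right", "unknown")))
    return("side must be 'left', 'right' or 'unknown'")
  TRUE
})

#' Procrustes-superimposed shapes
#'
#' The result of generalized Procrustes analysis: every configuration is
#' centred at the origin, scaled to unit centroid size, and rotated to the
#' consensus. Extends [LandmarkSet-class]; \code{coords} holds the aligned
#' coordinates.
#'
#' @slot consensus numeric \code{k x 2} mean shape.
#' @slot centroidSizes numeric vector of the original centroid sizes.
#' @slot iterations integer, number of GPA iterations performed.
#' @slot converged logical, whether the consensus displacement fell below
#'   the tolerance.
#'
#' @seealso [gpa()], [procrustesDistance()], [shapePCA()]
#' @export
setClass("AlignedShapes",
  contains = "LandmarkSet",
  representation(
    consensus = "matrix",
    centroidSizes = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("AlignedShapes", function(object) {
  d <- dim(object@coords)
  if (!all(dim(object@consensus) == c(d[1], 2L)))
    return("consensus must be k x 2")
  if (length(object@centroidSizes) != d[3])
    return("centroidSizes length must equal n")
  if (any(object@centroidSizes <= 0))
    return("centroid sizes must be positive")
  TRUE
})

#' Principal-component morphospace
#'
#' Covariance PCA of flattened Procrustes-aligned coordinates (or of any
#' per-taxon flat variable block, e.g. normalized elliptical-Fourier
#' coefficients). Scores are centred; eigenvectors are columns of
#' \code{rotation}.
#'
#' @slot scores numeric \code{n x m} matrix, taxa in rows.
#' @slot rotation numeric \code{p x m} matrix of eigenvectors (loadings).
#' @slot eigenvalues numeric vector, non-increasing.
#' @slot varianceFraction numeric vector summing to 1.
#' @slot center numeric vector of length p, the variable means.
#' @slot consensus numeric \code{k x 2} consensus shape, or a 0-row matrix
#'   when scores do not derive from landmarks.
#' @slot taxonOrder character vector of row labels.
#'
#' @seealso [shapePCA()], [varianceExplained()], [shapeAt()]
#' @export
setClass("Morphospace",
  representation(
    scores = "matrix",
    rotation = "matrix",
    eigenvalues = "numeric",
    varianceFraction = "numeric",
    center = "numeric",
    consensus = "matrix",
    taxonOrder = "character"
  )
)

setValidity("Morphospace", function(object) {
  m <- length(object@eigenvalues)
  if (ncol(object@scores) != m || ncol(object@rotation) != m)
    return("scores, rotation and eigenvalues disagree on m")
  if (length(object@varianceFraction) != m)
    return("varianceFraction length must equal m")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
      any(diff(object@eigenvalues) > 1e-12 * max(object@eigenvalues, 1)))
    return("eigenvalues must be non-increasing")
  if (length(object@taxonOrder) != nrow(object@scores))
    return("taxonOrder length must equal nrow(scores)")
  if (abs(sum(object@varianceFraction) - 1) > 1e-8)
    return("variance fractions must sum to 1")
  TRUE
})

#' Kernel-density occupancy landscape over (PC1, PC2)
#'
#' @slot x,y numeric grid coordinates.
#' @slot density numeric matrix, \code{length(x) x length(y)}, non-negative.
#' @slot bandwidth numeric length-2 Gaussian kernel standard deviations.
#' @slot contourLevels numeric, increasing density levels.
#'
#' @seealso [kdeLandscape()]
#' @export
setClass("DensityLandscape",
  representation(
    x = "numeric",
    y = "numeric",
    density = "matrix",
    bandwidth = "numeric",
    contourLevels = "numeric"
  )
)

setValidity("DensityLandscape", function(object) {
  if (!all(dim(object@density) == c(length(object@x), length(object@y))))
    return("density must be length(x) x length(y)")
  if (any(object@density < 0)) return("density must be non-negative")
  if (length(object@bandwidth) != 2L || any(object@bandwidth <= 0))
    return("bandwidth must be two positive scalars")
  TRUE
})

#' Focal morphospace region
#'
#' Either an ellipse in the (PC1, PC2) plane or an explicit taxon set;
#' the user-facing analogue of hand-outlined occupancy peaks.
#'
#' @slot type \code{"ellipse"} or \code{"taxa"}.
#' @slot center numeric length-2 ellipse centre.
#' @slot semiAxes numeric length-2 positive semi-axes.
#' @slot angle numeric, rotation of the major axis in radians.
#' @slot taxa character, the explicit taxon set (type \code{"taxa"}).
#' @slot label character, a display label such as \code{"peak 1"}.
#'
#' @seealso [focalRegion()], [regionMembers()], [c5Count()]
#' @export
setClass("FocalRegion",
  representation(
    type = "character",
    center = "numeric",
    semiAxes = "numeric",
    angle = "numeric",
    taxa = "character",
    label = "character"
  )
)

setValidity("FocalRegion", function(object) {
  if (!object@type %in% c("ellipse", "taxa"))
    return("type must be 'ellipse' or 'taxa'")
  if (object@type == "ellipse") {
    if (length(object@center) != 2L) return("center must have length 2")
    if (length(object@semiAxes) != 2L || any(object@semiAxes <= 0))
      return("semiAxes must be two positive scalars")
  } else if (length(object@taxa) == 0L) {
    return("explicit taxon set must be non-empty")
  }
  TRUE
})

#' Phylomorphospace layout
#'
#' Tip points are the empirical (PC1, PC2) scores; internal-node points are
#' squared-change-parsimony reconstructions; edges connect parent to child
#' following the tree. Points are indexed like an \pkg{ape} \code{phylo}:
#' tips \code{1..n}, internal nodes \code{n+1..n+nnode}.
#'
#' @slot tipPoints numeric \code{n x 2}, rownames are tip labels.
#' @slot nodePoints numeric \code{nnode x 2}.
#' @slot edges integer 2-column matrix of point indices (parent, child).
#'
#' @seealso [phylomorphospace()], [c5Count()]
#' @export
setClass("PhylomorphospaceLayout",
  representation(
    tipPoints = "matrix",
    nodePoints = "matrix",
    edges = "matrix"
  )
)

setValidity("PhylomorphospaceLayout", function(object) {
  np <- nrow(object@tipPoints) + nrow(object@nodePoints)
  if (nrow(object@edges) != np - 1L)
    return("edge count must equal point count - 1")
  if (ncol(object@tipPoints) != 2L || ncol(object@nodePoints) != 2L)
    return("points must be 2-D")
  TRUE
})

#' Phylogenetic signal result (multivariate Blomberg K)
#'
#' @slot K non-negative statistic; about 1 under Brownian motion.
#' @slot p permutation p-value, \code{(count + 1) / (nPermutations + 1)}.
#' @slot nPermutations integer.
#' @slot seed integer seed used for the permutations.
#'
#' @seealso [kmult()]
#' @export
setClass("KResult",
  representation(K = "numeric", p = "numeric", nPermutations = "integer",
                 seed = "integer"))

setValidity("KResult", function(object) {
  if (object@K < 0) return("K must be non-negative")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  TRUE
})

#' Disparity (Procrustes variance) contrast
#'
#' @slot variances named per-group Procrustes variances.
#' @slot foldDifference max/min group variance, always >= 1.
#' @slot p permutation p-value for the largest pairwise contrast.
#' @slot pairwiseP matrix of pairwise permutation p-values.
#' @slot nPermutations,seed integers.
#'
#' @seealso [disparityTest()], [procrustesVariance()]
#' @export
setClass("DisparityResult",
  representation(variances = "numeric", foldDifference = "numeric",
                 p = "numeric", pairwiseP = "matrix",
                 nPermutations = "integer", seed = "integer"))

#' Multivariate evolutionary-rate contrast
#'
#' @slot rates named per-group Brownian rates (sigma^2 mult).
#' @slot foldDifference max/min rate.
#' @slot p simulation p-value under a common-rate Brownian null.
#' @slot nSims,seed integers.
#'
#' @seealso [compareEvolutionaryRates()]
#' @export
setClass("RateResult",
  representation(rates = "numeric", foldDifference = "numeric",
                 p = "numeric", nSims = "integer", seed = "integer"))

#' Evolutionary model comparison table
#'
#' Maximum-likelihood fits of Brownian motion (BM), white noise (WN),
#' Ornstein-Uhlenbeck (OU) and early burst (EB) to a single continuous
#' trait on an ultrametric tree, compared by small-sample AICc.
#'
#' @slot trait character, name of the trait (e.g. \code{"PC1"}).
#' @slot table data.frame with one row per model: \code{lnL}, \code{k},
#'   \code{AICc}, \code{dAICc} and the fitted parameters.
#' @slot parameters named list of per-model parameter vectors.
#' @slot converged named logical vector.
#'
#' @seealso [fitEvolutionaryModels()]
#' @export
setClass("ModelFitTable",
  representation(trait = "character", table = "data.frame",
                 parameters = "list", converged = "logical"))

#' Convergence metrics with simulation p-values
#'
#' Stayton's similarity measures C1-C4 over a focal taxon set and the
#' frequency measure C5 (independent entries into a morphospace region),
#' with p-values from Brownian-motion simulations. Convergence p-values use
#' the bare count / nSims convention, so an empirical value exceeding every
#' simulation reports p = 0.
#'
#' @slot focal the [FocalRegion-class] or explicit taxon set tested.
#' @slot C named numeric vector of the computed metrics.
#' @slot p named numeric vector of simulation p-values.
#' @slot nSims,seed integers.
#'
#' @seealso [cSimilarity()], [c5Count()], [convergenceTest()]
#' @export
setClass("ConvergenceResult",
  representation(focal = "ANY", C = "numeric", p = "numeric",
                 nSims = "integer", seed = "integer"))

#' Consolidated analysis report
#'
#' Output of [runFullAnalysis()]; every slot equals the value returned by
#' the corresponding module function called with the same inputs and seed.
#'
#' @slot aligned [AlignedShapes-class] (post replicate averaging).
#' @slot morphospace [Morphospace-class].
#' @slot landscape [DensityLandscape-class] or NULL.
#' @slot layout [PhylomorphospaceLayout-class] or NULL.
#' @slot signal [KResult-class] or NULL.
#' @slot disparity [DisparityResult-class] or NULL.
#' @slot rates [RateResult-class] or NULL.
#' @slot models list of [ModelFitTable-class], one per analysed PC.
#' @slot convergence list of [ConvergenceResult-class], one per region.
#' @slot droppedTaxa character, taxa absent from the tree and removed.
#' @slot seed integer master seed.
#' @slot config the run configuration list.
#'
#' @export
setClass("AnalysisReport",
  representation(aligned = "ANY", morphospace = "ANY", landscape = "ANY",
                 layout = "ANY", signal = "ANY", disparity = "ANY",
                 rates = "ANY", models = "list", convergence = "list",
                 droppedTaxa = "character", seed = "integer",
                 config = "list"))
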