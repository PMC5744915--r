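#' Read a run configuration file
#'
#' YAML key-value file understood by [runFullAnalysis()]. Recognised keys:
#' \code{landmarks} (TPS or CSV path), \code{tree} (Newick path),
#' \code{groups} (CSV path with columns taxon, group), \code{regions}
#' (list of \code{label, center, semiAxes, angle} blocks), stage toggles
#' (\code{landscape, phylomorphospace, signal, disparity, rates, models,
#' convergence}), \code{nPerm}, \code{nSims}, \code{seed}, \code{outDir}.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$regions))
    cfg$regions <- lapply(cfg$regions, function(r)
      focalRegion(center = r$center, semiAxes = r$semiAxes,
                  angle = if (is.null(r$angle)) 0 else r$angle,
                  label = if (is.null(r$label)) "region" else r$label))
  cfg
}

## derived sub-seeds keep each stage reproducible in isolation
stageSeed <- function(seed, offset) as.integer((seed + offset) %% 2147483647L)

#' Run the full analysis chain
#'
#' Executes the stages in order: replicate averaging within taxa, GPA,
#' PCA, density landscape, phylomorphospace, phylogenetic signal, group
#' disparity, evolutionary-rate contrast, evolutionary-model fits on PC1
#' and PC2, and convergence tests per focal region. Taxa missing from the
#' tree are dropped with a recorded list; each stage's statistic equals
#' the corresponding module function called directly with the same inputs
#' and (derived) seed, and the whole run is deterministic given
#' \code{seed}.
#'
#' @param config a list (see [readRunConfig()]); in-memory objects are
#'   accepted for \code{landmarks} (a [LandmarkSet-class]), \code{tree}
#'   (a \code{phylo}) and \code{groups} (named vector).
#' @return an [AnalysisReport-class].
#' @export
runFullAnalysis <- function(config) {
  cfg <- config
  lm <- cfg$landmarks
  if (is.character(lm))
    lm <- if (grepl("\\.tps$", lm, ignore.case = TRUE)) readTPS(lm)
          else readLandmarkCSV(lm)
  tree <- cfg$tree
  if (is.character(tree)) tree <- readNewick(tree)
  groups <- cfg$groups
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gdf <- utils::read.csv(groups, stringsAsFactors = FALSE)
    groups <- stats::setNames(gdf$group, gdf$taxon)
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  nPerm <- if (is.null(cfg$nPerm)) 1000L else as.integer(cfg$nPerm)
  nSims <- if (is.null(cfg$nSims)) 1000L else as.integer(cfg$nSims)
  on <- function(stage, default = TRUE)
    if (is.null(cfg[[stage]])) default else isTRUE(cfg[[stage]])

  ## replicate averaging -> taxon-level GPA
  pre <- gpa(lm)
  byTaxon <- averageByTaxon(pre)
  dropped <- setdiff(byTaxon@taxon, tree$tip.label)
  if (length(dropped)) {
    message("dropping taxa absent from the tree: ",
            paste(dropped, collapse = ", "))
    byTaxon <- byTaxon[setdiff(byTaxon@specimenID, dropped)]
  }
  if (nSpecimens(byTaxon) < 4L)
    stop("fewer than 4 taxa remain after reconciling with the tree")
  tree <- pruneTo(tree, byTaxon@taxon)
  aligned <- gpa(byTaxon)
  ms <- shapePCA(aligned)

  landscape <- if (on("landscape")) kdeLandscape(ms) else NULL
  layout <- if (on("phylomorphospace")) phylomorphospace(tree, ms) else NULL
  signal <- if (on("signal"))
    kmult(aligned, tree, nPerm = nPerm, seed = stageSeed(seed, 11L)) else NULL
  disparity <- NULL
  rates <- NULL
  if (!is.null(groups)) {
    if (on("disparity"))
      disparity <- disparityTest(aligned, groups, nPerm = nPerm,
                                 seed = stageSeed(seed, 23L))
    if (on("rates"))
      rates <- compareEvolutionaryRates(tree, aligned, groups,
                                        nSims = nSims,
                                        seed = stageSeed(seed, 37L))
  }
  models <- list()
  if (on("models")) {
    for (pc in seq_len(min(2L, ncol(ms@scores)))) {
      tr <- stats::setNames(ms@scores[, pc], ms@taxonOrder)
      models[[paste0("PC", pc)]] <-
        fitEvolutionaryModels(tree, tr, traitName = paste0("PC", pc))
    }
  }
  convergence <- list()
  if (on("convergence") && !is.null(cfg$regions)) {
    for (i in seq_along(cfg$regions)) {
      rg <- cfg$regions[[i]]
      convergence[[rg@label]] <-
        convergenceTest(tree, ms, rg, nSims = nSims,
                        seed = stageSeed(seed, 101L + i))
    }
  }
  report <- new("AnalysisReport", aligned = aligned, morphospace = ms,
                landscape = landscape, layout = layout, signal = signal,
                disparity = disparity, rates = rates, models = models,
                convergence = convergence, droppedTaxa = dropped,
                seed = seed, config = cfg[!vapply(cfg, is.object, logical(1))])
  if (!is.null(cfg$outDir)) writeReport(report, cfg$outDir)
  report
}

#' Serialise an analysis report
#'
#' \code{reportJSON} returns the numeric payload (statistics, p-values,
#' seeds, model tables, variance explained) as a JSON string;
#' \code{writeReport} writes it plus the CSV artefacts (aligned
#' coordinates, PC scores, landscape grid, layout tables) under
#' \code{dir}.
#'
#' @param report an [AnalysisReport-class].
#' @return \code{reportJSON}: a JSON string.
#' @export
reportJSON <- function(report) {
  ms <- report@morphospace
  out <- list(
    seed = report@seed,
    nTaxa = nSpecimens(report@aligned),
    gpa = list(iterations = report@aligned@iterations,
               converged = report@aligned@converged),
    pca = list(varianceFraction = unname(ms@varianceFraction),
               pc12 = varianceExplained(ms, min(2L, ncol(ms@scores)))),
    droppedTaxa = report@droppedTaxa)
  if (!is.null(report@signal))
    out$signal <- list(K = report@signal@K, p = report@signal@p,
                       nPermutations = report@signal@nPermutations)
  if (!is.null(report@disparity))
    out$disparity <- list(variances = as.list(report@disparity@variances),
                          foldDifference = report@disparity@foldDifference,
                          p = report@disparity@p)
  if (!is.null(report@rates))
    out$rates <- list(rates = as.list(report@rates@rates),
                      foldDifference = report@rates@foldDifference,
                      p = report@rates@p)
  if (length(report@models))
    out$models <- lapply(report@models, function(m)
      lapply(split(m@table, m@table$model),
             function(r) list(lnL = r$lnL, k = r$k, AICc = r$AICc,
                              dAICc = r$dAICc)))
  if (length(report@convergence))
    out$convergence <- lapply(report@convergence, function(cv)
      list(C = as.list(cv@C), p = as.list(cv@p), nSims = cv@nSims))
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}

#' @rdname reportJSON
#' @param dir output directory (created if needed).
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLandmarkCSV(report@aligned, file.path(dir, "aligned.csv"))
  sc <- data.frame(taxon = report@morphospace@taxonOrder,
                   report@morphospace@scores, check.names = FALSE)
  utils::write.csv(sc, file.path(dir, "scores.csv"), row.names = FALSE)
  if (!is.null(report@landscape)) {
    ls <- report@landscape
    utils::write.csv(
      data.frame(x = rep(ls@x, times = length(ls@y)),
                 y = rep(ls@y, each = length(ls@x)),
                 density = as.vector(ls@density)),
      file.path(dir, "landscape.csv"), row.names = FALSE)
  }
  if (!is.null(report@layout))
    writeLayoutCSV(report@layout, file.path(dir, "layout_points.csv"),
                   file.path(dir, "layout_edges.csv"))
  writeLines(reportJSON(report), file.path(dir, "report.json"))
  invisible(dir)
}
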