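# Synthetic fixtures with planted ground truth for the tracer,
# coexpression and metabolomics stages. Every generator is a pure function
# of its seed and parameters.

#' Simulate isotopologue measurements with known labeling
#'
#' Forward-convolves a planted labeling-fraction vector with the
#' natural-abundance correction matrix, scales to instrument-like
#' intensities and applies multiplicative log-normal noise. An unlabeled
#' companion set (all species M+0) is generated the same way, so the pair
#' can exercise both the matrix-correction and the paired
#' labeled-vs-unlabeled enrichment paths.
#'
#' @param trueFractions labeling fractions over M+0..M+n (sums to 1).
#' @param formula fragment formula (default the lysine TMS fragment
#'   is not assumed; plain `"C6H14N2O2"` lysine).
#' @param labelElement tracer element (default `"C"`).
#' @param noiseCV multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param nReplicates replicate count per condition (default 3).
#' @param scale mean M+0-pool intensity in instrument units.
#' @param compound compound label for the generated vectors.
#' @param seed RNG seed.
#' @return list with `labeled` and `unlabeled` (lists of
#'   [IsotopologueVector-class]), the correction `matrix`, and `truth`
#'   (planted fractions and parameters).
#' @export
makeIsotopologueFixtures <- function(trueFractions,
                                     formula = "C6H14N2O2",
                                     labelElement = "C",
                                     noiseCV = 0.05, nReplicates = 3,
                                     scale = 1e6, compound = "lysine",
                                     seed = 1) {
  if (any(trueFractions < 0)) stop("negative fractions", call. = FALSE)
  if (abs(sum(trueFractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  n <- length(trueFractions) - 1L
  cm <- correctionMatrix(formula, labelElement, n)
  unlabFrac <- c(1, rep(0, n))
  withSeed(seed, {
    gen <- function(frac) lapply(seq_len(nReplicates), function(i) {
      mu <- as.vector(cm %*% frac) * scale
      isotopologueVector(compound, mu * lognormNoise(length(mu), noiseCV),
                         formula = formula)
    })
    labeled <- gen(trueFractions)
    unlabeled <- gen(unlabFrac)
    list(labeled = labeled, unlabeled = unlabeled, matrix = cm,
         truth = list(fractions = trueFractions, formula = formula,
                      labelElement = labelElement, noiseCV = noiseCV,
                      scale = scale, seed = seed))
  })
}

#' Simulate an expression compendium with one planted coexpressed module
#'
#' Background genes are independent standard normals per condition; module
#' genes share a per-condition latent factor, giving pairwise Pearson
#' correlation approximately `moduleRho`. `nSmall` additional datasets are
#' generated with fewer conditions than the compendium filter admits, to
#' exercise it.
#'
#' @param nDatasets datasets passing the filter (default 8).
#' @param conditionsPerDataset conditions per retained dataset
#'   (default 15).
#' @param nGenes gene universe size (default 500).
#' @param moduleGenes planted module size (default 6).
#' @param moduleRho latent-factor pairwise correlation in `[0, 1)`
#'   (default 0.8).
#' @param nSmall undersized datasets added (default 2, at 8 conditions).
#' @param seed RNG seed.
#' @return list with `datasets` (named list of gene x condition matrices)
#'   and `truth` (module member ids, rho, parameters).
#' @export
makeCompendium <- function(nDatasets = 8, conditionsPerDataset = 15,
                           nGenes = 500, moduleGenes = 6,
                           moduleRho = 0.8, nSmall = 2, seed = 1) {
  stopifnot(moduleRho >= 0, moduleRho < 1)
  if (moduleGenes > nGenes)
    stop("module larger than gene universe", call. = FALSE)
  ids <- sprintf("g%04d", seq_len(nGenes))
  withSeed(seed, {
    module <- sort(sample(ids, moduleGenes))
    sizes <- c(rep(conditionsPerDataset, nDatasets),
               rep(8, nSmall))
    datasets <- lapply(seq_along(sizes), function(d) {
      nc <- sizes[d]
      m <- matrix(stats::rnorm(nGenes * nc), nGenes, nc,
                  dimnames = list(ids, NULL))
      latent <- stats::rnorm(nc)
      m[module, ] <- sqrt(moduleRho) * matrix(latent, moduleGenes, nc,
                                              byrow = TRUE) +
        sqrt(1 - moduleRho) * m[module, ]
      m
    })
    names(datasets) <- sprintf("ds%02d", seq_along(sizes))
    list(datasets = datasets,
         truth = list(module = module, rho = moduleRho,
                      undersized = names(datasets)[seq_len(nSmall) +
                                                     nDatasets],
                      seed = seed))
  })
}

#' Simulate a metabolite abundance table with planted fold changes
#'
#' Log-normal baseline abundances per metabolite, group-specific planted
#' fold changes, multiplicative replicate noise, and blank samples at a
#' configured fraction of signal.
#'
#' @param nMetabolites metabolite count (default 30).
#' @param groups group labels (default `c("WT", "dhgd-1")`); planted folds
#'   apply to the second group relative to the first.
#' @param plantedFC named numeric vector metabolite-id -> fold change
#'   (> 0); metabolites default to fold 1.
#' @param noiseCV replicate noise coefficient of variation (default 0.2,
#'   a typical biological-replicate spread for targeted GC-MS panels).
#' @param nReplicates replicates per group (default 5).
#' @param nBlanks blank samples (default 2).
#' @param blankFraction blank signal level relative to baseline
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list with `table` (an [AbundanceExperiment-class], raw) and
#'   `truth`.
#' @export
makeMetaboliteTable <- function(nMetabolites = 30,
                                groups = c("WT", "dhgd-1"),
                                plantedFC = numeric(), noiseCV = 0.2,
                                nReplicates = 5, nBlanks = 2,
                                blankFraction = 0.05, seed = 1) {
  if (nReplicates < 2) stop("need nReplicates >= 2", call. = FALSE)
  if (any(plantedFC <= 0)) stop("fold changes must be > 0", call. = FALSE)
  stopifnot(length(groups) == 2)
  mids <- sprintf("met%03d", seq_len(nMetabolites))
  unknown <- setdiff(names(plantedFC), mids)
  if (length(unknown))
    stop("plantedFC names not in metabolite panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  withSeed(seed, {
    baseline <- stats::rlnorm(nMetabolites, meanlog = 11.5, sdlog = 0.8)
    names(baseline) <- mids
    fold <- stats::setNames(rep(1, nMetabolites), mids)
    fold[names(plantedFC)] <- plantedFC
    cols <- list()
    group <- character()
    isBlank <- logical()
    for (g in seq_along(groups)) {
      gf <- if (g == 2) fold else rep(1, nMetabolites)
      for (i in seq_len(nReplicates)) {
        cols[[length(cols) + 1L]] <-
          baseline * gf * lognormNoise(nMetabolites, noiseCV)
        group <- c(group, groups[g])
        isBlank <- c(isBlank, FALSE)
      }
    }
    for (i in seq_len(nBlanks)) {
      cols[[length(cols) + 1L]] <-
        baseline * blankFraction * lognormNoise(nMetabolites, noiseCV)
      group <- c(group, "blank")
      isBlank <- c(isBlank, TRUE)
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- mids
    colnames(vals) <- make.unique(paste(group, "rep", sep = "_"),
                                  sep = "")
    table <- AbundanceExperiment(vals, group = group, isBlank = isBlank)
    list(table = table,
         truth = list(baseline = baseline, fold = fold,
                      planted = names(plantedFC), noiseCV = noiseCV,
                      blankFraction = blankFraction, seed = seed))
  })
}
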