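#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Constraint-based metabolic network model
#'
#' Holds a stoichiometric model in the usual constraint-based form: a set of
#' metabolites, a set of bounded reactions, and the stoichiometric matrix
#' linking them. Gene associations are stored as boolean gene-reaction rule
#' strings (e.g. `"mccc-1 and mccc-2"`), the convention used by COBRA-style
#' JSON model files such as the published C. elegans network iCEL1314.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`.
#' @slot reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`.
#' @slot stoichiometry numeric matrix (metabolites x reactions); a negative
#'   coefficient means the metabolite is consumed by the reaction.
#' @slot notes free-text provenance.
#'
#' @seealso [readNetworkModel()], [setReactionBounds()], [maximizeFlux()]
#' @export
setClass("MetabolicNetwork",
  representation(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "Matrix",
    notes         = "character"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment")
  need_rxn <- c("id", "name", "lower_bound", "upper_bound", "gene_rule",
                "subsystem")
  if (!all(need_met %in% names(met)))
    msgs <- c(msgs, "metabolites must have columns id, name, compartment")
  if (!all(need_rxn %in% names(rxn)))
    msgs <- c(msgs, paste("reactions must have columns",
                          paste(need_rxn, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(met$id))
    msgs <- c(msgs, paste0("duplicate metabolite id: ",
                           paste(unique(met$id[duplicated(met$id)]),
                                 collapse = ", ")))
  if (anyDuplicated(rxn$id))
    msgs <- c(msgs, paste0("duplicate reaction id: ",
                           paste(unique(rxn$id[duplicated(rxn$id)]),
                                 collapse = ", ")))
  if (any(!nzchar(met$id))) msgs <- c(msgs, "empty metabolite id")
  if (any(!nzchar(rxn$id))) msgs <- c(msgs, "empty reaction id")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, sprintf(
      "stoichiometry is %d x %d but model has %d metabolites and %d reactions",
      nrow(S), ncol(S), nrow(met), nrow(rxn)))
  else {
    if (!identical(rownames(S), met$id))
      msgs <- c(msgs, "stoichiometry rownames must equal metabolite ids")
    if (!identical(colnames(S), rxn$id))
      msgs <- c(msgs, "stoichiometry colnames must equal reaction ids")
    empty <- which(Matrix::colSums(S != 0) == 0)
    if (length(empty))
      msgs <- c(msgs, paste0("reaction with all-zero stoichiometry: ",
                             paste(rxn$id[empty], collapse = ", ")))
  }
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad))
    msgs <- c(msgs, paste0("lower_bound > upper_bound for reaction: ",
                           paste(rxn$id[bad], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Result of a single flux balance optimisation
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unsolved"`.
#' @slot objectiveReaction id of the maximised (or minimised) reaction.
#' @slot objectiveValue optimum in model flux units (`NA` unless optimal).
#' @slot fluxes named flux vector over all reactions (empty unless optimal).
#' @slot solverTolerance feasibility tolerance used to verify the solution.
#'
#' @export
setClass("FluxSolution",
  representation(
    status            = "character",
    objectiveReaction = "character",
    objectiveValue    = "numeric",
    fluxes            = "numeric",
    solverTolerance   = "numeric"
  )
)

#' Scenario-by-objective production potential table
#'
#' Output of [runB12Protocol()]: maximum attainable flux of each objective
#' (energy, acetoacetate, 3-hydroxybutyrate) under each cumulative knockout
#' scenario, in both B12-replete and low-B12 conditions. Infeasible cells are
#' recorded as such, not as zero.
#'
#' @slot table data.frame with columns `scenario`, `b12`, `objective`,
#'   `value`, `status`.
#' @slot baseline maximum biomass flux of the unperturbed model.
#' @slot lowB12Baseline maximum biomass flux with the methionine-synthase
#'   reaction capped at half its flux-variability maximum.
#' @slot msCap the methionine-synthase flux cap used in low-B12 scenarios.
#' @slot log ordered character log of every bound edit applied.
#'
#' @export
setClass("ProductionPotentialTable",
  representation(
    table          = "data.frame",
    baseline       = "numeric",
    lowB12Baseline = "numeric",
    msCap          = "numeric",
    log            = "character"
  )
)

#' Per-compound isotopologue intensity vector
#'
#' Ordered M+0 .. M+n intensities for one quantified fragment of one
#' compound, plus the elemental composition of the fragment (needed for
#' natural-abundance correction; derivatisation-added atoms such as TMS
#' groups must be included by the caller).
#'
#' @slot compound compound label.
#' @slot formula named integer vector, element symbol -> atom count.
#' @slot intensities non-negative numeric vector, M+0 first.
#' @slot corrected TRUE once natural-abundance correction has been applied
#'   (intensities are then fractions summing to 1).
#'
#' @export
setClass("IsotopologueVector",
  representation(
    compound    = "character",
    formula     = "numeric",
    intensities = "numeric",
    corrected   = "logical"
  )
)

setValidity("IsotopologueVector", function(object) {
  msgs <- character()
  if (any(object@intensities < 0)) msgs <- c(msgs, "negative intensity")
  if (length(object@intensities) < 1) msgs <- c(msgs, "empty intensity vector")
  if (length(msgs)) msgs else TRUE
})

#' Multi-dataset z-normalised expression compendium
#'
#' Genes x conditions matrix obtained by z-normalising each gene within each
#' contributing dataset and concatenating datasets column-wise over the union
#' of genes; a gene absent from a dataset carries `NA` in that dataset's
#' columns.
#'
#' @slot exprs numeric matrix, genes x pooled conditions.
#' @slot datasets data.frame with columns `id`, `n_conditions`, `retained`.
#' @slot droppedGenes named list of constant (zero-variance) gene ids dropped
#'   per dataset.
#'
#' @export
setClass("ExpressionCompendium",
  representation(
    exprs        = "matrix",
    datasets     = "data.frame",
    droppedGenes = "list"
  )
)

#' Metabolite abundance experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] with metabolites as rows
#' and samples as columns. `colData` carries `group`, `replicate` and
#' `is_blank`; metadata flags record whether blank subtraction and
#' total-metabolite normalisation have been applied.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msgs <- character()
  cd <- SummarizedExperiment::colData(object)
  for (col in c("group", "is_blank"))
    if (!col %in% names(cd)) msgs <- c(msgs, paste0("colData needs ", col))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'abundance' is required")
  else if (any(SummarizedExperiment::assay(object, "abundance") < 0,
               na.rm = TRUE))
    msgs <- c(msgs, "abundances must be non-negative")
  if (length(msgs)) msgs else TRUE
})
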