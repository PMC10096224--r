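#' Accessors for MetabolicNetwork objects
#'
#' @param x a [MetabolicNetwork-class] object.
#' @return `reactionIds`/`metaboliteIds` return character vectors;
#'   `nReactions`/`nMetabolites` integers; `stoichMatrix` the metabolite x
#'   reaction coefficient matrix; `reactionBounds` a data.frame with `id`,
#'   `lower_bound`, `upper_bound`; `geneRules` a named character vector of
#'   gene-reaction rules; `modelGenes` the sorted set of gene ids appearing
#'   in any rule.
#' @name MetabolicNetwork-accessors
NULL

#' @rdname MetabolicNetwork-accessors
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions$id)

#' @rdname MetabolicNetwork-accessors
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @rdname MetabolicNetwork-accessors
setMethod("nReactions", "MetabolicNetwork", function(x) nrow(x@reactions))

#' @rdname MetabolicNetwork-accessors
setMethod("nMetabolites", "MetabolicNetwork", function(x) nrow(x@metabolites))

#' @rdname MetabolicNetwork-accessors
setMethod("stoichMatrix", "MetabolicNetwork",
          function(x) as.matrix(x@stoichiometry))

#' @rdname MetabolicNetwork-accessors
setMethod("reactionBounds", "MetabolicNetwork", function(x)
  x@reactions[, c("id", "lower_bound", "upper_bound")])

#' @rdname MetabolicNetwork-accessors
setMethod("geneRules", "MetabolicNetwork", function(x)
  stats::setNames(x@reactions$gene_rule, x@reactions$id))

#' @rdname MetabolicNetwork-accessors
setMethod("modelGenes", "MetabolicNetwork", function(x) {
  g <- unique(unlist(lapply(x@reactions$gene_rule, ruleGenes)))
  sort(g)
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", nMetabolites(object), "metabolites x",
      nReactions(object), "reactions\n")
  g <- modelGenes(object)
  cat(" genes in rules:", length(g), "\n")
  if (nzchar(object@notes)) cat(" notes:", object@notes, "\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution for", object@objectiveReaction, "- status:",
      object@status, "\n")
  if (object@status == "optimal")
    cat(" objective value:", format(object@objectiveValue), "\n")
})

#' Accessors for ProductionPotentialTable objects
#'
#' @param x a [ProductionPotentialTable-class] object.
#' @return `potentialTable` returns the long-format scenario table;
#'   `constraintLog` the ordered log of bound edits.
#' @name ProductionPotentialTable-accessors
NULL

#' @rdname ProductionPotentialTable-accessors
setMethod("potentialTable", "ProductionPotentialTable", function(x) x@table)

#' @rdname ProductionPotentialTable-accessors
setMethod("constraintLog", "ProductionPotentialTable", function(x) x@log)

setMethod("show", "ProductionPotentialTable", function(object) {
  cat("ProductionPotentialTable (",
      length(unique(object@table$scenario)), " scenarios x ",
      length(unique(object@table$objective)), " objectives, both B12 states)\n",
      sep = "")
  cat(" biomass baseline:", format(object@baseline),
      "| low-B12 baseline:", format(object@lowB12Baseline), "\n")
  wide <- stats::reshape(
    object@table[, c("scenario", "b12", "objective", "value")],
    idvar = c("scenario", "b12"), timevar = "objective",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
})

#' Accessors for ExpressionCompendium objects
#'
#' @param x an [ExpressionCompendium-class] object.
#' @return `compendiumMatrix` returns the pooled genes x conditions matrix;
#'   `datasetInfo` the per-dataset bookkeeping table.
#' @name ExpressionCompendium-accessors
NULL

#' @rdname ExpressionCompendium-accessors
setMethod("compendiumMatrix", "ExpressionCompendium", function(x) x@exprs)

#' @rdname ExpressionCompendium-accessors
setMethod("datasetInfo", "ExpressionCompendium", function(x) x@datasets)

setMethod("show", "ExpressionCompendium", function(object) {
  cat("ExpressionCompendium:", nrow(object@exprs), "genes x",
      ncol(object@exprs), "pooled conditions from",
      sum(object@datasets$retained), "of", nrow(object@datasets),
      "datasets\n")
})

#' Accessors for IsotopologueVector objects
#'
#' @param x an [IsotopologueVector-class] object.
#' @return `intensities` returns the M+0..M+n vector; `isCorrected` the
#'   correction flag.
#' @name IsotopologueVector-accessors
NULL

#' @rdname IsotopologueVector-accessors
setMethod("intensities", "IsotopologueVector", function(x) x@intensities)

#' @rdname IsotopologueVector-accessors
setMethod("isCorrected", "IsotopologueVector", function(x) x@corrected)

setMethod("show", "IsotopologueVector", function(object) {
  n <- length(object@intensities) - 1L
  cat("IsotopologueVector:", object@compound, " M+0..M+", n,
      if (object@corrected) " (corrected fractions)" else " (raw)", "\n",
      sep = "")
  v <- object@intensities
  names(v) <- paste0("M+", 0:n)
  print(v)
})
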