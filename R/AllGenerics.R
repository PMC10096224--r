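#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("reactionBounds", function(x) standardGeneric("reactionBounds"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("geneRules", function(x) standardGeneric("geneRules"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' @rdname ProductionPotentialTable-accessors
#' @export
setGeneric("potentialTable", function(x) standardGeneric("potentialTable"))

#' @rdname ProductionPotentialTable-accessors
#' @export
setGeneric("constraintLog", function(x) standardGeneric("constraintLog"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("compendiumMatrix", function(x) standardGeneric("compendiumMatrix"))

#' @rdname ExpressionCompendium-accessors
#' @export
setGeneric("datasetInfo", function(x) standardGeneric("datasetInfo"))

#' @rdname IsotopologueVector-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname IsotopologueVector-accessors
#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))
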