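# Reading, writing, validating and editing constraint-based models.

# COBRA convention: "unbounded" reactions are given +/- 1000 model flux
# units so every linear program stays bounded.
BOUND_SENTINEL <- 1000

clampBound <- function(b, default) {
  b <- suppressWarnings(as.numeric(b))
  if (length(b) != 1 || is.na(b)) return(default)
  if (!is.finite(b)) return(sign(b) * BOUND_SENTINEL)
  if (abs(b) >= 1e6) return(sign(b) * BOUND_SENTINEL)
  b
}

#' Construct a MetabolicNetwork from its parts
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (missing `name`/`compartment` are filled with the id / `""`).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound` and optionally `name`, `gene_rule`, `subsystem`.
#' @param stoichiometry named list (reaction id -> named coefficient vector
#'   over metabolite ids) or a full metabolite x reaction matrix.
#' @param notes free-text provenance string.
#'
#' @return a validated [MetabolicNetwork-class].
#' @examples
#' m <- newMetabolicNetwork(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("up", "conv", "out"),
#'                          lower_bound = 0, upper_bound = c(10, 1000, 1000)),
#'   stoichiometry = list(up = c(A = 1), conv = c(A = -1, B = 1),
#'                        out = c(B = -1)))
#' @export
newMetabolicNetwork <- function(metabolites, reactions, stoichiometry,
                                notes = "") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$lower_bound <- vapply(reactions$lower_bound, clampBound,
                                  numeric(1), default = -BOUND_SENTINEL)
  reactions$upper_bound <- vapply(reactions$upper_bound, clampBound,
                                  numeric(1), default = BOUND_SENTINEL)
  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      unknown <- setdiff(names(coefs), metabolites$id)
      if (length(unknown))
        stop("reaction '", rid, "' references unknown metabolite(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      if (!rid %in% reactions$id)
        stop("stoichiometry given for unknown reaction '", rid, "'",
             call. = FALSE)
      S[names(coefs), rid] <- coefs
    }
  } else {
    S <- as.matrix(stoichiometry)
    rownames(S) <- metabolites$id
    colnames(S) <- reactions$id
  }
  obj <- new("MetabolicNetwork",
             metabolites = metabolites[, c("id", "name", "compartment")],
             reactions = reactions[, c("id", "name", "lower_bound",
                                       "upper_bound", "gene_rule",
                                       "subsystem")],
             stoichiometry = Matrix::Matrix(S, sparse = TRUE),
             notes = notes)
  validObject(obj)
  obj
}

#' Read a constraint-based model file
#'
#' Reads the COBRA-compatible JSON dialect (lists of metabolite and reaction
#' records with `lower_bound`/`upper_bound`/`gene_reaction_rule` keys), in
#' which the published iCEL1314 model from WormFlux loads unmodified. An
#' SBML Level 3 FBC reader is provided as best effort.
#'
#' Non-finite or very large (`|b| >= 1e6`) bounds are mapped to the +/-1000
#' sentinel so the flux polytope stays bounded.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @return a validated [MetabolicNetwork-class].
#' @export
readNetworkModel <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "json") readModelJSON(path) else readModelSBML(path)
}

readModelJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a COBRA-style JSON model (missing 'metabolites'/'reactions'): ",
         path, call. = FALSE)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), ""),
    name = vapply(doc$metabolites,
                  function(m) as.character(m$name %||% m$id), ""),
    compartment = vapply(doc$metabolites,
                         function(m) as.character(m$compartment %||% ""), ""),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), ""),
    name = vapply(doc$reactions,
                  function(r) as.character(r$name %||% r$id), ""),
    lower_bound = vapply(doc$reactions, function(r)
      clampBound(r$lower_bound, -BOUND_SENTINEL), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r)
      clampBound(r$upper_bound, BOUND_SENTINEL), numeric(1)),
    gene_rule = vapply(doc$reactions, function(r)
      as.character(r$gene_reaction_rule %||% ""), ""),
    subsystem = vapply(doc$reactions, function(r)
      as.character(r$subsystem %||% ""), ""),
    stringsAsFactors = FALSE)
  stoich <- lapply(doc$reactions, function(r) {
    coefs <- unlist(r$metabolites)
    if (is.null(coefs)) stop("reaction '", r$id,
                             "' has empty stoichiometry", call. = FALSE)
    coefs
  })
  names(stoich) <- rxns$id
  notes <- as.character(doc$id %||% "")
  newMetabolicNetwork(mets, rxns, stoich, notes = notes)
}

#' Write a model in the COBRA-compatible JSON dialect
#'
#' `readNetworkModel(writeNetworkModel(m, f))` round-trips field by field.
#'
#' @param model a [MetabolicNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkModel <- function(model, path) {
  stopifnot(is(model, "MetabolicNetwork"))
  S <- stoichMatrix(model)
  mets <- lapply(seq_len(nMetabolites(model)), function(i)
    list(id = model@metabolites$id[i],
         name = model@metabolites$name[i],
         compartment = model@metabolites$compartment[i]))
  rxns <- lapply(seq_len(nReactions(model)), function(j) {
    col <- S[, j]
    col <- col[col != 0]
    list(id = model@reactions$id[j],
         name = model@reactions$name[j],
         metabolites = as.list(col),
         lower_bound = model@reactions$lower_bound[j],
         upper_bound = model@reactions$upper_bound[j],
         gene_reaction_rule = model@reactions$gene_rule[j],
         subsystem = model@reactions$subsystem[j])
  })
  doc <- list(id = model@notes, metabolites = mets, reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Best-effort SBML Level 3 FBC reader: species, reactions with
# speciesReference stoichiometries, fbc bound parameters and
# geneProductAssociation trees. XPath queries go through local-name() and
# attributes are matched prefix-insensitively, so the reader is agnostic to
# namespace prefixes.
readModelSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ln <- function(parent, nm) paste0(parent, "*[local-name()='", nm, "']")
  attrAny <- function(node, nm) {
    a <- xml2::xml_attrs(node)
    hit <- which(names(a) == nm | sub("^.*:", "", names(a)) == nm)
    if (length(hit)) a[[hit[1]]] else NA_character_
  }
  params <- xml2::xml_find_all(doc, paste0(".//", ln("", "parameter")))
  pvals <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(params, "value"))),
    xml2::xml_attr(params, "id"))
  spp <- xml2::xml_find_all(doc, paste0(".//", ln("", "species")))
  keep <- xml2::xml_attr(spp, "boundaryCondition") %in% c(NA, "false")
  spp <- spp[keep]
  mets <- data.frame(
    id = xml2::xml_attr(spp, "id"),
    name = ifelse(is.na(xml2::xml_attr(spp, "name")),
                  xml2::xml_attr(spp, "id"), xml2::xml_attr(spp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(spp, "compartment")), "",
                         xml2::xml_attr(spp, "compartment")),
    stringsAsFactors = FALSE)
  rnodes <- xml2::xml_find_all(
    doc, paste0(".//", ln("", "listOfReactions"), "/", ln("", "reaction")))
  gpaString <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(attrAny(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpaString, character(1))
    parts <- parts[nzchar(parts)]
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  stoich <- list()
  rxns <- do.call(rbind, lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lbRef <- attrAny(rn, "lowerFluxBound")
    ubRef <- attrAny(rn, "upperFluxBound")
    lb <- if (!is.na(lbRef) && lbRef %in% names(pvals)) pvals[[lbRef]]
          else if (rev) -BOUND_SENTINEL else 0
    ub <- if (!is.na(ubRef) && ubRef %in% names(pvals)) pvals[[ubRef]]
          else BOUND_SENTINEL
    coefs <- numeric()
    addCoef <- function(s, k) {
      prev <- if (s %in% names(coefs)) coefs[[s]] else 0
      coefs[s] <<- prev + k
    }
    for (sr in xml2::xml_find_all(rn, paste0(
      "./", ln("", "listOfReactants"), "/", ln("", "speciesReference")))) {
      s <- xml2::xml_attr(sr, "species")
      k <- suppressWarnings(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      if (s %in% mets$id) addCoef(s, -k)
    }
    for (sr in xml2::xml_find_all(rn, paste0(
      "./", ln("", "listOfProducts"), "/", ln("", "speciesReference")))) {
      s <- xml2::xml_attr(sr, "species")
      k <- suppressWarnings(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      if (s %in% mets$id) addCoef(s, k)
    }
    gpa <- xml2::xml_find_first(
      rn, paste0("./", ln("", "geneProductAssociation"), "/*"))
    rule <- if (inherits(gpa, "xml_missing")) "" else gpaString(gpa)
    rule <- gsub("^\\((.*)\\)$", "\\1", rule)
    stoich[[rid]] <<- coefs
    data.frame(id = rid,
               name = ifelse(is.na(xml2::xml_attr(rn, "name")), rid,
                             xml2::xml_attr(rn, "name")),
               lower_bound = clampBound(lb, -BOUND_SENTINEL),
               upper_bound = clampBound(ub, BOUND_SENTINEL),
               gene_rule = rule, subsystem = "",
               stringsAsFactors = FALSE)
  }))
  modelId <- xml2::xml_attr(
    xml2::xml_find_first(doc, paste0(".//", ln("", "model"))), "id")
  newMetabolicNetwork(mets, rxns, stoich,
                      notes = if (is.na(modelId)) "" else modelId)
}

#' Validate a model, reporting every structural defect
#'
#' Runs the class validity checks (unique ids, stoichiometry referencing only
#' known metabolites, lower <= upper bounds, no all-zero reaction columns)
#' and either returns the model invisibly or throws a structured error
#' listing every defect found.
#'
#' @param model a [MetabolicNetwork-class].
#' @return the model, invisibly, when valid.
#' @export
validateNetworkModel <- function(model) {
  validObject(model)
  invisible(model)
}

reactionIndex <- function(model, id) {
  i <- match(id, model@reactions$id)
  if (is.na(i))
    stop("unknown reaction id: '", id, "'", call. = FALSE)
  i
}

#' Edit the flux bounds of one reaction
#'
#' @param model a [MetabolicNetwork-class].
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` keeps the current value.
#' @return the edited model; all other reactions untouched.
#' @examples
#' # make the glyoxylate-analog irreversible / block propionate secretion
#' # m <- setReactionBounds(m, "RM00479", lower = 0)
#' # m <- setReactionBounds(m, "EX00163", upper = 0)
#' @export
setReactionBounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- reactionIndex(model, id)
  lb <- if (is.null(lower)) model@reactions$lower_bound[i] else lower
  ub <- if (is.null(upper)) model@reactions$upper_bound[i] else upper
  if (lb > ub)
    stop("lower bound (", lb, ") exceeds upper bound (", ub,
         ") for reaction '", id, "'", call. = FALSE)
  model@reactions$lower_bound[i] <- lb
  model@reactions$upper_bound[i] <- ub
  model
}

#' Constrain reactions to zero flux
#'
#' Sets `lower = upper = 0` for every listed reaction (in-silico reaction
#' knockout; idempotent, and a no-op for an empty list).
#'
#' @param model a [MetabolicNetwork-class].
#' @param ids character vector of reaction ids.
#' @return the edited model.
#' @export
knockoutReactions <- function(model, ids) {
  for (id in ids) {
    i <- reactionIndex(model, id)
    model@reactions$lower_bound[i] <- 0
    model@reactions$upper_bound[i] <- 0
  }
  model
}

#' Fix a reaction flux at an exact value
#'
#' Sets `lower = upper = value`. The value may lie outside the reaction's
#' previous bounds (protocols tighten and relax bounds freely); the solver
#' may then report infeasibility.
#'
#' @param model a [MetabolicNetwork-class].
#' @param id reaction id.
#' @param value flux value, model units.
#' @return the edited model.
#' @export
fixFlux <- function(model, id, value) {
  i <- reactionIndex(model, id)
  model@reactions$lower_bound[i] <- value
  model@reactions$upper_bound[i] <- value
  model
}

#' Restrict a gene to a subset of its reactions
#'
#' Removes `gene` from the gene-reaction rule of every reaction not in
#' `keep`, simplifying the boolean rules as it goes (the pre-simulation
#' model edit that associates HPHD-1 solely with 3HP oxidation). Reactions
#' whose rule becomes empty are reported via the `"emptiedRules"` attribute.
#' Stoichiometry and bounds are never touched.
#'
#' @param model a [MetabolicNetwork-class].
#' @param gene gene id; must occur in at least one rule.
#' @param keep character vector of reaction ids allowed to keep the gene.
#' @return the edited model, with attribute `emptiedRules`.
#' @export
restrictGeneToReactions <- function(model, gene, keep) {
  carriers <- vapply(model@reactions$gene_rule,
                     function(r) gene %in% ruleGenes(r), logical(1))
  if (!any(carriers))
    stop("gene '", gene, "' absent from model; genes present: ",
         paste(modelGenes(model), collapse = ", "), call. = FALSE)
  unknown <- setdiff(keep, model@reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s) in keep list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  emptied <- character()
  for (i in which(carriers)) {
    rid <- model@reactions$id[i]
    if (rid %in% keep) next
    tree <- dropGeneFromTree(parseGeneRule(model@reactions$gene_rule[i]),
                             gene)
    newRule <- deparseGeneRule(tree)
    if (!nzchar(newRule)) emptied <- c(emptied, rid)
    model@reactions$gene_rule[i] <- newRule
  }
  attr(model, "emptiedRules") <- emptied
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
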