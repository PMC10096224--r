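# Toy metabolic network generator.
#
# A miniature, fully analysable stand-in for the genome-scale C. elegans
# network: bacterial food digestion releasing propionate as an obligatory
# byproduct, the canonical B12-dependent propionate route (methylmalonyl-CoA
# mutase analog), the 5-step propionate shunt with the HPHD-1/DHGD-1
# alpha-ketoglutarate <-> D-2-hydroxyglutarate couple (3HP oxidation
# consumes aKG and yields D-2HG 1:1 with malonic semialdehyde; a separate
# recycling reaction regenerates aKG, so knocking out recycling starves the
# couple and kills shunt flux emergently), ketogenic lysine and leucine
# degradation, ketone-body interconversion and oxidation, an oxygen-limited
# respiratory budget, ATP demand, and a biomass analog. Every
# production-potential value of the simulation protocol on this network has
# a closed-form bottleneck expression, which is stored as planted truth.

#' Parameters of the toy metabolic network
#'
#' Defaults define the reference study conditions used throughout the test
#' suite. Flux units are arbitrary but consistent.
#'
#' @param food bacterial food uptake bound (default 10); each unit digested
#'   on the efficient route yields 1 nutrient (2 ATP) and releases 0.5
#'   propionate that must be disposed of.
#' @param propionate supplemental propionate uptake bound (default 4).
#' @param lysine,leucine amino-acid uptake bounds (default 2 each).
#' @param oxygen respiratory oxygen budget (default 25); every ATP produced
#'   costs one oxygen, capping total energy yield.
#' @param biomassCap upper bound of the biomass analog (default 5 ATP
#'   units).
#' @param maintenance growth-independent maintenance energy demand, the
#'   lower bound of the ATP demand reaction (default 0).
#' @param b12Available when `FALSE` the generated model ships with the
#'   mutase analog closed and the methionine-synthase analog halved
#'   (low-B12 bounds baked in).
#' @param biomassRequiresMet couple the biomass analog to methionine from
#'   the methionine-synthase (MS) analog. With the default `metUptake` of
#'   9.1 the MS flux-variability maximum is 9.1, so capping MS at half
#'   (4.55) lowers the biomass potential from 5 to 4.55 -- the ~9 percent
#'   low-B12 biomass reduction the genome-scale C. elegans model exhibits.
#' @param metUptake methionine-precursor uptake bound (default 9.1).
#' @return a named list of class `"toyNetworkSpec"`.
#' @export
toyNetworkSpec <- function(food = 10, propionate = 4, lysine = 2,
                           leucine = 2, oxygen = 25, biomassCap = 5,
                           maintenance = 0, b12Available = TRUE,
                           biomassRequiresMet = FALSE, metUptake = 9.1) {
  spec <- list(food = food, propionate = propionate, lysine = lysine,
               leucine = leucine, oxygen = oxygen, biomassCap = biomassCap,
               maintenance = maintenance, b12Available = b12Available,
               biomassRequiresMet = biomassRequiresMet,
               metUptake = metUptake)
  if (any(unlist(spec[1:7]) < 0)) stop("bounds must be >= 0", call. = FALSE)
  class(spec) <- "toyNetworkSpec"
  spec
}

# Closed-form production potentials. Every substrate converts to ATP and to
# acetoacetate at a fixed exchange rate of 0.5 acetoacetate per ATP
# foregone (lysine: 2 ATP or 1 AcAc; leucine: 3 ATP or 1.5 AcAc;
# propionate-derived acetyl-CoA: 1 ATP or 0.5 AcAc), which makes the
# optimum a bottleneck arithmetic, not a numerical LP.
toyTruthTable <- function(spec) {
  F <- spec$food; P <- spec$propionate; K <- spec$lysine; L <- spec$leucine
  O <- spec$oxygen; B <- spec$biomassCap; M <- spec$maintenance
  sRep <- 2 * F + (0.5 * F + P) + 2 * K + 3 * L
  baseline <- min(B, min(O, sRep) - M)
  if (spec$biomassRequiresMet) baseline <- min(baseline, spec$metUptake)
  if (baseline <= 0)
    stop("infeasible toy-network spec: maintenance demand exceeds ",
         "achievable ATP", call. = FALSE)
  lowB12 <- if (spec$biomassRequiresMet)
    min(baseline, 0.5 * spec$metUptake) else baseline
  Bbg <- lowB12
  rows <- list()
  for (b12 in c("replete", "low")) {
    for (sc in c("WT", "dhgd-1 KO", "dhgd-1+aass-1 KO",
                 "dhgd-1+aass-1+mccc-1 KO")) {
      dhgdKO <- sc != "WT"
      aassOpen <- !sc %in% c("dhgd-1+aass-1 KO", "dhgd-1+aass-1+mccc-1 KO")
      mcccOpen <- sc != "dhgd-1+aass-1+mccc-1 KO"
      propOpen <- (b12 == "replete" && spec$b12Available) || !dhgdKO
      propPool <- if (propOpen) 0.5 * F + P else 0
      sAtp <- (if (propOpen) 2 * F else 0.5 * F) + propPool +
        2 * K * aassOpen + 3 * L * mcccOpen
      foodAtp <- if (propOpen) 2 * F else 0.5 * F
      cap <- min(O, sAtp)
      energyOK <- cap >= Bbg + M
      energy <- if (energyOK) cap - Bbg else NA_real_
      A <- K * aassOpen + 1.5 * L * mcccOpen + 0.5 * propPool
      deficit <- max(0, (Bbg + M) - min(O - 0, foodAtp))
      acacOK <- energyOK && 0.5 * deficit <= A + 1e-12
      acac <- if (acacOK) A - 0.5 * deficit else NA_real_
      for (ob in c("energy", "acetoacetate", "bhb")) {
        v <- switch(ob, energy = energy, acac)
        ok <- switch(ob, energy = energyOK, acacOK)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, b12 = b12, objective = ob, value = v,
          status = if (ok) "optimal" else "infeasible",
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$scenario <- factor(tab$scenario,
                         levels = c("WT", "dhgd-1 KO", "dhgd-1+aass-1 KO",
                                    "dhgd-1+aass-1+mccc-1 KO"))
  tab$b12 <- factor(tab$b12, levels = c("replete", "low"))
  list(baseline = baseline, lowB12Baseline = lowB12,
       msCap = 0.5 * spec$metUptake, table = tab)
}

#' Generate the toy metabolic network with planted truth
#'
#' See [toyNetworkSpec()] for the tunable study conditions. The returned
#' truth holds the closed-form biomass baselines and the full
#' production-potential table expected from [runB12Protocol()] with
#' [toyIdMap()].
#'
#' @param spec a [toyNetworkSpec()].
#' @return list with elements `model` (a validated
#'   [MetabolicNetwork-class]) and `truth` (baselines plus the expected
#'   scenario table).
#' @examples
#' toy <- makeToyNetwork()
#' toy$model
#' head(toy$truth$table)
#' @export
makeToyNetwork <- function(spec = toyNetworkSpec()) {
  stopifnot(inherits(spec, "toyNetworkSpec"))
  mets <- data.frame(
    id = c("food", "nutr", "prop", "succ", "accoa", "atp", "o2",
           "threehp", "msa", "akg", "d2hg", "lys", "aad", "glt",
           "acac", "bhb", "leu", "metin", "met"),
    name = c("bacterial food", "generic nutrient", "propionate",
             "succinate", "acetyl-CoA", "ATP", "oxygen",
             "3-hydroxypropionate", "malonic semialdehyde",
             "alpha-ketoglutarate", "D-2-hydroxyglutarate", "lysine",
             "2-aminoadipate", "glutarate", "acetoacetate",
             "3-hydroxybutyrate", "leucine", "methionine precursor",
             "methionine"),
    compartment = "c", stringsAsFactors = FALSE)

  U <- BOUND_SENTINEL
  r <- function(id, name, stoich, lb = 0, ub = U, gene = "", sub = "")
    list(id = id, name = name, stoich = stoich, lb = lb, ub = ub,
         gene = gene, sub = sub)
  msUb <- if (spec$b12Available) U else 0.5 * spec$metUptake
  mutUb <- if (spec$b12Available) U else 0
  bioStoich <- if (spec$biomassRequiresMet)
    c(atp = -1, met = -1) else c(atp = -1)
  defs <- list(
    r("R_EX_FOOD", "bacterial food intake", c(food = 1),
      ub = spec$food, sub = "exchange"),
    r("R_DIGEST", "food digestion (propionate-releasing)",
      c(food = -1, nutr = 1, prop = 0.5), sub = "digestion"),
    r("R_DIGEST_ALT", "food digestion (inefficient, propionate-free)",
      c(food = -1, nutr = 0.25), sub = "digestion"),
    r("R_NUTR_OX", "nutrient oxidation", c(nutr = -1, o2 = -2, atp = 2),
      sub = "energy"),
    r("R_EX_O2", "oxygen intake", c(o2 = 1), ub = spec$oxygen,
      sub = "exchange"),
    r("R_EX_PROP", "propionate uptake", c(prop = 1),
      ub = spec$propionate, sub = "exchange"),
    r("R_EX_PROPSEC", "propionate secretion", c(prop = -1),
      sub = "exchange"),
    r("R_MUT", "canonical propionate route (B12-dependent mutase)",
      c(prop = -1, succ = 1), ub = mutUb, gene = "mmcm-1",
      sub = "propionate canonical"),
    r("R_TCA", "succinate oxidation (TCA)", c(succ = -1, o2 = -1, atp = 1),
      sub = "energy"),
    r("R_GLYX", "glyoxylate shunt analog", c(succ = -1, accoa = 1),
      lb = -U, sub = "glyoxylate"),
    r("R_PCT", "propionate to 3-hydroxypropionate (shunt entry)",
      c(prop = -1, threehp = 1), gene = "acdh-1 and ech-6",
      sub = "propionate shunt"),
    r("R_HPHD", "3HP oxidation coupled to aKG reduction (HPHD-1)",
      c(threehp = -1, akg = -1, msa = 1, d2hg = 1), gene = "hphd-1",
      sub = "propionate shunt"),
    r("R_DHGD", "D-2HG oxidation back to aKG (DHGD-1)",
      c(d2hg = -1, akg = 1), gene = "dhgd-1", sub = "propionate shunt"),
    r("R_MSA", "malonic semialdehyde to acetyl-CoA",
      c(msa = -1, accoa = 1), gene = "alh-8 or hphd-1",
      sub = "propionate shunt"),
    r("R_OX_ACCOA", "acetyl-CoA oxidation", c(accoa = -1, o2 = -1, atp = 1),
      sub = "energy"),
    r("R_EX_LYS", "lysine uptake", c(lys = 1), ub = spec$lysine,
      sub = "exchange"),
    r("R_AASS", "lysine degradation entry (AASS-1)", c(lys = -1, aad = 1),
      gene = "aass-1", sub = "lysine degradation"),
    r("R_GCDH", "2-aminoadipate to glutarate", c(aad = -1, glt = 1),
      gene = "gcdh-1", sub = "lysine degradation"),
    r("R_KB_LYS", "glutarate to acetoacetate", c(glt = -1, acac = 1),
      gene = "kat-1", sub = "lysine degradation"),
    r("R_EX_LEU", "leucine uptake", c(leu = 1), ub = spec$leucine,
      sub = "exchange"),
    r("R_MCCC", "leucine degradation (MCCC complex)",
      c(leu = -1, accoa = 1, acac = 1), gene = "mccc-1 and mccc-2",
      sub = "leucine degradation"),
    r("R_KETOGEN", "ketogenesis from acetyl-CoA",
      c(accoa = -2, acac = 1), gene = "hmgs-1 and hmgl-1",
      sub = "ketone bodies"),
    r("R_KB_OX", "acetoacetate oxidation to acetyl-CoA",
      c(acac = -1, accoa = 2), sub = "ketone bodies"),
    r("R_BDH", "3-hydroxybutyrate dehydrogenase",
      c(acac = -1, bhb = 1), lb = -U, gene = "bdh-1",
      sub = "ketone bodies"),
    r("R_EX_AA", "acetoacetate export", c(acac = -1), sub = "exchange"),
    r("R_EX_BHB", "3-hydroxybutyrate export", c(bhb = -1),
      sub = "exchange"),
    r("R_ATPM", "energy demand (ATP maintenance)", c(atp = -1),
      lb = spec$maintenance, sub = "energy"),
    r("R_BIO", "biomass analog", bioStoich, ub = spec$biomassCap,
      sub = "biomass"),
    r("R_EX_MET", "methionine precursor uptake", c(metin = 1),
      ub = spec$metUptake, sub = "exchange"),
    r("R_MS", "methionine synthase analog (B12-dependent)",
      c(metin = -1, met = 1), ub = msUb, gene = "metr-1",
      sub = "one-carbon"),
    r("R_MET_SINK", "methionine sink", c(met = -1), sub = "exchange"))

  rxns <- data.frame(
    id = vapply(defs, `[[`, "", "id"),
    name = vapply(defs, `[[`, "", "name"),
    lower_bound = vapply(defs, `[[`, 0, "lb"),
    upper_bound = vapply(defs, `[[`, 0, "ub"),
    gene_rule = vapply(defs, `[[`, "", "gene"),
    subsystem = vapply(defs, `[[`, "", "sub"),
    stringsAsFactors = FALSE)
  stoich <- stats::setNames(lapply(defs, `[[`, "stoich"), rxns$id)
  model <- newMetabolicNetwork(mets, rxns, stoich,
                               notes = "b12flux toy propionate network")
  list(model = model, truth = toyTruthTable(spec))
}
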