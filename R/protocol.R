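# The cumulative low-B12 / knockout simulation protocol.
#
# Roles are injected via a role -> reaction id map so that the same protocol
# drives both the genome-scale C. elegans network (iCEL1314 ids, the
# defaults) and the bundled toy network.

PROTOCOL_ROLES <- c("biomass", "ms", "mutase", "glyoxylate",
                    "propionate_secretion", "dhgd", "aass", "mccc",
                    "energy", "acetoacetate_export", "bhb_export")

#' Role-to-reaction id maps for the simulation protocol
#'
#' `defaultIdMap()` carries the iCEL1314 reaction ids: biomass `BIO0107`,
#' methionine synthase `RC00946`, methylmalonyl-CoA mutase `RM00833`,
#' glyoxylate shunt `RM00479`, propionate secretion `EX00163`, DHGD-1
#' `RM03534`, lysine degradation entry (AASS-1) `RM00716`,
#' methylcrotonyl-CoA carboxylase (MCCC) `RM04138`, energy demand `RCC0005`,
#' acetoacetate export `EX00164` and 3-hydroxybutyrate export `EX03197`.
#' `toyIdMap()` maps the same roles onto the bundled toy network of
#' [makeToyNetwork()].
#'
#' @return named character vector, role -> reaction id.
#' @export
defaultIdMap <- function() {
  c(biomass = "BIO0107", ms = "RC00946", mutase = "RM00833",
    glyoxylate = "RM00479", propionate_secretion = "EX00163",
    dhgd = "RM03534", aass = "RM00716", mccc = "RM04138",
    energy = "RCC0005", acetoacetate_export = "EX00164",
    bhb_export = "EX03197")
}

#' @rdname defaultIdMap
#' @export
toyIdMap <- function() {
  c(biomass = "R_BIO", ms = "R_MS", mutase = "R_MUT",
    glyoxylate = "R_GLYX", propionate_secretion = "R_EX_PROPSEC",
    dhgd = "R_DHGD", aass = "R_AASS", mccc = "R_MCCC",
    energy = "R_ATPM", acetoacetate_export = "R_EX_AA",
    bhb_export = "R_EX_BHB")
}

checkIdMap <- function(model, idMap, roles = PROTOCOL_ROLES) {
  missingRoles <- setdiff(roles, names(idMap))
  if (length(missingRoles))
    stop("id map is missing role(s): ",
         paste(missingRoles, collapse = ", "), call. = FALSE)
  absent <- idMap[roles][!idMap[roles] %in% reactionIds(model)]
  if (length(absent))
    stop("id map names reaction(s) absent from the model: ",
         paste(sprintf("%s (%s)", absent, names(absent)), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Apply the base simulation constraints
#'
#' Makes the glyoxylate shunt irreversible (lower bound 0) and prevents
#' propionate secretion (upper bound 0). The model's own dietary-intake and
#' growth-independent maintenance constraints are left exactly as shipped.
#' Idempotent.
#'
#' @param model a [MetabolicNetwork-class].
#' @param idMap role -> reaction id map; see [defaultIdMap()].
#' @return the edited model.
#' @export
applyBaseConstraints <- function(model, idMap = defaultIdMap()) {
  checkIdMap(model, idMap, c("glyoxylate", "propionate_secretion"))
  model <- setReactionBounds(model, idMap[["glyoxylate"]], lower = 0)
  setReactionBounds(model, idMap[["propionate_secretion"]], upper = 0)
}

#' Establish the background metabolic activity level
#'
#' Maximises biomass, then repeats the maximisation with the methionine
#' synthase (MS) reaction capped at `msFraction` of its flux-variability
#' maximum at the biomass optimum (the low-B12 biomass potential; on the
#' genome-scale network this cap lowers biomass by about 9 percent). The
#' returned model enforces the low-B12 biomass level as a lower bound on the
#' biomass reaction for all subsequent simulations, with the MS cap removed.
#'
#' @param model a [MetabolicNetwork-class], normally after
#'   [applyBaseConstraints()].
#' @param idMap role -> reaction id map.
#' @param msFraction fraction of the MS flux-variability maximum retained
#'   under low B12 (default 0.5).
#' @param tolerance solver tolerance.
#' @return list with elements `model` (biomass lower bound installed),
#'   `baseline`, `lowB12Baseline` and `msCap`.
#' @export
computeBackgroundActivity <- function(model, idMap = defaultIdMap(),
                                      msFraction = 0.5, tolerance = 1e-9) {
  checkIdMap(model, idMap, c("biomass", "ms"))
  bioId <- idMap[["biomass"]]
  msId <- idMap[["ms"]]
  base <- maximizeFlux(model, bioId, tolerance = tolerance)
  if (base@status != "optimal")
    stop("biomass maximisation failed: status ", base@status, call. = FALSE)
  baseline <- base@objectiveValue
  msMax <- maxFluxAtObjectiveFraction(model, msId, bioId, fraction = 1,
                                      tolerance = tolerance)
  msCap <- msFraction * msMax
  i <- reactionIndex(model, msId)
  capped <- setReactionBounds(model, msId,
                              lower = min(model@reactions$lower_bound[i],
                                          msCap),
                              upper = msCap)
  low <- maximizeFlux(capped, bioId, tolerance = tolerance)
  if (low@status != "optimal")
    stop("low-B12 biomass maximisation failed: status ", low@status,
         call. = FALSE)
  lowB12Baseline <- low@objectiveValue
  out <- setReactionBounds(model, bioId, lower = lowB12Baseline)
  list(model = out, baseline = baseline,
       lowB12Baseline = lowB12Baseline, msCap = msCap)
}

#' Impose the low-B12 condition
#'
#' Caps the methionine synthase reaction at `msCap` and fixes the
#' methylmalonyl-CoA mutase reaction at zero flux, disabling the canonical
#' B12-dependent propionate route. Idempotent.
#'
#' @param model a [MetabolicNetwork-class].
#' @param idMap role -> reaction id map.
#' @param msCap MS flux cap (from [computeBackgroundActivity()]).
#' @return the edited model.
#' @export
applyLowB12 <- function(model, idMap = defaultIdMap(), msCap) {
  checkIdMap(model, idMap, c("ms", "mutase"))
  stopifnot(msCap >= 0)
  i <- reactionIndex(model, idMap[["ms"]])
  model <- setReactionBounds(model, idMap[["ms"]],
                             lower = min(model@reactions$lower_bound[i],
                                         msCap),
                             upper = msCap)
  fixFlux(model, idMap[["mutase"]], 0)
}

#' Run the full cumulative knockout protocol
#'
#' Applies the base constraints, establishes the background biomass level,
#' and then, for both B12 states (replete and low), runs four cumulative
#' scenarios -- wild type; DHGD-1 reaction knocked out; additionally the
#' lysine-degradation entry (AASS-1); additionally methylcrotonyl-CoA
#' carboxylase (MCCC) -- each inheriting all constraints of the previous
#' one. In every scenario the fluxes of the energy, acetoacetate and
#' 3-hydroxybutyrate objectives are maximised, yielding an 8 scenario x 3
#' objective production-potential table.
#'
#' @param model a [MetabolicNetwork-class] (unedited; base constraints are
#'   applied internally).
#' @param idMap role -> reaction id map; see [defaultIdMap()] / [toyIdMap()].
#' @param msFraction MS cap fraction under low B12 (default 0.5).
#' @param tolerance solver tolerance.
#' @return a [ProductionPotentialTable-class].
#' @examples
#' toy <- makeToyNetwork()
#' runB12Protocol(toy$model, toyIdMap())
#' @export
runB12Protocol <- function(model, idMap = defaultIdMap(),
                           msFraction = 0.5, tolerance = 1e-9) {
  checkIdMap(model, idMap)
  log <- character()
  addLog <- function(...) log <<- c(log, paste0(...))

  model <- applyBaseConstraints(model, idMap)
  addLog("set lower bound of ", idMap[["glyoxylate"]],
         " to 0 (glyoxylate shunt irreversible)")
  addLog("set upper bound of ", idMap[["propionate_secretion"]],
         " to 0 (propionate secretion blocked)")

  bg <- computeBackgroundActivity(model, idMap, msFraction, tolerance)
  model <- bg$model
  addLog(sprintf("biomass baseline %.6g; low-B12 baseline %.6g (MS cap %.6g)",
                 bg$baseline, bg$lowB12Baseline, bg$msCap))
  addLog("set lower bound of ", idMap[["biomass"]], " to ",
         format(bg$lowB12Baseline), " (background metabolic activity)")

  scenarios <- list(
    "WT" = character(),
    "dhgd-1 KO" = idMap[["dhgd"]],
    "dhgd-1+aass-1 KO" = idMap[c("dhgd", "aass")],
    "dhgd-1+aass-1+mccc-1 KO" = idMap[c("dhgd", "aass", "mccc")])
  objectives <- c(energy = idMap[["energy"]],
                  acetoacetate = idMap[["acetoacetate_export"]],
                  bhb = idMap[["bhb_export"]])

  rows <- list()
  for (b12 in c("replete", "low")) {
    mB <- model
    if (b12 == "low") {
      mB <- applyLowB12(mB, idMap, bg$msCap)
      addLog(sprintf("low B12: MS (%s) capped at %.6g; mutase (%s) fixed at 0",
                     idMap[["ms"]], bg$msCap, idMap[["mutase"]]))
    }
    for (sc in names(scenarios)) {
      mS <- knockoutReactions(mB, scenarios[[sc]])
      if (length(scenarios[[sc]]))
        addLog(b12, " B12 / ", sc, ": knocked out ",
               paste(scenarios[[sc]], collapse = ", "))
      for (obName in names(objectives)) {
        sol <- maximizeFlux(mS, objectives[[obName]], tolerance = tolerance)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, b12 = b12, objective = obName,
          value = if (sol@status == "optimal") sol@objectiveValue else
            NA_real_,
          status = sol@status, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$scenario <- factor(tab$scenario, levels = names(scenarios))
  tab$b12 <- factor(tab$b12, levels = c("replete", "low"))
  new("ProductionPotentialTable", table = tab,
      baseline = bg$baseline, lowB12Baseline = bg$lowB12Baseline,
      msCap = bg$msCap, log = log)
}
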