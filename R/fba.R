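# Flux balance analysis: assemble and solve the steady-state linear
# programs. The LP
#
#   max  v[obj]   s.t.  S v = 0,  lb <= v <= ub
#
# is solved with the package's bounded-variable simplex (R/lp-solver.R).
# All bounds are finite (see BOUND_SENTINEL), so the program is never
# unbounded.

lpMaximize <- function(S, lb, ub, objective, maximize = TRUE, tol = 1e-9) {
  keepRows <- which(apply(S != 0, 1, any))
  Sr <- as.matrix(S[keepRows, , drop = FALSE])
  res <- boundedSimplex(Sr, rep(0, nrow(Sr)), lb, ub, objective,
                        maximize = maximize, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, fluxes = NULL))
  v <- res$x
  # independent feasibility audit of the returned vertex
  mb <- max(abs(S %*% v))
  scale <- max(1, max(abs(v)))
  if (mb > max(tol, 1e-6) * scale ||
      any(v < lb - max(tol, 1e-6) * scale) ||
      any(v > ub + max(tol, 1e-6) * scale))
    warning("solver returned a vertex violating feasibility beyond tolerance",
            call. = FALSE)
  list(status = "optimal", value = sum(objective * v), fluxes = v)
}

#' Maximise (or minimise) the flux of one reaction
#'
#' Solves the flux balance analysis linear program: steady-state mass
#' balance `S v = 0` with the model's bounds, optimising the flux of
#' `objective`.
#'
#' @param model a [MetabolicNetwork-class].
#' @param objective reaction id to optimise.
#' @param sense `"maximize"` (default) or `"minimize"`.
#' @param tolerance feasibility tolerance reported in the solution and used
#'   for the post-solve mass-balance audit.
#' @return a [FluxSolution-class]; `status` is `"infeasible"` when no flux
#'   vector satisfies the constraints, in which case no flux vector is
#'   returned.
#' @examples
#' m <- newMetabolicNetwork(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("up", "conv", "out"),
#'                          lower_bound = 0, upper_bound = c(10, 1000, 1000)),
#'   stoichiometry = list(up = c(A = 1), conv = c(A = -1, B = 1),
#'                        out = c(B = -1)))
#' maximizeFlux(m, "out")  # bottlenecked at 10 by the uptake bound
#' @export
maximizeFlux <- function(model, objective,
                         sense = c("maximize", "minimize"),
                         tolerance = 1e-9) {
  sense <- match.arg(sense)
  j <- reactionIndex(model, objective)
  S <- stoichMatrix(model)
  obj <- numeric(nReactions(model))
  obj[j] <- 1
  res <- lpMaximize(S, model@reactions$lower_bound,
                    model@reactions$upper_bound, obj,
                    maximize = (sense == "maximize"), tol = tolerance)
  fluxes <- if (is.null(res$fluxes)) numeric() else
    stats::setNames(res$fluxes, reactionIds(model))
  new("FluxSolution",
      status = res$status,
      objectiveReaction = objective,
      objectiveValue = res$value,
      fluxes = fluxes,
      solverTolerance = tolerance)
}

#' Maximum flux of a probe reaction at a held objective level
#'
#' Flux-variability-style query: first maximises `objective`, then returns
#' the maximum feasible flux of `probe` subject to the objective flux being
#' at least `fraction` times its unconstrained optimum. This makes "the
#' flux of reaction X at the optimum" well defined even though individual
#' fluxes of a single FBA solution are degenerate.
#'
#' With `fraction = 0` the objective constraint is dropped and the query is
#' a plain `maximizeFlux` of the probe.
#'
#' @param model a [MetabolicNetwork-class].
#' @param probe reaction whose maximum flux is sought.
#' @param objective reaction held near its optimum.
#' @param fraction number in `[0, 1]`.
#' @param tolerance solver tolerance.
#' @return maximum probe flux (numeric scalar).
#' @export
maxFluxAtObjectiveFraction <- function(model, probe, objective,
                                       fraction = 1, tolerance = 1e-9) {
  stopifnot(fraction >= 0, fraction <= 1)
  reactionIndex(model, probe)
  if (fraction == 0) {
    sol <- maximizeFlux(model, probe, tolerance = tolerance)
    if (sol@status != "optimal")
      stop("probe maximisation not optimal: status ", sol@status,
           call. = FALSE)
    return(sol@objectiveValue)
  }
  base <- maximizeFlux(model, objective, tolerance = tolerance)
  if (base@status != "optimal")
    stop("objective maximisation not optimal: status ", base@status,
         call. = FALSE)
  j <- reactionIndex(model, objective)
  floorVal <- max(model@reactions$lower_bound[j],
                  fraction * base@objectiveValue)
  m2 <- setReactionBounds(model, objective, lower = floorVal)
  sol <- maximizeFlux(m2, probe, tolerance = tolerance)
  if (sol@status != "optimal")
    stop("probe maximisation infeasible after holding objective at ",
         format(floorVal), call. = FALSE)
  sol@objectiveValue
}
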