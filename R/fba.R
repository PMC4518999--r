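#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize the flux of one reaction subject
#' to steady state (\eqn{S v = 0}), the flux bounds, and any extra linear
#' constraints carried by the model (e.g. a hydrogen yield cap). Where the
#' optimum is degenerate an arbitrary optimal vertex is returned; scientific
#' statements about flux ranges should use [fluxVariability()], which is
#' degeneracy-proof.
#'
#' @param model a [MetabolicModel-class] passing [validateModel()] with no
#'   errors.
#' @param objective_id reaction id to optimize; defaults to the model's
#'   objective (biomass).
#' @param sense \code{"max"} or \code{"min"}.
#' @return an [FBAResult-class]; \code{status} faithfully reports
#'   infeasibility or unboundedness, in which case no fluxes are returned.
#' @examples
#' b <- generateLinearPathway(3, uptake_bound = 10, seed = 1)
#' solveFBA(b@model)
#' @export
solveFBA <- function(model, objective_id = objectiveId(model),
                     sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!length(objective_id)) {
    stop("model has no objective reaction and none was given", call. = FALSE)
  }
  lp <- .build_lp(model)
  if (!objective_id %in% lp$rids) {
    stop("objective reaction not in model: ", objective_id, call. = FALSE)
  }
  r <- .lp_opt(lp, setNames(1, objective_id), sense)
  new("FBAResult", status = r$status,
      objectiveValue = if (identical(r$status, "optimal")) r$objective else NA_real_,
      fluxes = r$fluxes)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above a stated fraction of its optimum. Each bound
#' is itself an LP optimum. At fraction 1 the ranges describe the optimal
#' face (alternate optima); at fraction 0 they describe the whole feasible
#' space.
#'
#' @param model a [MetabolicModel-class].
#' @param fraction_of_optimum number in [0, 1].
#' @param reactions reaction ids to analyse (default: all).
#' @param objective_id objective reaction (default: the model's).
#' @return data.frame with columns \code{reaction}, \code{min_flux},
#'   \code{max_flux}; attribute \code{fraction_of_optimum} records the
#'   fraction, attribute \code{optimum} the unconstrained optimum.
#' @export
fluxVariability <- function(model, fraction_of_optimum = 1,
                            reactions = reactionIds(model),
                            objective_id = objectiveId(model)) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  lp <- .build_lp(model)
  base <- .lp_opt(lp, setNames(1, objective_id), "max")
  if (!identical(base$status, "optimal")) {
    stop("base FBA problem is ", base$status,
         "; flux variability is undefined", call. = FALSE)
  }
  floor_val <- fraction_of_optimum * base$objective
  lower <- setNames(floor_val, objective_id)
  n <- length(reactions)
  mn <- mx <- numeric(n)
  for (i in seq_len(n)) {
    obj <- setNames(1, reactions[i])
    lo <- .lp_opt(lp, obj, "min", lower = lower)
    hi <- .lp_opt(lp, obj, "max", lower = lower)
    if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal")) {
      stop("flux variability subproblem for ", reactions[i], " is ",
           lo$status, call. = FALSE)
    }
    mn[i] <- lo$objective; mx[i] <- hi$objective
  }
  out <- data.frame(reaction = reactions, min_flux = mn, max_flux = mx,
                    stringsAsFactors = FALSE)
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  attr(out, "optimum") <- base$objective
  out
}

#' FBA with selected fluxes fixed
#'
#' Equivalent to temporarily setting \code{lower_bound = upper_bound =
#' value} for each fixed reaction and then solving FBA. A fix outside a
#' reaction's declared bounds is a precondition error, never silently
#' clamped.
#'
#' @param model a [MetabolicModel-class].
#' @param fixes named numeric vector, reaction id to fixed flux value.
#' @param objective_id reaction to optimize (default: model objective).
#' @param sense \code{"max"} or \code{"min"}.
#' @return an [FBAResult-class].
#' @export
optimizeWithFixedFluxes <- function(model, fixes,
                                    objective_id = objectiveId(model),
                                    sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- .build_lp(model)
  r <- .lp_opt(lp, setNames(1, objective_id), sense, fixes = fixes)
  new("FBAResult", status = r$status,
      objectiveValue = if (identical(r$status, "optimal")) r$objective else NA_real_,
      fluxes = r$fluxes)
}
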