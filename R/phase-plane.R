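#' Phenotypic phase plane
#'
#' Maximal growth as a surface over a grid of two fixed fluxes (classically
#' substrate uptake vs product secretion). Each finite cell is the LP
#' optimum of [optimizeWithFixedFluxes()] at that grid point; infeasible
#' cells are marked \code{NA}, never zero-filled.
#'
#' @param model a [MetabolicModel-class].
#' @param x_id,y_id distinct reaction ids for the two fixed fluxes.
#' @param x_range,y_range length-2 numeric ranges, within the reactions'
#'   declared bounds.
#' @param n_points grid resolution per axis (>= 2; default 50).
#' @param objective_id growth reaction (default: model objective).
#' @return a [PhasePlaneGrid-class].
#' @export
phasePlane <- function(model, x_id, y_id, x_range, y_range, n_points = 50,
                       objective_id = objectiveId(model)) {
  stopifnot(n_points >= 2, length(x_range) == 2, length(y_range) == 2)
  if (identical(x_id, y_id)) {
    stop("x_id and y_id must name different reactions", call. = FALSE)
  }
  lp <- .build_lp(model)
  for (id in c(x_id, y_id)) {
    if (!id %in% lp$rids) stop("unknown reaction id: ", id, call. = FALSE)
  }
  xs <- seq(x_range[1], x_range[2], length.out = n_points)
  ys <- seq(y_range[1], y_range[2], length.out = n_points)
  gm <- matrix(NA_real_, n_points, n_points,
               dimnames = list(format(xs, digits = 6), format(ys, digits = 6)))
  obj <- setNames(1, objective_id)
  for (i in seq_along(xs)) {
    for (j in seq_along(ys)) {
      r <- .lp_opt(lp, obj, "max", fixes = setNames(c(xs[i], ys[j]),
                                                    c(x_id, y_id)))
      if (identical(r$status, "optimal")) gm[i, j] <- r$objective
    }
  }
  new("PhasePlaneGrid", xId = x_id, yId = y_id, x = xs, y = ys, growth = gm)
}

#' Production envelope
#'
#' Minimum and maximum product flux over a grid of growth values from 0 to
#' the growth optimum. The envelope is a closed region: min and max meet
#' where feasibility ends. Its shape reveals growth coupling — a strictly
#' positive minimum at maximal growth means every growth-optimal flux state
#' must secrete the product.
#'
#' @param model a [MetabolicModel-class].
#' @param product_id product reaction id.
#' @param n_points number of growth values (default 50).
#' @param objective_id growth reaction (default: model objective).
#' @return a [ProductionEnvelope-class].
#' @export
productionEnvelope <- function(model, product_id, n_points = 50,
                               objective_id = objectiveId(model)) {
  stopifnot(n_points >= 2)
  lp <- .build_lp(model)
  if (!product_id %in% lp$rids) {
    stop("unknown product reaction: ", product_id, call. = FALSE)
  }
  base <- .lp_opt(lp, setNames(1, objective_id), "max")
  if (!identical(base$status, "optimal")) {
    stop("model growth problem is ", base$status,
         "; no envelope exists", call. = FALSE)
  }
  gs <- seq(0, base$objective, length.out = n_points)
  mn <- mx <- numeric(n_points)
  obj <- setNames(1, product_id)
  for (i in seq_along(gs)) {
    fx <- setNames(gs[i], objective_id)
    lo <- .lp_opt(lp, obj, "min", fixes = fx)
    hi <- .lp_opt(lp, obj, "max", fixes = fx)
    if (!identical(lo$status, "optimal") || !identical(hi$status, "optimal")) {
      # growth grid point at the numerical edge of feasibility
      mn[i] <- NA_real_; mx[i] <- NA_real_
    } else {
      mn[i] <- lo$objective; mx[i] <- hi$objective
    }
  }
  new("ProductionEnvelope", productId = product_id, growth = gs,
      minProduct = mn, maxProduct = mx)
}

#' Growth-coupling strength
#'
#' The guaranteed minimum product flux over all flux states whose growth is
#' at least \code{fraction} of the optimum: a single LP minimizing the
#' product subject to \eqn{v_{growth} \ge fraction \cdot \mu^*}. A strictly
#' positive value means product formation is coupled to (near-)optimal
#' growth; 0 means the product can be avoided entirely.
#'
#' @param model a [MetabolicModel-class].
#' @param product_id product reaction id.
#' @param fraction fraction of the growth optimum in [0, 1] (default 0.99).
#' @param objective_id growth reaction (default: model objective).
#' @return guaranteed minimum product flux (numeric scalar).
#' @export
couplingStrength <- function(model, product_id, fraction = 0.99,
                             objective_id = objectiveId(model)) {
  stopifnot(fraction >= 0, fraction <= 1)
  lp <- .build_lp(model)
  base <- .lp_opt(lp, setNames(1, objective_id), "max")
  if (!identical(base$status, "optimal")) {
    stop("model growth problem is ", base$status, call. = FALSE)
  }
  r <- .lp_opt(lp, setNames(1, product_id), "min",
               lower = setNames(fraction * base$objective, objective_id))
  if (!identical(r$status, "optimal")) {
    stop("coupling subproblem is ", r$status, call. = FALSE)
  }
  r$objective
}
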