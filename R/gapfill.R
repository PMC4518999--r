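#' Minimal-additions gap filling
#'
#' Given a draft model that cannot sustain biomass flux and a universe of
#' database reactions, proposes a smallest set of universe reactions whose
#' addition restores growth to at least \code{min_growth}. Solved as a MILP
#' over the combined network: one binary per universe reaction gates its
#' bounds (\eqn{lb_j z_j \le v_j \le ub_j z_j}), the objective minimizes
#' the (optionally cost-weighted) number of activated reactions subject to
#' combined steady state and the growth floor.
#'
#' @param draft a [MetabolicModel-class] with a biomass objective.
#' @param universe a [MetabolicModel-class] of candidate reactions;
#'   reactions whose id already occurs in the draft are ignored
#'   (deduplicated).
#' @param min_growth growth threshold to restore (default 1e-3 h^-1).
#' @param costs optional named numeric vector of per-reaction costs over
#'   universe reaction ids (default: unweighted cardinality).
#' @return a [GapfillResult-class]; status \code{"infeasible"} when even
#'   the full universe cannot reach \code{min_growth}.
#' @examples
#' b <- generateLinearPathway(3, uptake_bound = 10, seed = 1)
#' d <- degradeModel(b@model, k = 1, seed = 2)
#' gapFill(d@model, d@universe)
#' @export
gapFill <- function(draft, universe, min_growth = 1e-3, costs = NULL) {
  .assert_solvable(draft)
  growth_id <- draft@objectiveId
  if (!length(growth_id)) {
    stop("draft model has no objective (biomass) reaction", call. = FALSE)
  }
  uni_ids <- setdiff(universe@reactions$id, draft@reactions$id)
  uni_rx <- universe@reactions[match(uni_ids, universe@reactions$id), ,
                               drop = FALSE]

  # already growing: nothing to add
  base <- solveFBA(draft)
  if (identical(base@status, "optimal") &&
      base@objectiveValue >= min_growth - 1e-9) {
    return(new("GapfillResult", added = character(),
               growth = base@objectiveValue, status = "optimal"))
  }

  combined <- .merge_models(draft, universe, uni_ids)
  lpc <- .build_lp(combined)
  n <- length(lpc$rids)
  nu <- length(uni_ids)
  uidx <- match(uni_ids, lpc$rids)
  ncol0 <- ncol(lpc$A)
  # columns: [combined lp cols][z binaries][coupling slacks]
  A <- cbind(lpc$A, matrix(0, nrow(lpc$A), nu + 2L * nu + 1L))
  col_z <- ncol0 + seq_len(nu)
  col_s <- ncol0 + nu + seq_len(2L * nu)
  col_sg <- ncol0 + nu + 2L * nu + 1L
  extra <- matrix(0, 2L * nu + 1L, ncol(A))
  erhs <- numeric(2L * nu + 1L)
  for (k in seq_len(nu)) {
    j <- uidx[k]
    # v_j - ub_j z_j + s = 0 ; v_j - lb_j z_j - s' = 0
    extra[2L * k - 1L, c(j, col_z[k], col_s[2L * k - 1L])] <-
      c(1, -uni_rx$upper_bound[k], 1)
    extra[2L * k, c(j, col_z[k], col_s[2L * k])] <-
      c(1, -uni_rx$lower_bound[k], -1)
  }
  gj <- match(growth_id, lpc$rids)
  extra[2L * nu + 1L, c(gj, col_sg)] <- c(1, -1)
  erhs[2L * nu + 1L] <- min_growth
  A <- rbind(A, extra)
  b <- c(lpc$b, erhs)
  l <- c(lpc$l, rep(0, nu), rep(0, 2L * nu), 0)
  u <- c(lpc$u, rep(1, nu), rep(.LP_BIG, 2L * nu), .LP_BIG)
  # universe reactions must be freed to admit zero when z = 0
  l[uidx] <- pmin(lpc$l[uidx], 0)
  u[uidx] <- pmax(lpc$u[uidx], 0)
  w <- rep(1, nu)
  if (!is.null(costs)) {
    hit <- match(uni_ids, names(costs))
    w[!is.na(hit)] <- unname(costs[hit[!is.na(hit)]])
  }
  cvec <- numeric(ncol(A))
  cvec[col_z] <- -w # maximize -cost = minimize cost
  sol <- .milp_solve(A, b, cvec, l, u, col_z)
  if (!identical(sol$status, "optimal")) {
    return(new("GapfillResult", added = character(), growth = NA_real_,
               status = "infeasible"))
  }
  added <- uni_ids[sol$x[col_z] > 0.5]
  patched <- .merge_models(draft, universe, added)
  g <- solveFBA(patched)
  new("GapfillResult", added = sort(added), growth = g@objectiveValue,
      status = "optimal")
}

# Combine a draft with selected universe reactions into one model.
.merge_models <- function(draft, universe, uni_ids) {
  if (!length(uni_ids)) return(draft)
  ui <- match(uni_ids, universe@reactions$id)
  if (anyNA(ui)) {
    stop("universe is missing reaction(s): ",
         paste(uni_ids[is.na(ui)], collapse = ", "), call. = FALSE)
  }
  rx <- rbind(draft@reactions, universe@reactions[ui, , drop = FALSE])
  st <- c(draft@stoichiometry, universe@stoichiometry[uni_ids])
  new_mets <- setdiff(universe@metabolites$id, draft@metabolites$id)
  used <- unique(unlist(lapply(universe@stoichiometry[uni_ids], names)))
  new_mets <- intersect(new_mets, used)
  mets <- rbind(draft@metabolites,
                universe@metabolites[match(new_mets, universe@metabolites$id), ,
                                     drop = FALSE])
  comp <- draft@compartments
  extra_comp <- setdiff(unique(mets$compartment), names(comp))
  if (length(extra_comp)) {
    comp <- c(comp, setNames(extra_comp, extra_comp))
  }
  m <- new("MetabolicModel", metabolites = mets, reactions = rx,
           stoichiometry = st, objectiveId = draft@objectiveId,
           compartments = comp, extraConstraints = draft@extraConstraints,
           annotations = draft@annotations)
  validObject(m)
  m
}
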