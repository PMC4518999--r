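# Growth-coupled knockout design.
#
# The bilevel program (outer: choose <= K reaction knockouts to maximize
# product formation; inner: the mutant maximizes growth) is collapsed to a
# single-level MILP by strong LP duality: the MILP carries primal
# feasibility of the mutant flux state, dual feasibility of the growth LP,
# and the equality of primal and dual objectives, so inner optimality is
# enforced exactly rather than iteratively. Binary y_j = 1 keeps reaction j
# active; knockouts act through bound coupling lb_j*y_j <= v_j <= ub_j*y_j.
# Dual variables are bounded and the bilinear dual-bound terms are
# linearized with big-M products on FVA-tightened primal bounds.
#
# Design selection: the classic formulation maximizes the product flux
# attainable at the inner optimum, but that objective cannot distinguish a
# knockout that merely removes alternate optima (e.g. closing a
# stoichiometrically equivalent fermentation branch) from leaving it open —
# all such designs tie at the same maximum. The default selection therefore
# ranks candidate designs by the GUARANTEED minimum product at the inner
# optimum (the quantity that measures growth coupling), taking candidates
# from the near-optimal band of the duality MILP enumerated with exclusion
# cuts; both the max and the guaranteed min are reported on every design.
# `objective = "max_at_optimum"` gives the classic behaviour.

.DESIGN_TOL <- 1e-6

.design_stats <- function(lp, growth_id, product_id, ko) {
  fx <- if (length(ko)) setNames(rep(0, length(ko)), ko) else NULL
  g <- .lp_opt(lp, setNames(1, growth_id), "max", fixes = fx)
  if (!identical(g$status, "optimal")) {
    return(list(feasible = FALSE, growth = NA_real_, min = NA_real_,
                max = NA_real_))
  }
  floor_g <- setNames(g$objective - .DESIGN_TOL * max(1, abs(g$objective)),
                      growth_id)
  lo <- .lp_opt(lp, setNames(1, product_id), "min", fixes = fx, lower = floor_g)
  hi <- .lp_opt(lp, setNames(1, product_id), "max", fixes = fx, lower = floor_g)
  list(feasible = TRUE, growth = g$objective,
       min = if (identical(lo$status, "optimal")) lo$objective else NA_real_,
       max = if (identical(hi$status, "optimal")) hi$objective else NA_real_)
}

# TRUE if design a beats design b under the selection mode
.design_better <- function(a, b, mode) {
  keys <- if (mode == "coupled_min") c("min", "max") else c("max", "min")
  for (k in keys) {
    if (a[[k]] > b[[k]] + .DESIGN_TOL) return(TRUE)
    if (a[[k]] < b[[k]] - .DESIGN_TOL) return(FALSE)
  }
  if (length(a$ko) != length(b$ko)) return(length(a$ko) < length(b$ko))
  paste(sort(a$ko), collapse = ",") < paste(sort(b$ko), collapse = ",")
}

.check_candidates <- function(model, candidates, product_id) {
  rx <- model@reactions
  idx <- match(candidates, rx$id)
  if (anyNA(idx)) {
    stop("unknown candidate reaction(s): ",
         paste(candidates[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  bad <- rx$is_exchange[idx] | candidates %in% model@objectiveId |
    candidates %in% "ATPM"
  if (any(bad)) {
    stop("candidates must exclude exchange, biomass and ATP-maintenance ",
         "reactions: ", paste(candidates[bad], collapse = ", "), call. = FALSE)
  }
  if (any(rx$lower_bound[idx] > 0 | rx$upper_bound[idx] < 0)) {
    stop("candidate reactions must admit zero flux (lb <= 0 <= ub)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Growth-coupled knockout design (bilevel MILP)
#'
#' Searches for a set of at most \code{max_knockouts} reaction deletions
#' that maximizes product formation by the growth-optimizing mutant. Inner
#' (growth) optimality is enforced exactly through strong LP duality in a
#' single-level MILP. See the package vignette for the selection rule; in
#' short, the default \code{"coupled_min"} mode ranks the near-optimal
#' designs of the duality MILP by their guaranteed minimum product at the
#' inner optimum, which reproduces the published electron-centred designs,
#' while \code{"max_at_optimum"} is the classic optimistic objective.
#'
#' @param model a [MetabolicModel-class] (all reaction bounds finite).
#' @param product_id product reaction id (e.g. the ethanol exchange).
#' @param max_knockouts K, maximal number of deletions (>= 0).
#' @param candidates candidate reaction ids; must exclude exchanges, the
#'   biomass reaction and ATP maintenance. Default: [candidateReactions()].
#' @param min_growth minimal acceptable mutant growth; default 10\% of the
#'   wild-type optimum.
#' @param objective selection mode, \code{"coupled_min"} (default) or
#'   \code{"max_at_optimum"}.
#' @param pool_tolerance relative width of the near-optimal band explored
#'   for guaranteed-min selection (default 0.02).
#' @param pool_limit maximal number of pooled designs (default 40).
#' @param dual_bound cap on dual variables in the duality coupling
#'   (default 100).
#' @return a [KnockoutDesign-class]; if no design attains \code{min_growth}
#'   the status is \code{"no_design"}.
#' @seealso [exhaustiveDesignSearch()] for the enumeration oracle,
#'   [verifyDesign()] to re-derive a design's statistics by plain FBA.
#' @export
optKnock <- function(model, product_id, max_knockouts,
                     candidates = candidateReactions(model),
                     min_growth = NULL,
                     objective = c("coupled_min", "max_at_optimum"),
                     pool_tolerance = 0.02, pool_limit = 40,
                     dual_bound = 100) {
  objective <- match.arg(objective)
  stopifnot(max_knockouts >= 0)
  .assert_solvable(model)
  candidates <- resolveReactionAlias(unique(candidates))
  .check_candidates(model, candidates, product_id)
  growth_id <- model@objectiveId
  if (!length(growth_id)) stop("model has no objective reaction", call. = FALSE)

  lp <- .build_lp(model, validated = TRUE)
  wt <- .lp_opt(lp, setNames(1, growth_id), "max")
  if (!identical(wt$status, "optimal")) {
    stop("wild-type growth problem is ", wt$status, call. = FALSE)
  }
  if (is.null(min_growth)) min_growth <- 0.1 * wt$objective

  # presolve: a blocked reaction (lb = ub = 0) is not a meaningful knockout; a
  # candidate whose single knockout already kills growth can never appear
  # in an acceptable design
  rxb <- model@reactions[match(candidates, model@reactions$id), ]
  candidates <- candidates[!(rxb$lower_bound == 0 & rxb$upper_bound == 0)]
  keep <- vapply(candidates, function(j) {
    r <- .lp_opt(lp, setNames(1, growth_id), "max", fixes = setNames(0, j))
    identical(r$status, "optimal") && r$objective >= min_growth - .DESIGN_TOL
  }, TRUE)
  cand <- candidates[keep]

  wt_stats <- .design_stats(lp, growth_id, product_id, character())
  as_design <- function(st, ko, status = "optimal") {
    new("KnockoutDesign", reactions = sort(ko), growth = st$growth,
        productId = product_id, productMax = st$max, productMin = st$min,
        status = status)
  }
  if (max_knockouts == 0L || !length(cand)) {
    if (!wt_stats$feasible || is.na(wt_stats$growth) ||
        wt_stats$growth < min_growth - .DESIGN_TOL) {
      return(new("KnockoutDesign", reactions = character(), growth = NA_real_,
                 productId = product_id, productMax = NA_real_,
                 productMin = NA_real_, status = "no_design"))
    }
    return(as_design(wt_stats, character()))
  }

  milp <- .optknock_milp(model, lp, growth_id, product_id, cand,
                         max_knockouts, min_growth, dual_bound)
  eps <- 1e-4
  seed_obj <- wt_stats$max + eps * length(cand)
  sol <- .milp_solve(milp$A, milp$b, milp$cvec, milp$l, milp$u, milp$bin_idx,
                     incumbent_obj = seed_obj - 1e-6)
  first_ko <- if (identical(sol$status, "optimal")) {
    cand[sol$x[milp$bin_idx] < 0.5]
  } else character() # nothing beats the wild type
  if (!identical(sol$status, "optimal")) {
    st <- wt_stats
    if (!st$feasible || st$growth < min_growth) {
      return(new("KnockoutDesign", reactions = character(), growth = NA_real_,
                 productId = product_id, productMax = NA_real_,
                 productMin = NA_real_, status = "no_design"))
    }
    best <- c(wt_stats, list(ko = character()))
    return(as_design(best, best$ko))
  }

  st1 <- .design_stats(lp, growth_id, product_id, first_ko)
  pool <- list(c(st1, list(ko = first_ko)))
  v_star <- st1$max
  if (wt_stats$feasible && wt_stats$growth >= min_growth) {
    pool <- c(pool, list(c(wt_stats, list(ko = character()))))
    v_star <- max(v_star, wt_stats$max)
  }

  if (objective == "coupled_min") {
    band_floor <- v_star - pool_tolerance * max(1, abs(v_star))
    A <- milp$A; b <- milp$b; l <- milp$l; u <- milp$u; cvec <- milp$cvec
    excl <- function(A, b, l, u, ko) {
      # exclude exactly this knockout set: sum_{j in ko} y_j +
      # sum_{j not in ko} (1 - y_j) >= 1
      row <- numeric(ncol(A) + 1L)
      in_ko <- cand %in% ko
      row[milp$bin_idx[in_ko]] <- 1
      row[milp$bin_idx[!in_ko]] <- -1
      row[ncol(A) + 1L] <- -1 # surplus
      rhs <- 1 - sum(!in_ko)
      A <- cbind(A, 0); A <- rbind(A, row)
      list(A = A, b = c(b, rhs), l = c(l, 0), u = c(u, .LP_BIG))
    }
    cur_ko <- first_ko
    repeat {
      best_min <- max(vapply(pool, function(d) {
        if (is.na(d$min)) -Inf else d$min
      }, 0))
      stop_at <- max(band_floor, best_min)
      e <- excl(A, b, l, u, cur_ko)
      A <- e$A; b <- e$b; l <- e$l; u <- e$u
      cvec <- c(cvec, 0)
      if (length(pool) >= pool_limit) break
      sol <- .milp_solve(A, b, cvec, l, u, milp$bin_idx,
                         incumbent_obj = stop_at)
      if (!identical(sol$status, "optimal")) break
      cur_ko <- cand[sol$x[milp$bin_idx] < 0.5]
      st <- .design_stats(lp, growth_id, product_id, cur_ko)
      if (st$feasible) pool <- c(pool, list(c(st, list(ko = cur_ko))))
    }
  }

  best <- pool[[1L]]
  for (d in pool[-1L]) if (.design_better(d, best, objective)) best <- d
  as_design(best, best$ko)
}

# Build the single-level duality MILP. Returns dense standard-form pieces.
.optknock_milp <- function(model, lp, growth_id, product_id, cand, K,
                           min_growth, Mdual) {
  S <- stoichiometricMatrix(model)
  m <- nrow(S); n <- ncol(S)
  rids <- colnames(S)
  ec <- model@extraConstraints
  E <- length(ec)
  C <- length(cand)
  cidx <- match(cand, rids)
  gpos <- match(growth_id, rids)
  ppos <- match(product_id, rids)

  # FVA-tightened primal bounds (valid for every knockout submodel)
  fva <- fluxVariability(model, 0)
  lb <- pmax(model@reactions$lower_bound, fva$min_flux - 1e-6)
  ub <- pmin(model@reactions$upper_bound, fva$max_flux + 1e-6)
  lb[cidx] <- pmin(lb[cidx], 0); ub[cidx] <- pmax(ub[cidx], 0)

  # column layout; p_k / q_k linearization variables exist only where the
  # corresponding tightened bound is nonzero (otherwise the duality term
  # ub_j p_k or lb_j q_k vanishes identically)
  need_p <- ub[cidx] > 1e-12
  need_q <- lb[cidx] < -1e-12
  nP <- sum(need_p); nQ <- sum(need_q)
  col_v <- seq_len(n)
  col_sE <- if (E) n + seq_len(E) else integer()
  col_sg <- n + E + 1L
  col_lam <- n + E + 1L + seq_len(m)
  col_th <- if (E) n + E + 1L + m + seq_len(E) else integer()
  col_mu <- n + E + 1L + m + E + seq_len(n)
  col_nu <- n + E + 1L + m + E + n + seq_len(n)
  col_p <- integer(C); col_p[need_p] <- n + E + 1L + m + E + 2L * n + seq_len(nP)
  col_q <- integer(C); col_q[need_q] <- n + E + 1L + m + E + 2L * n + nP + seq_len(nQ)
  col_y <- n + E + 1L + m + E + 2L * n + nP + nQ + seq_len(C)
  ncol_tot <- n + E + 1L + m + E + 2L * n + nP + nQ + C

  rows <- list(); rhs <- numeric(0)
  slack_cols <- list() # (row, sign) pairs appended after fixed columns
  add_row <- function(cols, vals, rhs_v, slack_sign = 0) {
    r <- numeric(ncol_tot)
    r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    rhs[length(rhs) + 1L] <<- rhs_v
    slack_cols[[length(slack_cols) + 1L]] <<- slack_sign
  }

  # primal: S v = 0
  for (i in seq_len(m)) add_row(col_v, S[i, ], 0)
  # primal extra constraints over v (slack by sense)
  for (e in seq_len(E)) {
    co <- ec[[e]]$coefficients
    j <- match(names(co), rids)
    sgn <- switch(ec[[e]]$sense, "<=" = 1, ">=" = -1, "=" = 0)
    r <- numeric(ncol_tot); r[col_v[j]] <- unname(co)
    if (sgn != 0) r[col_sE[e]] <- sgn
    rows[[length(rows) + 1L]] <- r
    rhs[length(rhs) + 1L] <- ec[[e]]$rhs
    slack_cols[[length(slack_cols) + 1L]] <- 0
  }
  # growth floor: v_g - sg = min_growth
  {
    r <- numeric(ncol_tot); r[col_v[gpos]] <- 1; r[col_sg] <- -1
    rows[[length(rows) + 1L]] <- r; rhs[length(rhs) + 1L] <- min_growth
    slack_cols[[length(slack_cols) + 1L]] <- 0
  }
  # knockout bound coupling for candidates: v_j - ub_j y_j <= 0,
  # v_j - lb_j y_j >= 0
  for (k in seq_len(C)) {
    j <- cidx[k]
    add_row(c(col_v[j], col_y[k]), c(1, -ub[j]), 0, slack_sign = 1)
    add_row(c(col_v[j], col_y[k]), c(1, -lb[j]), 0, slack_sign = -1)
  }
  # dual feasibility: S_j' lam + a_j' th + mu_j - nu_j = g_j
  for (j in seq_len(n)) {
    cols <- c(col_lam, col_mu[j], col_nu[j])
    vals <- c(S[, j], 1, -1)
    if (E) {
      av <- vapply(seq_len(E), function(e) {
        co <- ec[[e]]$coefficients
        v <- co[match(rids[j], names(co))]
        s <- if (identical(ec[[e]]$sense, ">=")) -1 else 1
        if (is.na(v)) 0 else s * v
      }, 0)
      cols <- c(cols, col_th); vals <- c(vals, av)
    }
    add_row(cols, vals, if (j == gpos) 1 else 0)
  }
  # strong duality: g'v - th'd - sum_cand(ub p - lb q)
  #               - sum_noncand(ub mu - lb nu) = 0
  {
    r <- numeric(ncol_tot)
    r[col_v[gpos]] <- 1
    if (E) {
      d <- vapply(seq_len(E), function(e) {
        s <- if (identical(ec[[e]]$sense, ">=")) -1 else 1
        s * ec[[e]]$rhs
      }, 0)
      r[col_th] <- -d
    }
    noncand <- setdiff(seq_len(n), cidx)
    r[col_mu[noncand]] <- -ub[noncand]
    r[col_nu[noncand]] <- lb[noncand]
    r[col_p[need_p]] <- -ub[cidx][need_p]
    r[col_q[need_q]] <- lb[cidx][need_q]
    rows[[length(rows) + 1L]] <- r; rhs[length(rhs) + 1L] <- 0
    slack_cols[[length(slack_cols) + 1L]] <- 0
  }
  # linearization p_k = mu_j y_k and q_k = nu_j y_k (where present)
  for (k in seq_len(C)) {
    j <- cidx[k]
    if (need_p[k]) {
      add_row(c(col_p[k], col_mu[j]), c(1, -1), 0, slack_sign = 1)
      add_row(c(col_p[k], col_y[k]), c(1, -Mdual), 0, slack_sign = 1)
      add_row(c(col_mu[j], col_p[k], col_y[k]), c(1, -1, Mdual), Mdual,
              slack_sign = 1)
    }
    if (need_q[k]) {
      add_row(c(col_q[k], col_nu[j]), c(1, -1), 0, slack_sign = 1)
      add_row(c(col_q[k], col_y[k]), c(1, -Mdual), 0, slack_sign = 1)
      add_row(c(col_nu[j], col_q[k], col_y[k]), c(1, -1, Mdual), Mdual,
              slack_sign = 1)
    }
  }
  # knapsack: sum y >= C - K
  add_row(col_y, rep(1, C), C - K, slack_sign = -1)

  A <- do.call(rbind, rows)
  # append slack columns
  ns <- sum(vapply(slack_cols, function(s) s != 0, TRUE))
  if (ns) {
    Sl <- matrix(0, nrow(A), ns)
    kk <- 0L
    for (r in seq_along(slack_cols)) {
      if (slack_cols[[r]] != 0) {
        kk <- kk + 1L
        Sl[r, kk] <- slack_cols[[r]]
      }
    }
    A <- cbind(A, Sl)
  }
  l <- numeric(ncol(A)); u <- numeric(ncol(A))
  l[col_v] <- lb; u[col_v] <- ub
  l[cidx] <- pmin(lb[cidx], 0); u[cidx] <- pmax(ub[cidx], 0)
  if (E) { l[col_sE] <- 0; u[col_sE] <- .LP_BIG }
  l[col_sg] <- 0; u[col_sg] <- .LP_BIG
  l[col_lam] <- -Inf; u[col_lam] <- Inf
  if (E) {
    for (e in seq_len(E)) {
      if (identical(ec[[e]]$sense, "=")) {
        l[col_th[e]] <- -Mdual; u[col_th[e]] <- Mdual
      } else {
        l[col_th[e]] <- 0; u[col_th[e]] <- Mdual
      }
    }
  }
  l[col_mu] <- 0; u[col_mu] <- Mdual
  l[col_nu] <- 0; u[col_nu] <- Mdual
  l[col_p[need_p]] <- 0; u[col_p[need_p]] <- Mdual
  l[col_q[need_q]] <- 0; u[col_q[need_q]] <- Mdual
  l[col_y] <- 0; u[col_y] <- 1
  if (ns) {
    sl <- ncol_tot + seq_len(ns)
    l[sl] <- 0; u[sl] <- .LP_BIG
  }
  cvec <- numeric(ncol(A))
  cvec[col_v[ppos]] <- 1
  cvec[col_y] <- 1e-4 # prefer fewer knockouts among product-equivalent designs
  list(A = A, b = rhs, cvec = cvec, l = l, u = u, bin_idx = col_y)
}

#' Exhaustive knockout-design search (oracle)
#'
#' Enumerates every subset of at most K candidate reactions, applies the
#' knockouts, maximizes growth and evaluates the product flux at that
#' optimum, returning the best design under the same selection rule as
#' [optKnock()]. Serves as the independent correctness oracle for the
#' duality MILP on instances small enough to enumerate.
#'
#' @inheritParams optKnock
#' @param subset_guard maximal number of subsets enumerable (default
#'   50000); beyond it an error instructs use of the MILP.
#' @return a [KnockoutDesign-class].
#' @export
exhaustiveDesignSearch <- function(model, product_id, max_knockouts,
                                   candidates = candidateReactions(model),
                                   min_growth = NULL,
                                   objective = c("coupled_min", "max_at_optimum"),
                                   subset_guard = 50000) {
  objective <- match.arg(objective)
  stopifnot(max_knockouts >= 0)
  .assert_solvable(model)
  candidates <- resolveReactionAlias(unique(candidates))
  if (length(candidates)) .check_candidates(model, candidates, product_id)
  growth_id <- model@objectiveId
  lp <- .build_lp(model, validated = TRUE)
  wt <- .lp_opt(lp, setNames(1, growth_id), "max")
  if (!identical(wt$status, "optimal")) {
    stop("wild-type growth problem is ", wt$status, call. = FALSE)
  }
  if (is.null(min_growth)) min_growth <- 0.1 * wt$objective
  K <- min(max_knockouts, length(candidates))
  n_subsets <- sum(vapply(0:K, function(k) choose(length(candidates), k), 0))
  if (n_subsets > subset_guard) {
    stop("subset enumeration guard exceeded (", n_subsets, " > ",
         subset_guard, "); use optKnock()", call. = FALSE)
  }
  best <- NULL
  for (k in 0:K) {
    sets <- if (k == 0) list(character()) else {
      cb <- combn(sort(candidates), k)
      lapply(seq_len(ncol(cb)), function(i) cb[, i])
    }
    for (ko in sets) {
      st <- .design_stats(lp, growth_id, product_id, ko)
      if (!st$feasible || is.na(st$growth) ||
          st$growth < min_growth - .DESIGN_TOL) next
      d <- c(st, list(ko = ko))
      if (is.null(best) || .design_better(d, best, objective)) best <- d
    }
  }
  if (is.null(best)) {
    return(new("KnockoutDesign", reactions = character(), growth = NA_real_,
               productId = product_id, productMax = NA_real_,
               productMin = NA_real_, status = "no_design"))
  }
  new("KnockoutDesign", reactions = sort(best$ko), growth = best$growth,
      productId = product_id, productMax = best$max, productMin = best$min,
      status = "optimal")
}

#' Verify a knockout design by plain FBA
#'
#' Re-applies the design's knockouts and recomputes the growth optimum and
#' the min/max product flux at that optimum with ordinary LPs, flagging any
#' discrepancy with the recorded values beyond the tolerance.
#'
#' @param model the model the design was computed on.
#' @param design a [KnockoutDesign-class].
#' @param tol discrepancy tolerance (default 1e-5).
#' @return list with \code{consistent} (logical), \code{discrepancies}
#'   (character), and the recomputed \code{growth}, \code{productMin},
#'   \code{productMax}.
#' @export
verifyDesign <- function(model, design, tol = 1e-5) {
  stopifnot(is(design, "KnockoutDesign"))
  .assert_solvable(model)
  lp <- .build_lp(model, validated = TRUE)
  st <- .design_stats(lp, model@objectiveId, design@productId,
                      design@reactions)
  disc <- character()
  chk <- function(label, got, rec) {
    if (is.na(got) != is.na(rec) ||
        (!is.na(got) && abs(got - rec) > tol * max(1, abs(rec)))) {
      sprintf("%s: recorded %.8g, recomputed %.8g", label, rec, got)
    } else character()
  }
  disc <- c(chk("growth", st$growth, design@growth),
            chk("productMin", st$min, design@productMin),
            chk("productMax", st$max, design@productMax))
  list(consistent = length(disc) == 0L, discrepancies = disc,
       growth = st$growth, productMin = st$min, productMax = st$max)
}
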