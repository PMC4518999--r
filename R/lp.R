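# Internal LP/MILP layer. The dense bounded-variable simplex lives in
# src/simplex.cpp; everything here marshals models into
#   max c'x  s.t.  A x = b, l <= x <= u
# form (extra inequality constraints get slack columns) and implements a
# depth-first branch-and-bound on binary variables for the MILP problems
# (knockout design, gap filling).

.LP_BIG <- 1e5          # slack upper bound; fluxes are O(1e3) at most
.FEAS_TOL <- 1e-9
.VAL_TOL <- 1e-6

.lp_statuses <- c("optimal", "infeasible", "unbounded", "error")

.lp_raw <- function(A, b, cvec, l, u, max_iter = 50000L) {
  if (nrow(A) == 0L) { # no balance rows: pad with a vacuous one
    A <- matrix(0, 1L, ncol(A)); b <- 0
  }
  r <- .lp_solve_dense(A, b, cvec, l, u, max_iter)
  if (r$status == 3L) stop("LP solver failed to converge", call. = FALSE)
  list(status = .lp_statuses[r$status + 1L], objective = r$objective,
       x = as.numeric(r$x))
}

# Build the standard-form skeleton for a model: columns are the model's
# reactions followed by one slack per inequality extra-constraint.
.build_lp <- function(model, validated = FALSE) {
  if (!validated) .assert_solvable(model)
  S <- stoichiometricMatrix(model)
  rids <- colnames(S)
  n <- length(rids)
  ec <- model@extraConstraints
  n_slack <- sum(vapply(ec, function(e) e$sense %in% c("<=", ">="), TRUE))
  A <- rbind(S, matrix(0, length(ec), n))
  if (n_slack > 0L) {
    A <- cbind(A, matrix(0, nrow(A), n_slack))
  }
  b <- c(rep(0, nrow(S)), numeric(length(ec)))
  slack_j <- n
  for (k in seq_along(ec)) {
    row <- nrow(S) + k
    co <- ec[[k]]$coefficients
    idx <- match(names(co), rids)
    if (anyNA(idx)) {
      stop("extra constraint references unknown reaction(s): ",
           paste(names(co)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    A[row, idx] <- unname(co)
    b[row] <- ec[[k]]$rhs
    if (ec[[k]]$sense == "<=") {
      slack_j <- slack_j + 1L; A[row, slack_j] <- 1
    } else if (ec[[k]]$sense == ">=") {
      slack_j <- slack_j + 1L; A[row, slack_j] <- -1
    } else if (ec[[k]]$sense != "=") {
      stop("unknown constraint sense: ", ec[[k]]$sense, call. = FALSE)
    }
  }
  l <- c(model@reactions$lower_bound, rep(0, n_slack))
  u <- c(model@reactions$upper_bound, rep(.LP_BIG, n_slack))
  list(A = A, b = b, l = l, u = u, n = n, rids = rids)
}

# Optimize a linear objective (sparse named vector over reaction ids) over a
# built skeleton, optionally fixing fluxes or overriding bounds.
.lp_opt <- function(lp, obj, sense = c("max", "min"), fixes = NULL,
                    lower = NULL, upper = NULL) {
  sense <- match.arg(sense)
  cvec <- numeric(ncol(lp$A))
  idx <- match(names(obj), lp$rids)
  if (anyNA(idx)) {
    stop("objective references unknown reaction(s): ",
         paste(names(obj)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cvec[idx] <- unname(obj)
  if (sense == "min") cvec <- -cvec
  l <- lp$l; u <- lp$u
  if (!is.null(lower)) {
    j <- match(names(lower), lp$rids); l[j] <- pmax(l[j], unname(lower))
  }
  if (!is.null(upper)) {
    j <- match(names(upper), lp$rids); u[j] <- pmin(u[j], unname(upper))
  }
  if (!is.null(fixes) && length(fixes)) {
    j <- match(names(fixes), lp$rids)
    if (anyNA(j)) {
      stop("fix references unknown reaction(s): ",
           paste(names(fixes)[is.na(j)], collapse = ", "), call. = FALSE)
    }
    out <- unname(fixes) < lp$l[j] - .VAL_TOL | unname(fixes) > lp$u[j] + .VAL_TOL
    if (any(out)) {
      stop("fixed flux outside declared bounds for: ",
           paste(names(fixes)[out], collapse = ", "), call. = FALSE)
    }
    l[j] <- u[j] <- unname(fixes)
  }
  r <- .lp_raw(lp$A, lp$b, cvec, l, u)
  if (identical(r$status, "optimal")) {
    obj_val <- sum(cvec * r$x)
    r$objective <- if (sense == "min") -obj_val else obj_val
    r$fluxes <- setNames(r$x[seq_len(lp$n)], lp$rids)
  } else {
    r$objective <- NA_real_
    r$fluxes <- setNames(numeric(0), character(0))
  }
  r
}

# ---- branch and bound -----------------------------------------------------

# Maximize c'x s.t. A x = b, l <= x <= u, x[bin_idx] binary.
# Depth-first best-child-first search; prunes on the LP relaxation bound.
.milp_solve <- function(A, b, cvec, l, u, bin_idx, node_limit = 100000L,
                        int_tol = 1e-6, incumbent_obj = -Inf) {
  best_x <- NULL
  best <- incumbent_obj
  stack <- list(list(l = l, u = u))
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      stop("branch-and-bound node limit exceeded", call. = FALSE)
    }
    r <- .lp_raw(A, b, cvec, node$l, node$u)
    if (!identical(r$status, "optimal")) next
    if (r$objective <= best + 1e-7) next
    frac <- abs(r$x[bin_idx] - round(r$x[bin_idx]))
    if (all(frac <= int_tol)) {
      # verify the rounded point: big-M couplings make a tiny fractional
      # binary feasible in the relaxation while its rounding is not
      fl <- node$l; fu <- node$u
      fl[bin_idx] <- fu[bin_idx] <- round(r$x[bin_idx])
      rf <- .lp_raw(A, b, cvec, fl, fu)
      if (identical(rf$status, "optimal")) {
        if (rf$objective > best + 1e-7) {
          best <- rf$objective
          x <- rf$x
          x[bin_idx] <- round(r$x[bin_idx])
          best_x <- x
        }
        next
      }
      if (max(frac) == 0) next # exactly integral yet infeasible: numerical
      # otherwise fall through and branch on the largest fractionality
    }
    j <- bin_idx[which.max(frac)]
    xj <- r$x[j]
    dn <- node; dn$u[j] <- 0
    up <- node; up$l[j] <- 1
    # push the less promising child first so the rounding-nearest child is
    # explored next (stack is LIFO)
    if (xj >= 0.5) stack <- c(stack, list(dn), list(up))
    else stack <- c(stack, list(up), list(dn))
  }
  if (is.null(best_x)) {
    list(status = "infeasible", objective = NA_real_, x = NULL, nodes = nodes)
  } else {
    list(status = "optimal", objective = best, x = best_x, nodes = nodes)
  }
}
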