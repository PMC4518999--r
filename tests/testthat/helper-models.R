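# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written from first principles (enumeration,
# direct algebra) and never call the solver paths they are used to check.

# linear chain EX_A(uptake <= cap) -> A -> B -> EX_B
chain_model <- function(cap = 10) {
  makeModel(data.frame(
    id = c("EX_A", "T1", "T2", "EX_B"),
    formula = c("A[e] ->", "A[e] -> B[c]", "B[c] -> B[e]", "B[e] ->"),
    lb = c(-cap, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
    stringsAsFactors = FALSE), objective = "EX_B")
}

# branched toy: substrate converts to P1 (yield 1) or P2 (yield 2)
branched_model <- function(cap = 10) {
  makeModel(data.frame(
    id = c("EX_S", "UP", "R1", "R2", "EX_P1", "EX_P2"),
    formula = c("S[e] ->", "S[e] -> S[c]", "S[c] -> P1[e]",
                "S[c] -> 2 P2[e]", "P1[e] ->", "P2[e] ->"),
    lb = c(-cap, 0, 0, 0, 0, 0), ub = c(0, rep(1000, 5)),
    stringsAsFactors = FALSE), objective = "EX_P2")
}

# random small network built directly (columns may be mass-imbalanced on
# purpose; the exercise is LP correctness, not chemistry)
random_lp_model <- function(seed) {
  set.seed(seed)
  m <- sample(1:4, 1)
  n <- sample(2:6, 1)
  S <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
  mids <- sprintf("m%d[c]", seq_len(m))
  rids <- sprintf("r%d", seq_len(n))
  dimnames(S) <- list(mids, rids)
  lb <- round(runif(n, -5, 0), 3)
  ub <- round(runif(n, 0, 5), 3)
  stoich <- lapply(seq_len(n), function(j) {
    v <- S[, j]; v[v != 0]
  })
  names(stoich) <- rids
  new("MetabolicModel",
      metabolites = data.frame(id = mids, name = mids, compartment = "c",
                               formula = "", stringsAsFactors = FALSE),
      reactions = data.frame(id = rids, name = rids, lower_bound = lb,
                             upper_bound = ub, gene_rule = "",
                             is_exchange = TRUE, stringsAsFactors = FALSE),
      stoichiometry = stoich, objectiveId = rids[n],
      compartments = c(c = "cytosol", e = "extracellular"))
}

# brute-force vertex enumeration oracle for max c'v s.t. S v = 0,
# lb <= v <= ub (vertices of the polytope are basic solutions)
vertex_optimum <- function(S, lb, ub, cvec) {
  n <- ncol(S); m <- nrow(S)
  best <- -Inf; feasible <- FALSE
  for (k in 0:min(m, n)) {
    bases <- if (k == 0) list(integer()) else {
      cb <- combn(n, k); lapply(seq_len(ncol(cb)), function(i) cb[, i])
    }
    for (B in bases) {
      N <- setdiff(seq_len(n), B)
      grid <- if (length(N)) {
        expand.grid(rep(list(1:2), length(N)))
      } else data.frame(row.names = 1)
      for (gi in seq_len(nrow(grid))) {
        x <- numeric(n)
        if (length(N)) {
          x[N] <- ifelse(unlist(grid[gi, ]) == 1, lb[N], ub[N])
        }
        if (k > 0) {
          SB <- S[, B, drop = FALSE]
          SBtSB <- crossprod(SB)
          if (abs(det(SBtSB)) < 1e-10) next
          rhs <- -(if (length(N)) S[, N, drop = FALSE] %*% x[N] else
                   matrix(0, m, 1))
          xB <- tryCatch(solve(SBtSB, crossprod(SB, rhs)),
                         error = function(e) NULL)
          if (is.null(xB)) next
          x[B] <- xB
          if (max(abs(S %*% x)) > 1e-7) next
        } else {
          if (max(abs(S %*% x)) > 1e-7) next
        }
        if (all(x >= lb - 1e-7 & x <= ub + 1e-7)) {
          feasible <- TRUE
          best <- max(best, sum(cvec * x))
        }
      }
    }
  }
  list(feasible = feasible, optimum = best)
}

# brute-force minimality check for a gap-fill solution: no proper subset
# of the additions restores growth
gapfill_is_minimal <- function(draft, universe, added, min_growth = 1e-3) {
  if (!length(added)) return(TRUE)
  for (k in 0:(length(added) - 1L)) {
    subs <- if (k == 0) list(character()) else {
      cb <- combn(added, k); lapply(seq_len(ncol(cb)), function(i) cb[, i])
    }
    for (s in subs) {
      patched <- thermoflux:::.merge_models(draft, universe, s)
      g <- solveFBA(patched)
      if (identical(g@status, "optimal") &&
          g@objectiveValue >= min_growth - 1e-9) {
        return(FALSE)
      }
    }
  }
  TRUE
}

core_constrained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- applyHydrogenaseConstraints(buildCoreModel())
    }
    cache
  }
})
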