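test_that("FBA finds the bottleneck optimum of a linear chain", {
  r <- solveFBA(chain_model(10))
  expect_identical(r@status, "optimal")
  expect_equal(r@objectiveValue, 10, tolerance = 1e-8)
  S <- stoichiometricMatrix(chain_model(10))
  expect_lt(max(abs(S %*% r@fluxes[colnames(S)])), 1e-6)
})

test_that("FBA reports infeasibility when maintenance has no fuel", {
  core <- buildCoreModel()
  closed <- setReactionBounds(core, c("EX_glc", "EX_nh4", "EX_h2o", "EX_h"),
                              lower = 0, upper = 0)
  r <- solveFBA(closed)
  expect_identical(r@status, "infeasible")
  expect_length(r@fluxes, 0L)
})

test_that("branched yields match the vertex-enumeration oracle", {
  m <- branched_model(10)
  r <- solveFBA(m)  # product 2 per substrate
  expect_equal(r@objectiveValue, 20, tolerance = 1e-8)
  S <- stoichiometricMatrix(m)
  o <- vertex_optimum(S, m@reactions$lower_bound, m@reactions$upper_bound,
                      as.numeric(colnames(S) == "EX_P2"))
  expect_true(o$feasible)
  expect_equal(r@objectiveValue, o$optimum, tolerance = 1e-6)
})

test_that("LP optimum equals brute-force enumeration on random networks", {
  for (seed in 1:40) {
    m <- random_lp_model(seed)
    r <- solveFBA(m)
    S <- stoichiometricMatrix(m)
    o <- vertex_optimum(S, m@reactions$lower_bound, m@reactions$upper_bound,
                        as.numeric(seq_len(ncol(S)) == ncol(S)))
    if (!o$feasible) {
      expect_identical(r@status, "infeasible", label = paste("seed", seed))
    } else {
      expect_identical(r@status, "optimal", label = paste("seed", seed))
      expect_equal(r@objectiveValue, o$optimum, tolerance = 1e-6,
                   label = paste("seed", seed))
      expect_lt(max(abs(S %*% r@fluxes)), 1e-6)
    }
  }
})

test_that("adding a constraint never increases a maximization optimum", {
  core <- applyHydrogenaseConstraints(buildCoreModel())
  base <- solveFBA(core)@objectiveValue
  for (cap in c(8, 5, 2)) {
    tighter <- setReactionBounds(core, "EX_glc", lower = -cap)
    expect_lte(solveFBA(tighter)@objectiveValue, base + 1e-9)
  }
  extra <- core
  extra@extraConstraints <- c(extra@extraConstraints,
                              list(list(coefficients = c(EX_etoh = 1),
                                        sense = "<=", rhs = 5)))
  expect_lte(solveFBA(extra)@objectiveValue, base + 1e-9)
})

test_that("flux variability brackets are nested across fractions", {
  core <- strainModel(core_constrained(), "WT")
  ids <- c("EX_etoh", "EX_ac", "EX_h2", "LDH_L")
  f1 <- fluxVariability(core, 1, reactions = ids)
  f9 <- fluxVariability(core, 0.9, reactions = ids)
  f0 <- fluxVariability(core, 0, reactions = ids)
  expect_true(all(f1$min_flux >= f9$min_flux - 1e-6))
  expect_true(all(f1$max_flux <= f9$max_flux + 1e-6))
  expect_true(all(f9$min_flux >= f0$min_flux - 1e-6))
  expect_true(all(f9$max_flux <= f0$max_flux + 1e-6))
})

test_that("a linear chain at fraction 1 is fully determined", {
  f <- fluxVariability(chain_model(10), 1)
  expect_equal(f$min_flux, f$max_flux, tolerance = 1e-6)
  expect_equal(f$max_flux[f$reaction == "EX_B"], 10, tolerance = 1e-6)
})

test_that("flux variability at fraction 0 recovers raw bounds on free chains", {
  m <- chain_model(10)
  f <- fluxVariability(m, 0)
  # every reaction in the chain can be off or run at the uptake cap
  expect_equal(f$min_flux[f$reaction == "EX_B"], 0, tolerance = 1e-6)
  expect_equal(f$max_flux[f$reaction == "EX_B"], 10, tolerance = 1e-6)
})

test_that("fixed-flux optimization honours and checks its fixes", {
  m <- chain_model(10)
  r <- optimizeWithFixedFluxes(m, c(EX_B = 10), "EX_B")
  expect_equal(r@objectiveValue, 10, tolerance = 1e-8)
  r7 <- optimizeWithFixedFluxes(m, c(EX_B = 7), "EX_B")
  expect_equal(r7@objectiveValue, 7, tolerance = 1e-8)
  # a fix above the uptake bound is a precondition error, not a clamp
  expect_error(optimizeWithFixedFluxes(m, c(EX_B = 1001), "EX_B"), "bounds")
  # infeasible fix combination
  r11 <- optimizeWithFixedFluxes(m, c(EX_A = -10, EX_B = 11), "EX_B")
  expect_identical(r11@status, "infeasible")
})

test_that("degenerate alternate optima keep the objective but vary fluxes", {
  wt <- strainModel(core_constrained(), "WT")
  f <- fluxVariability(wt, 1, reactions = "EX_etoh")
  expect_gt(f$max_flux - f$min_flux, 1)  # wide optimal face
  # every reported optimum satisfies steady state
  r <- solveFBA(wt)
  S <- stoichiometricMatrix(wt)
  expect_lt(max(abs(S %*% r@fluxes[colnames(S)])), 1e-6)
})
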