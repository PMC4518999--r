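test_that("the core model is structurally clean and grows on glucose", {
  core <- buildCoreModel()
  rep <- validateModel(core)
  expect_equal(nrow(rep@errors), 0L)
  i <- match("HFS", core@reactions$id)
  expect_equal(core@reactions$gene_rule[i],
               "Tsac_1550 & Tsac_1551 & Tsac_1552 & Tsac_1553")
  r <- solveFBA(core)
  expect_identical(r@status, "optimal")
  expect_gt(r@objectiveValue, 0)
})

test_that("the unconstrained hydrogenase complement permits acetate overflow", {
  core <- buildCoreModel()  # no hydrogenase constraints yet
  mu <- solveFBA(core)@objectiveValue
  lp <- thermoflux:::.build_lp(core)
  hi <- thermoflux:::.lp_opt(lp, c(EX_ac = 1), "max",
                             lower = c(BIOMASS = mu * (1 - 1e-6)))
  expect_gt(hi$objective, 1)  # acetate production feasible at optimum
})

test_that("hydrogenase constraints block ECH and cap the H2 yield", {
  core <- core_constrained()
  fva <- fluxVariability(core, 0, reactions = c("ECH", "EX_h2"))
  ech <- fva[fva$reaction == "ECH", ]
  expect_equal(ech$min_flux, 0, tolerance = 1e-9)
  expect_equal(ech$max_flux, 0, tolerance = 1e-9)
  h2 <- fva[fva$reaction == "EX_h2", ]
  expect_lte(h2$max_flux, 0.9 * 10 + 1e-6)  # yield cap at full uptake
  # the cap is a coupling, not a fixed bound: max of v_H2 - 0.9*|v_glc| <= 0
  lp <- thermoflux:::.build_lp(core)
  worst <- thermoflux:::.lp_opt(lp, c(EX_h2 = 1, EX_glc = 0.9), "max")
  expect_lte(worst$objective, 1e-6)
  # uptake-only hydrogenases cannot produce H2
  b <- core@reactions[match(c("BIFH2", "NADH2"), core@reactions$id), ]
  expect_true(all(b$upper_bound == 0))
})

test_that("applying the hydrogenase constraint set is idempotent", {
  once <- applyHydrogenaseConstraints(buildCoreModel())
  twice <- applyHydrogenaseConstraints(once)
  expect_equal(twice@reactions, once@reactions)
  expect_equal(length(twice@extraConstraints), length(once@extraConstraints))
  expect_error(applyHydrogenaseConstraints(chain_model()), "absent")
})

test_that("strains are viable and ordered as observed", {
  core <- core_constrained()
  mu <- sapply(c("WT", "ldh_pta", "ldh_hfs", "ldh_hfs_glud"),
               function(s) solveFBA(strainModel(core, s))@objectiveValue)
  expect_true(all(mu > 0))                      # every strain grows
  expect_lt(mu[["ldh_hfs"]], mu[["WT"]])        # growth penalty
  expect_identical(strainModel(core, "WT")@reactions, core@reactions)
  expect_error(strainModel(core, "ldh_xyz"), "valid names")
  # triple knockout guarantees at least the double knockout's ethanol
  cs_hfs <- couplingStrength(strainModel(core, "ldh_hfs"), "EX_etoh", 1)
  cs_glud <- couplingStrength(strainModel(core, "ldh_hfs_glud"), "EX_etoh", 1)
  expect_gte(cs_glud, cs_hfs - 1e-6)
})

test_that("ammonium assimilation costs 1 extra ATP via GLNS+GLUS", {
  core <- buildCoreModel()
  glud <- ammoniumAssimilationAtpCost(core, "GLUD")
  glns <- ammoniumAssimilationAtpCost(core, "GLNS_GLUS")
  expect_equal(glud, 0)
  expect_equal(glns, 1)
  expect_equal(glns - glud, 1)
  # purely stoichiometric: bounds do not matter
  squeezed <- setReactionBounds(core, c("GLNS", "GLUSy", "GLUDy"),
                                lower = 0, upper = 0)
  expect_equal(ammoniumAssimilationAtpCost(squeezed, "GLNS_GLUS"), 1)
  noglu <- chain_model()
  expect_error(ammoniumAssimilationAtpCost(noglu, "GLUD"), "missing")
})

test_that("prose aliases resolve to curated reaction ids", {
  expect_equal(resolveReactionAlias(c("LDH", "PTA", "GLUD", "HFS")),
               c("LDH_L", "PTAr", "GLUDy", "HFS"))
})
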