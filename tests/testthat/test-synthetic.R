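test_that("generators are deterministic under their seed", {
  a <- generateLinearPathway(4, seed = 9)
  b <- generateLinearPathway(4, seed = 9)
  expect_equal(a@model@reactions, b@model@reactions)
  expect_equal(a@groundTruth, b@groundTruth)
  c1 <- generateCoupledToy(seed = 5)
  c2 <- generateCoupledToy(seed = 5)
  expect_equal(c1@model@reactions, c2@model@reactions)
  d1 <- degradeModel(c1@model, 2, seed = 13)
  d2 <- degradeModel(c2@model, 2, seed = 13)
  expect_equal(d1@groundTruth$removed, d2@groundTruth$removed)
  # a different seed changes the drawn capacities
  expect_false(identical(generateLinearPathway(4, seed = 10)@model@reactions,
                         a@model@reactions))
})

test_that("linear pathway ground truth matches the bottleneck algebra", {
  b <- generateLinearPathway(3, uptake_bound = 10, seed = 1)
  expect_equal(b@groundTruth$optimum, 10)
  expect_equal(solveFBA(b@model)@objectiveValue, 10, tolerance = 1e-8)
  b1 <- generateLinearPathway(1, uptake_bound = 10, seed = 2)
  expect_equal(solveFBA(b1@model)@objectiveValue, 10, tolerance = 1e-8)
  tight <- generateLinearPathway(4, uptake_bound = 10, seed = 3,
                                 tight_step = 2, tight_bound = 4.5)
  expect_equal(tight@groundTruth$optimum, 4.5)
  expect_equal(solveFBA(tight@model)@objectiveValue, 4.5, tolerance = 1e-8)
})

test_that("coupled toy reproduces its hand-derived coupling structure", {
  b <- generateCoupledToy(seed = 4, uptake_bound = 10)
  m <- b@model
  expect_equal(solveFBA(m)@objectiveValue, b@groundTruth$wild_optimum,
               tolerance = 1e-6)
  # intact: the vent makes the product avoidable at optimum
  expect_equal(couplingStrength(m, "EX_prodB", 1), 0, tolerance = 1e-5)
  # vent knocked out: growth halves, product is forced
  ko <- knockOutReactions(m, "SINKA")
  expect_equal(solveFBA(ko)@objectiveValue,
               b@groundTruth$sinkA_knockout_optimum, tolerance = 1e-6)
  expect_equal(couplingStrength(ko, "EX_prodB", 1),
               b@groundTruth$coupled_min_product, tolerance = 1e-3)
})

test_that("degradeModel guards its preconditions", {
  b <- generateLinearPathway(3, seed = 1)
  expect_error(degradeModel(b@model, k = 50, seed = 1), "essential")
  d0 <- degradeModel(b@model, k = 0, seed = 1)
  expect_equal(nrow(d0@model@reactions), nrow(b@model@reactions))
  g <- gapFill(d0@model, d0@universe)
  expect_length(g@added, 0L)
})

test_that("bundles round-trip through their directory serialization", {
  dir <- withr::local_tempdir()
  b <- degradeModel(generateCoupledToy(seed = 2)@model, 1, seed = 6)
  writeSyntheticBundle(b, dir)
  b2 <- readSyntheticBundle(dir)
  expect_equal(b2@seed, b@seed)
  expect_equal(b2@groundTruth$removed, b@groundTruth$removed)
  expect_equal(b2@model@reactions, b@model@reactions)
  expect_equal(b2@model@stoichiometry[reactionIds(b@model)],
               b@model@stoichiometry)
  expect_equal(b2@universe@reactions$id, b@universe@reactions$id)
})

test_that("export helpers produce stable TSV with explicit NA tokens", {
  dir <- withr::local_tempdir()
  hfs <- strainModel(core_constrained(), "ldh_hfs")
  g <- phasePlane(hfs, "EX_glc", "EX_etoh", c(-10, 0), c(0, 20),
                  n_points = 4)
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  exportTSV(g, p1); exportTSV(g, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-stable
  txt <- readLines(p1)
  expect_true(any(grepl("\tNA", txt)))  # infeasible cells are NA, not 0
  env <- productionEnvelope(hfs, "EX_etoh", n_points = 4)
  exportTSV(env, p1)
  expect_equal(readLines(p1)[1], "growth\tmin_product\tmax_product")
})
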