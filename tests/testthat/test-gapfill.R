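test_that("a single missing secretion step is uniquely repaired", {
  full <- chain_model(10)
  draft <- thermoflux:::.subset_reactions(full, setdiff(reactionIds(full), "T2"))
  universe <- thermoflux:::.subset_reactions(full, "T2",
                                             keep_objective = FALSE)
  g <- gapFill(draft, universe)
  expect_identical(g@status, "optimal")
  expect_identical(g@added, "T2")
  expect_gte(g@growth, 1e-3)
})

test_that("a feasible draft needs no additions", {
  b <- generateCoupledToy(seed = 1)
  g <- gapFill(b@model, chain_model())
  expect_identical(g@status, "optimal")
  expect_length(g@added, 0L)
})

test_that("an insufficient universe yields an explicit infeasible status", {
  full <- chain_model(10)
  draft <- thermoflux:::.subset_reactions(full, setdiff(reactionIds(full), "T2"))
  empty_uni <- thermoflux:::.subset_reactions(full, character(),
                                              keep_objective = FALSE)
  g <- gapFill(draft, empty_uni)
  expect_identical(g@status, "infeasible")
})

test_that("degrade-then-repair recovers growth with minimal additions", {
  for (seed in 1:6) {
    base <- generateLinearPathway(4, uptake_bound = 10, seed = seed)@model
    k <- 1 + (seed %% 3)
    d <- degradeModel(base, k = k, seed = seed)
    expect_length(d@groundTruth$removed, k)
    draft_growth <- solveFBA(d@model)
    expect_true(!identical(draft_growth@status, "optimal") ||
                draft_growth@objectiveValue < 1e-3)
    g <- gapFill(d@model, d@universe)
    expect_identical(g@status, "optimal")
    expect_lte(length(g@added), k)   # the removed set is always a repair
    expect_gte(g@growth, 1e-3)
    expect_true(gapfill_is_minimal(d@model, d@universe, g@added))
    expect_false(any(grepl("^DECOY", g@added)))
  }
})

test_that("growing the universe never enlarges the repair", {
  base <- generateCoupledToy(seed = 5)@model
  d <- degradeModel(base, k = 2, seed = 7, n_decoys = 2)
  small <- gapFill(d@model, d@universe)
  big_uni <- thermoflux:::.concat_models(
    d@universe,
    makeModel(data.frame(id = sprintf("PAD%d", 1:6),
                         formula = sprintf("pa%d[c] -> pb%d[c]", 1:6, 1:6),
                         stringsAsFactors = FALSE)))
  big <- gapFill(d@model, big_uni)
  expect_identical(big@status, "optimal")
  expect_lte(length(big@added), length(small@added))
})

test_that("reported growth is reproduced by plain FBA on draft + additions", {
  base <- generateLinearPathway(5, uptake_bound = 8, seed = 11)@model
  d <- degradeModel(base, k = 2, seed = 3)
  g <- gapFill(d@model, d@universe)
  patched <- thermoflux:::.merge_models(d@model, d@universe, g@added)
  expect_equal(solveFBA(patched)@objectiveValue, g@growth, tolerance = 1e-6)
})
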