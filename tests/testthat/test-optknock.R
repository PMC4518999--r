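test_that("the coupled toy's single best knockout is the electron valve", {
  b <- generateCoupledToy(seed = 1)
  d <- optKnock(b@model, "EX_prodB", 1)
  expect_identical(d@reactions, "SINKA")
  expect_equal(d@growth, b@groundTruth$sinkA_knockout_optimum,
               tolerance = 1e-5)
  expect_equal(d@productMin, b@groundTruth$coupled_min_product,
               tolerance = 1e-4)
  o <- exhaustiveDesignSearch(b@model, "EX_prodB", 1)
  expect_identical(o@reactions, d@reactions)
  expect_equal(o@productMin, d@productMin, tolerance = 1e-4)
})

test_that("MILP and exhaustive oracle agree across seeded toys and modes", {
  for (seed in 1:5) {
    b <- generateCoupledToy(seed = seed, uptake_bound = 4 + seed)
    for (K in 1:2) {
      for (mode in c("coupled_min", "max_at_optimum")) {
        d <- optKnock(b@model, "EX_prodB", K, objective = mode)
        o <- exhaustiveDesignSearch(b@model, "EX_prodB", K, objective = mode)
        expect_identical(d@reactions, o@reactions,
                         label = sprintf("seed %d K %d %s", seed, K, mode))
        expect_equal(d@productMin, o@productMin, tolerance = 1e-4)
        expect_equal(d@productMax, o@productMax, tolerance = 1e-4)
        # strong-duality consistency: recorded growth equals plain FBA
        ko <- knockOutReactions(b@model, d@reactions)
        expect_equal(d@growth, solveFBA(ko)@objectiveValue, tolerance = 1e-6)
      }
    }
  }
})

test_that("objective is monotone in K and respects min_growth", {
  b <- generateCoupledToy(seed = 3)
  v <- sapply(0:2, function(K)
    optKnock(b@model, "EX_prodB", K)@productMin)
  expect_true(all(diff(v) >= -1e-6))
  # K = 0 returns the wild type
  d0 <- optKnock(b@model, "EX_prodB", 0)
  expect_length(d0@reactions, 0L)
  expect_equal(d0@growth, b@groundTruth$wild_optimum, tolerance = 1e-5)
  # an unattainable growth floor yields an explicit no-design result
  dn <- optKnock(b@model, "EX_prodB", 1,
                 min_growth = 10 * b@groundTruth$wild_optimum)
  expect_identical(dn@status, "no_design")
  # raising min_growth cannot improve the coupled objective
  lo <- optKnock(b@model, "EX_prodB", 1,
                 min_growth = 0.05 * b@groundTruth$wild_optimum)@productMin
  hi <- optKnock(b@model, "EX_prodB", 1,
                 min_growth = 1.5 * b@groundTruth$sinkA_knockout_optimum)
  expect_lte(if (identical(hi@status, "no_design")) -Inf else hi@productMin,
             lo + 1e-6)
})

test_that("candidate preconditions are enforced", {
  b <- generateCoupledToy(seed = 1)
  expect_error(optKnock(b@model, "EX_prodB", 1, candidates = "EX_S"),
               "exclude exchange")
  expect_error(optKnock(b@model, "EX_prodB", 1, candidates = "BIO"),
               "exclude")
  expect_error(optKnock(b@model, "EX_prodB", 1, candidates = "NOPE"),
               "unknown")
  expect_error(exhaustiveDesignSearch(b@model, "EX_prodB", 3,
                                      subset_guard = 2),
               "guard")
})

test_that("verifyDesign reproduces recorded values and flags corruption", {
  b <- generateCoupledToy(seed = 2)
  d <- optKnock(b@model, "EX_prodB", 1)
  v <- verifyDesign(b@model, d)
  expect_true(v$consistent)
  bad <- d
  bad@growth <- d@growth * 1.05
  v2 <- verifyDesign(b@model, bad)
  expect_false(v2$consistent)
  expect_match(v2$discrepancies, "growth", all = FALSE)
})
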