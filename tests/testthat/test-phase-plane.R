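test_that("phase-plane cells equal direct fixed-flux FBA", {
  wt <- strainModel(core_constrained(), "WT")
  g <- phasePlane(wt, "EX_glc", "EX_etoh", x_range = c(-10, 0),
                  y_range = c(0, 20), n_points = 5)
  for (i in seq_along(g@x)) {
    for (j in seq_along(g@y)) {
      r <- optimizeWithFixedFluxes(wt, setNames(c(g@x[i], g@y[j]),
                                                c("EX_glc", "EX_etoh")))
      if (is.na(g@growth[i, j])) {
        expect_false(identical(r@status, "optimal"))
      } else {
        expect_equal(g@growth[i, j], r@objectiveValue, tolerance = 1e-6)
      }
    }
  }
  expect_error(phasePlane(wt, "EX_glc", "EX_glc", c(-10, 0), c(0, 1)),
               "different")
})

test_that("wild-type optimum spans many ethanol values, ldh_hfs few", {
  core <- core_constrained()
  wt <- strainModel(core, "WT")
  hfs <- strainModel(core, "ldh_hfs")
  gw <- phasePlane(wt, "EX_glc", "EX_etoh", c(-10, -10), c(0, 18),
                   n_points = 19)
  gh <- phasePlane(hfs, "EX_glc", "EX_etoh", c(-10, -10), c(0, 18),
                   n_points = 19)
  # x is pinned at full uptake, so examine one row of ethanol cells
  near_max <- function(g) {
    row <- g@growth[1, ]
    sum(!is.na(row) & row > max(row, na.rm = TRUE) - 1e-6)
  }
  expect_gte(near_max(gw), 5)   # optimal growth across a wide ethanol range
  expect_lte(near_max(gh), 2)   # tightly dictated ethanol flux
})

test_that("production envelopes are closed, ordered and coupled as expected", {
  core <- core_constrained()
  wt <- strainModel(core, "WT")
  hfs <- strainModel(core, "ldh_hfs")
  ew <- productionEnvelope(wt, "EX_etoh", n_points = 12)
  eh <- productionEnvelope(hfs, "EX_etoh", n_points = 12)
  expect_true(all(ew@minProduct <= ew@maxProduct + 1e-6, na.rm = TRUE))
  # at rest with free uptake, secretion can always be off
  expect_equal(ew@minProduct[1], 0, tolerance = 1e-6)
  # wild type keeps slack at max growth; the electron-centred strain not
  n <- length(ew@growth)
  expect_gt(ew@maxProduct[n] - ew@minProduct[n], 1)
  expect_gt(eh@minProduct[length(eh@growth)], 0)
  expect_lt(eh@maxProduct[length(eh@growth)] -
            eh@minProduct[length(eh@growth)], 0.5)
})

test_that("envelope values are invariant to grid resolution at shared points", {
  hfs <- strainModel(core_constrained(), "ldh_hfs")
  e5 <- productionEnvelope(hfs, "EX_etoh", n_points = 5)
  e9 <- productionEnvelope(hfs, "EX_etoh", n_points = 9)
  # growth grids share endpoints and midpoint
  shared5 <- c(1, 3, 5); shared9 <- c(1, 5, 9)
  expect_equal(e5@growth[shared5], e9@growth[shared9], tolerance = 1e-9)
  expect_equal(e5@minProduct[shared5], e9@minProduct[shared9],
               tolerance = 1e-5)
  expect_equal(e5@maxProduct[shared5], e9@maxProduct[shared9],
               tolerance = 1e-5)
})

test_that("coupling strength is ordered across strains and monotone", {
  core <- core_constrained()
  cs <- sapply(c("WT", "ldh_pta", "ldh_hfs"), function(s)
    couplingStrength(strainModel(core, s), "EX_etoh", 0.99))
  expect_gt(cs[["ldh_hfs"]], cs[["ldh_pta"]])
  expect_gte(cs[["ldh_pta"]], cs[["WT"]])
  hfs <- strainModel(core, "ldh_hfs")
  vals <- sapply(c(0.2, 0.6, 0.9, 1), function(f)
    couplingStrength(hfs, "EX_etoh", f))
  expect_true(all(diff(vals) >= -1e-6))  # non-decreasing in fraction
  # fraction 0 with free secretion imposes nothing
  expect_equal(couplingStrength(strainModel(core, "WT"), "EX_etoh", 0), 0,
               tolerance = 1e-6)
})
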