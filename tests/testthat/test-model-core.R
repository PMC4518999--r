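test_that("formula parsing handles the curated-table grammar", {
  p <- parseReactionFormula(
    "glu-L[c] + ATP[c] + NH4[c] - > ADP[c] + Pi[c] + H[c] + gln-L[c]")
  expect_false(p$reversible)
  expect_equal(p$stoichiometry[c("glu-L[c]", "ATP[c]", "NH4[c]")],
               c("glu-L[c]" = -1, "ATP[c]" = -1, "NH4[c]" = -1))
  expect_equal(p$stoichiometry[c("ADP[c]", "Pi[c]", "H[c]", "gln-L[c]")],
               c("ADP[c]" = 1, "Pi[c]" = 1, "H[c]" = 1, "gln-L[c]" = 1))

  # spaced arrows, spaced compartment suffix, "< == >", default compartment
  p2 <- parseReactionFormula("lac-L[c] + NAD[c] < = > NADH [c] + H[c] + pyr[c]")
  expect_true(p2$reversible)
  expect_equal(p2$stoichiometry[["NADH[c]"]], 1)
  p3 <- parseReactionFormula("Fdred[c] + 2 h[c] < == > Fdox + H2[c]")
  expect_true(p3$reversible)
  expect_equal(p3$stoichiometry[["Fdox[c]"]], 1)  # bare token defaults to [c]
  expect_equal(p3$stoichiometry[["h[c]"]], -2)

  # exchange: one empty side
  ex <- parseReactionFormula("glc-D[e] ->")
  expect_true(ex$is_exchange)
  expect_equal(ex$stoichiometry, c("glc-D[e]" = -1))

  expect_error(parseReactionFormula("A[c] B[c]"), "arrow")
  expect_error(parseReactionFormula("A[c] -> B[c] -> C[c]"), "more than one")
  expect_error(parseReactionFormula("A[c] + + -> B[c]"), "term")
})

test_that("stoichiometric matrix matches definitions", {
  m <- makeModel(data.frame(id = "R1", formula = "A[c] -> B[c]",
                            stringsAsFactors = FALSE))
  S <- stoichiometricMatrix(m)
  expect_equal(S["A[c]", "R1"], -1)
  expect_equal(S["B[c]", "R1"], 1)
  expect_equal(dim(S), c(2L, 1L))

  core <- buildCoreModel()
  S <- stoichiometricMatrix(core)
  expect_equal(dim(S), c(nrow(core@metabolites), nrow(core@reactions)))
  glns <- S[, "GLNS"]
  expect_equal(glns[c("glu-L[c]", "ATP[c]", "NH4[c]")],
               c("glu-L[c]" = -1, "ATP[c]" = -1, "NH4[c]" = -1))
  expect_equal(glns[c("ADP[c]", "Pi[c]", "H[c]", "gln-L[c]")],
               c("ADP[c]" = 1, "Pi[c]" = 1, "H[c]" = 1, "gln-L[c]" = 1))
  expect_equal(sum(glns != 0), 7L)

  empty <- new("MetabolicModel")
  expect_equal(dim(stoichiometricMatrix(empty)), c(0L, 0L))
})

test_that("gene rules evaluate with standard boolean semantics", {
  hfs <- "Tsac_1550 & Tsac_1551 & Tsac_1552 & Tsac_1553"
  expect_false(evaluateGeneRule(hfs, "Tsac_1550"))
  expect_false(evaluateGeneRule(hfs, "Tsac_1553"))
  expect_true(evaluateGeneRule(hfs, character()))
  expect_true(evaluateGeneRule("Tsac_0179", character()))
  expect_false(evaluateGeneRule("Tsac_0179", "Tsac_0179"))
  expect_true(evaluateGeneRule("(a & b) | c", "a"))
  expect_false(evaluateGeneRule("(a & b) | c", c("a", "c")))
  expect_true(evaluateGeneRule("", c("a", "b", "c")))  # no gene associated
  expect_error(evaluateGeneRule("a &", ""), "malformed")
  expect_error(evaluateGeneRule("a & system('x')", "a"), "malformed")
  expect_setequal(ruleGenes(hfs),
                  c("Tsac_1550", "Tsac_1551", "Tsac_1552", "Tsac_1553"))
})

test_that("gene rule evaluation is monotone in the deletion set", {
  rules <- c("(a & b) | (c & d)", "a | b | c", "a & (b | c) & d", "x",
             "(a | b) & (c | d) & e")
  genes <- letters[1:5]
  set.seed(42)
  for (r in rules) {
    for (rep in 1:20) {
      small <- sample(genes, sample(0:3, 1))
      extra <- sample(setdiff(genes, small), sample(0:2, 1))
      big <- union(small, extra)
      # growing the deletion set can only flip TRUE -> FALSE
      if (!evaluateGeneRule(r, small)) {
        expect_false(evaluateGeneRule(r, big))
      }
    }
  }
})

test_that("validation reports structural defects without raising", {
  toy <- chain_model()
  rep <- validateModel(toy)
  expect_equal(nrow(rep@errors), 0L)
  expect_equal(unname(rep@statistics["reactions"]), 4L)

  bad <- setReactionBounds(toy, "T1", lower = 5, upper = 1)
  rep <- validateModel(bad)
  expect_true("BOUNDS_INVERTED" %in% rep@errors$code)

  dup <- toy
  dup@metabolites <- rbind(dup@metabolites, dup@metabolites[1, ])
  rep <- validateModel(dup)
  expect_true("DUPLICATE_METABOLITE" %in% rep@errors$code)

  orphan <- toy
  orphan@metabolites <- rbind(orphan@metabolites,
                              data.frame(id = "X[c]", name = "X",
                                         compartment = "c", formula = ""))
  rep <- validateModel(orphan)
  expect_equal(nrow(rep@errors), 0L)
  expect_true("ORPHAN_METABOLITE" %in% rep@warnings$code)

  unresolved <- toy
  unresolved@stoichiometry[["T1"]] <- c("A[e]" = -1, "GHOST[c]" = 1)
  rep <- validateModel(unresolved)
  expect_true("UNRESOLVED_METABOLITE" %in% rep@errors$code)
})

test_that("elemental balance checking is advisory and formula-gated", {
  ok <- makeModel(data.frame(id = "ISO", formula = "A[c] -> B[c]",
                             stringsAsFactors = FALSE),
                  metabolite_formulas = c("A[c]" = "C6H12O6",
                                          "B[c]" = "C6H12O6"))
  expect_false("ELEMENTAL_IMBALANCE" %in% validateModel(ok)@warnings$code)
  bad <- makeModel(data.frame(id = "SPLIT", formula = "A[c] -> B[c]",
                              stringsAsFactors = FALSE),
                   metabolite_formulas = c("A[c]" = "C6H12O6",
                                           "B[c]" = "C3H6O3"))
  rep <- validateModel(bad)
  expect_equal(nrow(rep@errors), 0L)  # advisory, not an error
  expect_true("ELEMENTAL_IMBALANCE" %in% rep@warnings$code)
})

test_that("knockouts zero bounds on a copy and preserve structure", {
  core <- buildCoreModel()
  ko <- knockOutReactions(core, "LDH_L")
  i <- match("LDH_L", ko@reactions$id)
  expect_equal(ko@reactions$lower_bound[i], 0)
  expect_equal(ko@reactions$upper_bound[i], 0)
  expect_equal(nrow(ko@reactions), nrow(core@reactions))
  expect_equal(nrow(ko@metabolites), nrow(core@metabolites))
  # original untouched
  expect_lt(core@reactions$lower_bound[i], 0)
  # identity and error cases
  expect_identical(knockOutReactions(core, character()), core)
  expect_error(knockOutReactions(core, c("LDH_L", "NOPE")), "NOPE")
})

test_that("gene deletions propagate through GPR rules", {
  core <- buildCoreModel()
  expect_equal(reactionsDisabledByGenes(core, "Tsac_0179"), "LDH_L")
  for (g in c("Tsac_1550", "Tsac_1551", "Tsac_1552", "Tsac_1553")) {
    expect_true("HFS" %in% reactionsDisabledByGenes(core, g))
  }
  expect_equal(reactionsDisabledByGenes(core, character()), character())
})
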