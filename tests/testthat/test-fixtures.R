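test_that("the shipped core-model fixtures equal the in-code constructor", {
  built <- buildCoreModel()
  for (f in c("tsac_core.json", "tsac_core.tsv")) {
    path <- system.file("extdata", f, package = "thermoflux")
    expect_true(nzchar(path), label = f)
    m <- readModel(path)
    expect_equal(m@reactions, built@reactions, label = f)
    expect_equal(m@stoichiometry[reactionIds(built)], built@stoichiometry,
                 label = f)
    expect_equal(m@objectiveId, built@objectiveId, label = f)
  }
})
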