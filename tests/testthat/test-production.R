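test_that("sink reactions are named canonically and added idempotently", {
  core <- make_glutamate_core()
  m <- add_sink(core, "glu__L_c")
  expect_true("sink_glu__L" %in% m$reactions$id)
  i <- match("sink_glu__L", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], 0)
  expect_equal(m$reactions$upper_bound[i], 1000)
  expect_identical(m$reactions$sbo[i], "SBO:0000632")
  # twice -> one reaction
  m2 <- add_sink(m, "glu__L_c")
  expect_equal(sum(m2$reactions$id == "sink_glu__L"), 1)
  # bare id resolves to the cytosolic form
  m3 <- add_sink(core, "glu__L")
  expect_true("sink_glu__L" %in% m3$reactions$id)
  expect_error(add_sink(core, "unobtainium_c"), "unknown metabolite")
})

test_that("the amino-acid profile records production economics at the optimum", {
  prof <- amino_acid_profile(make_glutamate_core(), growth_fix = 0.4)
  expect_equal(nrow(prof), 1)           # only glutamate exists in the core
  expect_identical(prof$metabolite, "glu__L_c")
  expect_equal(prof$production_rate, 10 - 0.0149 * 0.4, tolerance = 1e-8)
  expect_equal(prof$yield_on_glucose, prof$production_rate / 10,
               tolerance = 1e-10)
  # one CO2 is released per glutamate made (PDH + IDH emit two, one is
  # re-fixed by anaplerosis), and biomass-bound glutamate also counts
  expect_equal(prof$co2_rate, 10, tolerance = 1e-6)
  # ATP comes from glycolysis (10) + oxidative phosphorylation (75);
  # pyruvate-kinase flux (0..10) is vertex-dependent
  expect_gte(prof$atp_rate, 85 - 1e-6)
  expect_lte(prof$atp_rate, 95 + 1e-6)
  # infeasible growth fixes are refused with a named constraint
  expect_error(amino_acid_profile(make_glutamate_core(), growth_fix = 50),
               "cannot fix|infeasible")
})

test_that("the growth-glutamate trade-off is the exact hand-derived line", {
  core <- make_glutamate_core()
  tc <- tradeoff_curve(core, "glu__L_c")
  expect_equal(nrow(tc), 30)
  expect_equal(max(tc$mu), 2.125, tolerance = 1e-8)
  ok <- tc$status == "optimal"
  expect_true(all(ok))
  expect_equal(tc$production, 10 - 0.0149 * tc$mu, tolerance = 1e-6)
  # endpoints
  expect_equal(tc$production[1], 10, tolerance = 1e-8)
  # slightly beyond the maximal growth rate the point is infeasible
  beyond <- tradeoff_curve(core, "glu__L_c", mu_grid = c(0.4, 2.125 + 1e-3))
  expect_identical(beyond$status[2], "infeasible")
})

test_that("trade-off curves are non-increasing and concave", {
  for (m in list(make_glutamate_core(), core_with_sink())) {
    tc <- tradeoff_curve(m, "glu__L_c")
    p <- tc$production[tc$status == "optimal"]
    expect_true(all(diff(p) <= 1e-7))
    if (length(p) > 2) {
      expect_true(all(diff(diff(p)) <= 1e-6))
    }
  }
})

test_that("pyruvate-carboxylase knock-out is compensated by PEP carboxylase", {
  core <- make_glutamate_core()
  ko <- knockout_experiment(core, reaction_id = "PC", product = "glu__L_c",
                            growth_fix = 0.4)
  expect_identical(ko$before$status, "optimal")
  expect_identical(ko$after$status, "optimal")
  expect_equal(ko$after$production_rate, ko$before$production_rate,
               tolerance = 1e-6)
  expect_equal(ko$before$production_rate, 9.99404, tolerance = 1e-6)
  # the KO run carries zero flux through the knocked reaction
  expect_equal(ko$fluxes$flux_ko[ko$fluxes$id == "PC"], 0)
  # paired flux tables cover every reaction for map plotting
  expect_setequal(ko$fluxes$id, add_sink(fix_flux(core, "BIOMASS_core", 0.4),
                                         "glu__L_c")$reactions$id)
})

test_that("removing both anaplerotic routes abolishes glutamate production", {
  core <- knockout(make_glutamate_core(), "PPC")
  # with growth fixed > 0 the model cannot even sustain biomass
  ko <- knockout_experiment(core, reaction_id = "PC", growth_fix = 0.4)
  expect_identical(ko$after$status, "infeasible")
  # at zero growth the production collapses to zero
  ko0 <- knockout_experiment(core, reaction_id = "PC", growth_fix = 0)
  expect_equal(ko0$after$production_rate, 0, tolerance = 1e-8)
  expect_gt(ko0$before$production_rate, 9)
})

test_that("no single knock-out ever increases production", {
  core <- make_glutamate_core()
  base <- knockout_experiment(core, reaction_id = "PC", growth_fix = 0.4)$before
  for (rid in setdiff(core$reactions$id, "BIOMASS_core")) {
    ko <- knockout_experiment(core, reaction_id = rid, growth_fix = 0.4)
    if (ko$after$status == "optimal") {
      expect_lte(ko$after$production_rate,
                 base$production_rate + 1e-6)
    }
  }
})

test_that("pinned reactions are the rigid backbone of glutamate production", {
  pr <- pinned_reactions(make_glutamate_core(), product = "glu__L_c",
                         growth_fix = 0.4)
  # the anaplerotic split (PC vs PEP carboxylase, balanced by pyruvate
  # kinase) is the only freedom left at the fixed optimum
  expect_setequal(setdiff(pr$ranges$id, pr$pinned), c("PC", "PPC", "PYK"))
  expect_true(all(c("GLCpts", "EX_glc__D_e", "CS", "ACONT", "ICDHyr",
                    "GDH", "sink_glu__L") %in% pr$pinned))
  rng <- pr$ranges
  for (rid in c("PC", "PPC", "PYK")) {
    expect_equal(rng$min[rng$id == rid], 0, tolerance = 1e-6)
    expect_equal(rng$max[rng$id == rid], 10, tolerance = 1e-5)
  }
  expect_equal(rng$min[rng$id == "EX_glc__D_e"], -10, tolerance = 1e-6)
  expect_equal(rng$max[rng$id == "sink_glu__L"], 9.99404, tolerance = 1e-6)
  # the pinned set is stable under reaction reordering
  shuf <- make_glutamate_core()
  set.seed(1)
  perm <- sample(nrow(shuf$reactions))
  shuf$reactions <- shuf$reactions[perm, ]
  rownames(shuf$reactions) <- NULL
  shuf$stoichiometry <- shuf$stoichiometry[shuf$reactions$id]
  pr2 <- pinned_reactions(shuf, product = "glu__L_c", growth_fix = 0.4)
  expect_setequal(pr2$pinned, pr$pinned)
})
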