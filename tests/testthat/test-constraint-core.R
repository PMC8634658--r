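test_that("the stoichiometric matrix mirrors reaction stoichiometry exactly", {
  core <- make_glutamate_core()
  S <- build_matrix(core)
  expect_identical(dim(S), c(nrow(core$metabolites), nrow(core$reactions)))
  # citrate synthase: three reactants, three products, unit coefficients
  cs <- S[, "CS"]
  expect_equal(cs[c("accoa_c", "h2o_c", "oaa_c")],
               c(accoa_c = -1, h2o_c = -1, oaa_c = -1))
  expect_equal(cs[c("cit_c", "coa_c", "h_c")],
               c(cit_c = 1, coa_c = 1, h_c = 1))
  expect_equal(sum(cs != 0), 6)
  # simple conversion column
  ch <- make_linear_chain(3)
  Sc <- build_matrix(ch)
  expect_equal(Sc[c("M1_c", "M2_c"), "R1"], c(M1_c = -1, M2_c = 1))
  # empty model
  empty <- gem_model("empty")
  expect_identical(dim(build_matrix(empty)), c(0L, 0L))
})

test_that("FBA reproduces flow-conservation optima on the linear chain", {
  expect_equal(fba(make_linear_chain(4, uptake = 10))$objective, 10,
               tolerance = 1e-9)
  expect_equal(fba(make_linear_chain(1, uptake = 7))$objective, 7,
               tolerance = 1e-9)
  expect_equal(fba(make_linear_chain(3, uptake = 0))$objective, 0,
               tolerance = 1e-9)
  # forcing the objective's bounds forces its optimum
  m <- fix_flux(make_linear_chain(3), "BIOMASS", 0.4)
  expect_equal(fba(m)$objective, 0.4, tolerance = 1e-9)
  expect_error(fba(make_linear_chain(3), "NOPE"), "unknown reaction")
})

test_that("optimal flux vectors satisfy conservation and bounds", {
  models <- list(make_linear_chain(5), make_glutamate_core(),
                 core_with_sink())
  for (m in models) {
    sol <- fba(m)
    expect_identical(sol$status, "optimal")
    S <- build_matrix(m)
    expect_lt(max(abs(as.vector(S %*% sol$fluxes))), 1e-6)
    expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-8))
    expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-8))
    # objective value is reproducible across repeated calls
    expect_equal(fba(m)$objective, sol$objective, tolerance = 1e-6)
  }
})

test_that("fix_flux constrains a copy and rejects values outside bounds", {
  core <- make_glutamate_core()
  fixed <- fix_flux(core, "BIOMASS_core", 0.4)
  i <- match("BIOMASS_core", fixed$reactions$id)
  expect_equal(fixed$reactions$lower_bound[i], 0.4)
  expect_equal(fixed$reactions$upper_bound[i], 0.4)
  # original untouched
  expect_equal(core$reactions$lower_bound[i], 0)
  expect_error(fix_flux(core, "BIOMASS_core", -1), "outside")
  # fixing growth and maximising the sink keeps growth pinned in solution
  m <- add_sink(fixed, "glu__L_c")
  sol <- fba(m, "sink_glu__L")
  expect_equal(unname(sol$fluxes["BIOMASS_core"]), 0.4, tolerance = 1e-8)
})

test_that("fixing a structurally blocked reaction turns the model infeasible", {
  # dead-end branch: M2 -> D has an open bound range but can never carry
  # steady-state flux because D has no consumer
  ch <- make_linear_chain(3)
  ch <- plant_defect(ch, "dead_end", target = "M2_c")
  expect_equal(fva(ch, "DE1")$min, 0, tolerance = 1e-9)
  expect_equal(fva(ch, "DE1")$max, 0, tolerance = 1e-9)
  forced <- fix_flux(ch, "DE1", 1)
  expect_identical(fba(forced)$status, "infeasible")
})

test_that("knockouts obey reaction closure and GPR boolean semantics", {
  core <- make_glutamate_core()
  base <- fba(core)$objective
  # zero-flux reaction KO leaves the optimum unchanged
  sol <- fba(core)
  zf <- names(sol$fluxes)[abs(sol$fluxes) < 1e-9 &
                            !(names(sol$fluxes) %in% core$objective)][1]
  expect_equal(fba(knockout(core, zf))$objective, base, tolerance = 1e-6)
  # knocking out the sole path collapses growth
  ch <- make_linear_chain(3)
  expect_equal(fba(knockout(ch, "R1"))$objective, 0, tolerance = 1e-9)
  # gene KO: AND requires all subunits, OR tolerates isozyme loss
  i <- match("PDH", core$reactions$id)     # gpr: aceE and aceF and lpd
  ko <- knockout(core, "aceF")
  expect_equal(ko$reactions$upper_bound[i], 0)
  core2 <- core
  core2$reactions$gpr[i] <- "aceE or aceF"
  ko2 <- knockout(core2, "aceF")
  expect_equal(ko2$reactions$upper_bound[i], 1000)
  expect_error(knockout(core, "no_such_thing"), "neither reaction nor gene")
})

test_that("FVA brackets FBA and pins the carbon source at a fixed optimum", {
  core <- core_with_sink()
  sol <- fba(core)
  rng <- fva(core)
  expect_true(all(rng$min <= sol$fluxes[rng$id] + 1e-6))
  expect_true(all(sol$fluxes[rng$id] <= rng$max + 1e-6))
  # with growth fixed at its optimum the sole carbon exchange is pinned
  ch <- make_linear_chain(3, uptake = 10)
  chf <- fix_flux(ch, "BIOMASS", 10)
  ex <- fva(chf, "EX_M1_e")
  expect_equal(ex$min, -10, tolerance = 1e-8)
  expect_equal(ex$max, -10, tolerance = 1e-8)
  expect_error(fva(fix_flux(plant_defect(ch, "dead_end"), "DE1", 1)),
               "infeasible")
})
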