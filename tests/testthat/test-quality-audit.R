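test_that("balanced synthetic networks audit clean", {
  for (m in list(make_glutamate_core(), make_linear_chain(4))) {
    bal <- balance_audit(m)
    expect_true(all(bal$verdict == "balanced"))
    # pseudo-reactions (exchange, sink, biomass) are never audited
    expect_false(any(grepl("^EX_|^sink_|BIOMASS", bal$id)))
  }
})

test_that("planted mass and charge imbalances are detected with residuals", {
  mets <- list(met_spec("a_c", formula = "CH4", charge = 0L),
               met_spec("b_c", formula = "CH3", charge = 0L),
               met_spec("x_c", formula = "C", charge = 1L),
               met_spec("y_c", formula = "C", charge = 0L))
  rxns <- list(rxn_spec("MASS", c(a_c = -1, b_c = 1), lb = 0),
               rxn_spec("CHARGE", c(x_c = -1, y_c = 1), lb = 0))
  m <- gem_model("defects", mets, rxns)
  bal <- balance_audit(m)
  expect_identical(bal$verdict[bal$id == "MASS"], "mass_imbalanced")
  expect_equal(bal$element_residuals[bal$id == "MASS"][[1]][["H"]], -1)
  expect_identical(bal$verdict[bal$id == "CHARGE"], "charge_imbalanced")
  expect_equal(bal$charge_residual[bal$id == "CHARGE"], -1)
})

test_that("missing formulas or pseudo-elements make reactions unverifiable, not imbalanced", {
  mets <- list(met_spec("a_c", formula = NA, charge = 0L),
               met_spec("b_c", formula = "CH3", charge = 0L),
               met_spec("r1_c", formula = "C2R", charge = 0L),
               met_spec("r2_c", formula = "C2R", charge = 0L))
  rxns <- list(rxn_spec("NOFORM", c(a_c = -1, b_c = 1), lb = 0),
               rxn_spec("PSEUDOEL", c(r1_c = -1, r2_c = 1), lb = 0))
  bal <- balance_audit(gem_model("unver", mets, rxns))
  expect_identical(unique(bal$verdict), "unverifiable")
})

test_that("the balance audit flags exactly the planted defects", {
  core <- make_glutamate_core()
  planted <- character(0)
  # targets chosen with disjoint audited reactions: perturbing two
  # metabolites that share a reaction would cancel there
  for (tgt in c("cit_c", "akg_c", "g6p_c")) {
    core <- plant_defect(core, "imbalance", target = tgt)
    planted <- union(planted, attr(core, "planted")$reactions)
  }
  bal <- balance_audit(core)
  flagged <- bal$id[bal$verdict != "balanced"]
  expect_setequal(flagged, planted)
  expect_true(all(bal$verdict[bal$id %in% planted] == "mass_imbalanced"))
})

test_that("dead-end and orphan detection respects reversibility and exchanges", {
  clean <- find_dead_ends(make_glutamate_core())
  expect_length(clean$dead_end, 0)
  expect_length(clean$orphan, 0)
  # produced but never consumed
  m <- plant_defect(make_linear_chain(3), "dead_end")
  de <- find_dead_ends(m)
  expect_identical(de$dead_end, attr(m, "planted")$metabolite)
  expect_length(de$orphan, 0)
  # consumed but never produced
  m2 <- plant_defect(make_linear_chain(3), "orphan")
  de2 <- find_dead_ends(m2)
  expect_identical(de2$orphan, attr(m2, "planted")$metabolite)
  expect_length(de2$dead_end, 0)
  # a lone reversible conversion can produce either metabolite
  mets <- list(met_spec("a_c", formula = "C", charge = 0L),
               met_spec("b_c", formula = "C", charge = 0L))
  rxns <- list(rxn_spec("REV", c(a_c = -1, b_c = 1), lb = -1000))
  both <- find_dead_ends(gem_model("rev", mets, rxns))
  expect_length(both$orphan, 0)
})

test_that("stoichiometric consistency is 1 for balanced models and drops for mass creation", {
  expect_equal(stoichiometric_consistency(make_glutamate_core())$consistent_fraction,
               1, tolerance = 1e-9)
  expect_equal(stoichiometric_consistency(make_linear_chain(5))$consistent_fraction,
               1, tolerance = 1e-9)
  # A -> 2A creates mass from nothing; A cannot carry a positive conserved mass
  mets <- list(met_spec("a_c", formula = "C", charge = 0L),
               met_spec("b_c", formula = "C", charge = 0L))
  rxns <- list(rxn_spec("DOUBLE", c(a_c = 1), lb = 0),   # net A creation
               rxn_spec("CONV", c(a_c = -1, b_c = 1), lb = 0))
  m <- gem_model("inconsistent", mets, rxns)
  m$stoichiometry[["DOUBLE"]] <- c(a_c = 1)  # A -> 2A written as net +1 A
  cons <- stoichiometric_consistency(m)
  expect_lt(cons$consistent_fraction, 1)
  expect_true("a_c" %in% cons$inconsistent_metabolites)
})

test_that("biomass molecular weight follows the atomic-mass table and scaling law", {
  # biomass consuming exactly one glucose weighs 180.156 g/mol -> 0.180156 g/mmol
  mets <- list(met_spec("glc__D_c", formula = "C6H12O6", charge = 0L))
  rxns <- list(rxn_spec("BIOMASS", c(glc__D_c = -1), lb = 0,
                        sbo = "SBO:0000629"))
  m <- gem_model("bw", mets, rxns, objective = "BIOMASS")
  expect_equal(biomass_weight(m), 0.180156, tolerance = 1e-6)
  # scaling the equation by s scales the weight by s, and the maximal
  # growth rate by 1/s: the product (mass flux) is invariant
  core <- make_glutamate_core()
  s <- 2.5
  scaled <- core
  scaled$stoichiometry[["BIOMASS_core"]] <- s * core$stoichiometry[["BIOMASS_core"]]
  w1 <- biomass_weight(core); w2 <- biomass_weight(scaled)
  expect_equal(w2, s * w1, tolerance = 1e-9)
  mu1 <- fba(core)$objective; mu2 <- fba(scaled)$objective
  expect_equal(mu2, mu1 / s, tolerance = 1e-6)
  expect_equal(w1 * mu1, w2 * mu2, tolerance = 1e-6)
  # unverifiable without formulas
  m$metabolites$formula[1] <- NA
  expect_error(biomass_weight(m), "unverifiable")
})

test_that("the energy-generating-cycle scan is silent on clean models", {
  res <- suppressWarnings(egc_scan(make_glutamate_core()))
  present <- res[res$status != "absent", ]
  expect_true(all(c("atp", "nadh", "nadph", "glu__L") %in% present$carrier))
  expect_true(all(present$dissipation_flux <= 1e-6))
  # carriers whose species are missing are skipped, not errors
  expect_true(all(res$status[!(res$carrier %in% present$carrier)] == "absent"))
  expect_warning(egc_scan(make_linear_chain(3), carriers = "atp"), "skipped")
})

test_that("a planted cost-free charging reaction is detected as an EGC", {
  m <- plant_defect(make_glutamate_core(), "egc")
  res <- suppressWarnings(egc_scan(m, carriers = "atp"))
  expect_gt(res$dissipation_flux, 1e-6)
  expect_true(attr(m, "planted")$reactions[1] %in% res$cycle_support[[1]])
  # the cycle does not leak into other carriers
  res2 <- suppressWarnings(egc_scan(m))
  others <- res2[res2$status != "absent" & res2$carrier != "atp", ]
  expect_true(all(others$dissipation_flux <= 1e-6))
})

test_that("annotation coverage counts presence per class", {
  m <- make_linear_chain(2)
  cov0 <- annotation_coverage(m)
  expect_equal(cov0$metabolites$fraction_annotated, 0)
  expect_equal(cov0$n_databases, 0)
  m$annotations$reactions[["R1"]] <- list(ec = "1.1.1.1")
  m$annotations$metabolites[["M1_c"]] <- list(bigg.metabolite = "glc__D",
                                              kegg.compound = "C00031")
  cov <- annotation_coverage(m)
  expect_equal(cov$reactions$fraction_annotated, 1 / nrow(m$reactions))
  expect_equal(cov$metabolites$fraction_annotated, 1 / nrow(m$metabolites))
  expect_setequal(cov$metabolites$databases, c("bigg.metabolite", "kegg.compound"))
  expect_equal(cov$n_databases, 3)
  # SBO histogram counts distinct accessions
  hist <- annotation_coverage(make_glutamate_core())$sbo_histogram
  expect_true(all(c("SBO:0000627", "SBO:0000629") %in% names(hist)))
  expect_equal(sum(hist), nrow(make_glutamate_core()$reactions))
})
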