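sorted_stoich <- function(m) {
  st <- m$stoichiometry[order(names(m$stoichiometry))]
  lapply(st, function(x) x[order(names(x))])
}

test_that("SBML write/read round-trips every model field", {
  core <- make_glutamate_core()
  core$groups <- list("TCA cycle" = c("CS", "ACONT", "ICDHyr"),
                      "Glycolysis" = c("GLCpts", "EMP", "PYK"))
  core$annotations$metabolites[["glu__L_c"]] <-
    list(bigg.metabolite = "glu__L", kegg.compound = "C00025")
  core$annotations$reactions[["CS"]] <- list(ec = "2.3.3.16")
  core$annotations$genes[["gltA"]] <- list(ncbigene = "1019324")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(core, path)
  back <- read_sbml(path)
  expect_equal(back$metabolites, core$metabolites)
  expect_equal(back$reactions, core$reactions)
  expect_equal(sorted_stoich(back), sorted_stoich(core))
  expect_equal(back$groups, core$groups)
  expect_identical(back$objective, core$objective)
  expect_equal(back$annotations, core$annotations)
  expect_setequal(back$genes$id, core$genes$id)
  # the model still computes identically
  expect_equal(fba(back)$objective, fba(core)$objective, tolerance = 1e-9)
})

test_that("models without genes and with empty groups serialize fine", {
  ch <- make_linear_chain(2)
  ch$reactions$gpr <- NA_character_
  ch$genes <- ch$genes[0, ]
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(ch, path)
  back <- read_sbml(path)
  expect_equal(nrow(back$genes), 0)
  expect_equal(fba(back)$objective, 10, tolerance = 1e-9)
})

test_that("reader raises integrity errors for broken files", {
  ch <- make_linear_chain(2)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(ch, path)
  txt <- readLines(path, warn = FALSE)
  # reaction citing a species missing from listOfSpecies
  bad1 <- gsub('species="M_M1_c"', 'species="M_X_c"', txt)
  p1 <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad1, p1)
  expect_error(read_sbml(p1), "not in listOfSpecies")
  # flux-bound attribute pointing at an undeclared parameter
  bad2 <- sub('fbc:upperFluxBound="default_ub"',
              'fbc:upperFluxBound="ghost_param"', txt)
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad2, p2)
  expect_error(read_sbml(p2), "flux-bound parameter")
  # malformed XML reports a parse error
  p3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(txt[1], "<sbml><unclosed"), p3)
  expect_error(read_sbml(p3), "parse error")
})

test_that("writer refuses models with unresolved references", {
  ch <- make_linear_chain(2)
  ch$stoichiometry[["R1"]] <- c(M1_c = -1, ghost_c = 1)
  expect_error(write_sbml(ch, withr::local_tempfile(fileext = ".xml")),
               "undefined species")
})

test_that("equation strings parse into signed stoichiometry with reversibility", {
  eq <- parse_equation("accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c")
  expect_false(eq$reversible)
  expect_equal(eq$stoich[c("accoa_c", "h2o_c", "oaa_c")],
               c(accoa_c = -1, h2o_c = -1, oaa_c = -1))
  expect_equal(eq$stoich[c("cit_c", "coa_c", "h_c")],
               c(cit_c = 1, coa_c = 1, h_c = 1))
  expect_true(parse_equation("a_c <=> b_c")$reversible)
  expect_true(parse_equation("a_c ⇌ b_c")$reversible)
  expect_equal(unname(parse_equation("2 a_c -> b_c")$stoich["a_c"]), -2)
  expect_equal(length(parse_equation("a_c ->")$stoich), 1)
  expect_error(parse_equation("a_c + -> b_c"), "empty term")
  expect_error(parse_equation("a_c = b_c"), "no reaction arrow")
})

write_table_fixture <- function(dir) {
  mets <- data.frame(
    id = c("accoa_c", "h2o_c", "oaa_c", "cit_c", "coa_c", "h_c", "glc__D_e"),
    name = c("acetyl-CoA", "water", "oxaloacetate", "citrate",
             "coenzyme A", "proton", "D-glucose"),
    formula = c("C23H34N7O17P3S", "H2O", "C4H2O5", "C6H5O7",
                "C21H32N7O16P3S", "H", "C6H12O6"),
    charge = c(-4L, 0L, -2L, -3L, -4L, 1L, 0L))
  rxns <- data.frame(
    id = c("CS", "REV", "EX_glc__D_e"),
    name = c("citrate synthase", "toy reversible", "D-glucose exchange"),
    equation = c("accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c",
                 "cit_c <=> oaa_c", "glc__D_e ->"),
    lower_bound = c(NA, NA, -10),
    upper_bound = c(NA, NA, NA),
    gpr = c("gltA", "", ""),
    subsystem = c("TCA cycle", "TCA cycle", ""))
  mp <- file.path(dir, "mets.csv"); rp <- file.path(dir, "rxns.csv")
  utils::write.csv(mets, mp, row.names = FALSE)
  utils::write.csv(rxns, rp, row.names = FALSE)
  list(mets = mp, rxns = rp)
}

test_that("from_tables applies default bounds and builds groups", {
  dir <- withr::local_tempdir()
  fx <- write_table_fixture(dir)
  m <- from_tables(fx$rxns, fx$mets, model_id = "tabletest")
  i <- match("CS", m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], 0)       # irreversible arrow
  expect_equal(m$reactions$upper_bound[i], 1000)
  j <- match("REV", m$reactions$id)
  expect_equal(m$reactions$lower_bound[j], -1000)   # reversible default
  k <- match("EX_glc__D_e", m$reactions$id)
  expect_equal(m$reactions$lower_bound[k], -10)     # explicit bound wins
  expect_identical(m$reactions$sbo[k], "SBO:0000627")
  expect_equal(m$groups, list(`TCA cycle` = c("CS", "REV")))
  expect_identical(m$reactions$gpr[i], "gltA")
  # the converted CS is elementally and charge balanced
  bal <- balance_audit(m)
  expect_identical(bal$verdict[bal$id == "CS"], "balanced")
})

test_that("from_tables raises row-level errors and rejects duplicates", {
  dir <- withr::local_tempdir()
  fx <- write_table_fixture(dir)
  rt <- utils::read.csv(fx$rxns)
  rt$equation[1] <- "accoa_c + -> cit_c"
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(rt, bad, row.names = FALSE)
  expect_error(from_tables(bad, fx$mets), "row 1.*CS")
  rt2 <- utils::read.csv(fx$rxns)
  rt2 <- rbind(rt2, rt2[1, ])
  dup <- file.path(dir, "dup.csv")
  utils::write.csv(rt2, dup, row.names = FALSE)
  expect_error(from_tables(dup, fx$mets), "duplicate reaction")
})

test_that("the converter is idempotent through SBML", {
  dir <- withr::local_tempdir()
  fx <- write_table_fixture(dir)
  m <- from_tables(fx$rxns, fx$mets, model_id = "tabletest")
  path <- file.path(dir, "out.xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  expect_equal(back$reactions, m$reactions)
  expect_equal(sorted_stoich(back), sorted_stoich(m))
  expect_equal(back$groups, m$groups)
})

test_that("model_summary counts by enumeration", {
  core <- make_glutamate_core()
  s <- model_summary(core)
  expect_equal(s$n_metabolites, 30)
  expect_equal(s$n_reactions, 28)
  expect_equal(s$n_genes, 14)
  expect_equal(sum(s$sbo_histogram), 28)
  expect_setequal(names(s$sbo_histogram),
                  c("SBO:0000627", "SBO:0000655", "SBO:0000176",
                    "SBO:0000630", "SBO:0000629"))
  empty <- model_summary(gem_model("empty"))
  expect_equal(unlist(empty[c("n_metabolites", "n_reactions", "n_genes",
                              "n_groups")]),
               c(n_metabolites = 0, n_reactions = 0, n_genes = 0, n_groups = 0))
})
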