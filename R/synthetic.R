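#' Synthetic test models
#'
#' Deterministic generators for small metabolic models whose optima are
#' known analytically. They stand in for deposited genome-scale models so
#' that every pipeline stage (I/O, FBA/FVA, auditing, production analysis)
#' can be exercised and verified offline. All formulas are real molecular
#' formulas and all internal reactions are elementally and charge balanced,
#' so the quality audit runs on these models unmodified.
#'
#' @name synthetic_models
NULL

#' Linear-chain model
#'
#' Uptake of a single nutrient, a transport step, a unit-stoichiometry
#' conversion chain `M1 -> M2 -> ... -> Mn`, and a biomass drain on the last
#' metabolite. Flow conservation makes the maximal growth rate equal the
#' uptake bound, which is the hand-computable FBA oracle used in the tests.
#'
#' @param n_chain number of chain metabolites (>= 1).
#' @param uptake uptake bound of the nutrient exchange (mmol/gDW/h).
#' @param require_o2 make biomass additionally consume oxygen, turning the
#'   chain into an obligate aerobe (growth collapses to zero when the
#'   oxygen exchange is closed).
#' @return a `gem_model`.
#' @export
make_linear_chain <- function(n_chain = 3, uptake = 10, require_o2 = FALSE) {
  stopifnot(n_chain >= 1)
  glc <- "C6H12O6"
  mets <- list(met_spec("M1_e", "nutrient (extracellular)", glc, 0L,
                        sbo = "SBO:0000247"))
  for (i in seq_len(n_chain)) {
    mets[[length(mets) + 1L]] <- met_spec(paste0("M", i, "_c"),
                                          paste("chain metabolite", i),
                                          glc, 0L, sbo = "SBO:0000247")
  }
  rxns <- list(
    rxn_spec("EX_M1_e", c(M1_e = -1), "nutrient exchange",
             lb = -uptake, ub = 1000, sbo = "SBO:0000627"),
    rxn_spec("M1t", c(M1_e = -1, M1_c = 1), "nutrient transport",
             lb = 0, ub = 1000, gpr = "gT", sbo = "SBO:0000655")
  )
  if (n_chain > 1) {
    for (i in seq_len(n_chain - 1L)) {
      st <- stats::setNames(c(-1, 1), paste0("M", c(i, i + 1L), "_c"))
      rxns[[length(rxns) + 1L]] <-
        rxn_spec(paste0("R", i), st, paste0("conversion ", i),
                 lb = 0, ub = 1000, gpr = paste0("g", i), sbo = "SBO:0000176")
    }
  }
  bm <- stats::setNames(-1, paste0("M", n_chain, "_c"))
  if (require_o2) {
    mets[[length(mets) + 1L]] <- met_spec("o2_e", "oxygen (extracellular)",
                                          "O2", 0L, sbo = "SBO:0000247")
    mets[[length(mets) + 1L]] <- met_spec("o2_c", "oxygen", "O2", 0L,
                                          sbo = "SBO:0000247")
    rxns[[length(rxns) + 1L]] <- rxn_spec("EX_o2_e", c(o2_e = -1),
                                          "oxygen exchange", lb = -1000,
                                          ub = 1000, sbo = "SBO:0000627")
    rxns[[length(rxns) + 1L]] <- rxn_spec("O2t", c(o2_e = -1, o2_c = 1),
                                          "oxygen transport", lb = -1000,
                                          ub = 1000, sbo = "SBO:0000655")
    bm <- c(bm, o2_c = -1)
  }
  rxns[[length(rxns) + 1L]] <- rxn_spec("BIOMASS", bm, "biomass drain",
                                        lb = 0, ub = 1000, sbo = "SBO:0000629")
  gem_model(paste0("chain", n_chain), mets, rxns, objective = "BIOMASS")
}

#' Glutamate-producing core model
#'
#' A fixed ~28-reaction carbon-core network emulating glutamate production
#' from glucose: PTS glucose uptake, a lumped Embden-Meyerhof glycolysis,
#' pyruvate kinase, pyruvate dehydrogenase, both anaplerotic routes (PEP
#' carboxylase, and pyruvate carboxylase which costs one ATP), citrate
#' synthase, aconitase, isocitrate dehydrogenase, glutamate dehydrogenase,
#' an oxidative-phosphorylation lump with P/O ratio 2.5, ATP maintenance,
#' glutamate export, and a biomass drain consuming L-glutamate with
#' stoichiometric coefficient 0.0149 plus 40 ATP per unit growth.
#'
#' Every internal reaction is elementally and charge balanced. The network
#' is kept fixed (never randomised) so its hand-derived LP solutions can
#' serve as frozen test constants: with the default glucose uptake of
#' 10 mmol/gDW/h the maximal glutamate production is 10, the trade-off with
#' growth is the exact line `p(mu) = 10 - 0.0149 mu`, the maximal growth
#' rate is 85/40 = 2.125, and knocking out pyruvate carboxylase leaves
#' glutamate production unchanged because PEP carboxylase reroutes the
#' anaplerotic flux.
#'
#' @return a `gem_model`.
#' @export
make_glutamate_core <- function() {
  m <- function(id, name, formula, charge)
    met_spec(id, name, formula, charge, sbo = "SBO:0000247")
  mets <- list(
    m("glc__D_e", "D-glucose", "C6H12O6", 0L),
    m("g6p_c", "D-glucose 6-phosphate", "C6H11O9P", -2L),
    m("pep_c", "phosphoenolpyruvate", "C3H2O6P", -3L),
    m("pyr_c", "pyruvate", "C3H3O3", -1L),
    m("oaa_c", "oxaloacetate", "C4H2O5", -2L),
    m("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", -4L),
    m("coa_c", "coenzyme A", "C21H32N7O16P3S", -4L),
    m("cit_c", "citrate", "C6H5O7", -3L),
    m("icit_c", "isocitrate", "C6H5O7", -3L),
    m("akg_c", "2-oxoglutarate", "C5H4O5", -2L),
    m("glu__L_c", "L-glutamate", "C5H8NO4", -1L),
    m("glu__L_e", "L-glutamate (extracellular)", "C5H8NO4", -1L),
    m("nh4_c", "ammonium", "H4N", 1L),
    m("nh4_e", "ammonium (extracellular)", "H4N", 1L),
    m("atp_c", "ATP", "C10H12N5O13P3", -4L),
    m("adp_c", "ADP", "C10H12N5O10P2", -3L),
    m("pi_c", "phosphate", "HO4P", -2L),
    m("pi_e", "phosphate (extracellular)", "HO4P", -2L),
    m("nad_c", "NAD+", "C21H26N7O14P2", -1L),
    m("nadh_c", "NADH", "C21H27N7O14P2", -2L),
    m("nadp_c", "NADP+", "C21H25N7O17P3", -3L),
    m("nadph_c", "NADPH", "C21H26N7O17P3", -4L),
    m("h_c", "proton", "H", 1L),
    m("h_e", "proton (extracellular)", "H", 1L),
    m("h2o_c", "water", "H2O", 0L),
    m("h2o_e", "water (extracellular)", "H2O", 0L),
    m("o2_c", "oxygen", "O2", 0L),
    m("o2_e", "oxygen (extracellular)", "O2", 0L),
    m("co2_c", "carbon dioxide", "CO2", 0L),
    m("co2_e", "carbon dioxide (extracellular)", "CO2", 0L)
  )
  ex <- function(id, met, lb) rxn_spec(id, stats::setNames(-1, met),
                                       paste(met, "exchange"),
                                       lb = lb, ub = 1000, sbo = "SBO:0000627")
  rxns <- list(
    ex("EX_glc__D_e", "glc__D_e", -10),
    ex("EX_o2_e", "o2_e", -1000),
    ex("EX_co2_e", "co2_e", 0),
    ex("EX_nh4_e", "nh4_e", -10),
    ex("EX_pi_e", "pi_e", -10),
    ex("EX_h_e", "h_e", -1000),
    ex("EX_h2o_e", "h2o_e", -1000),
    ex("EX_glu__L_e", "glu__L_e", 0),
    rxn_spec("GLCpts", c(glc__D_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
             "D-glucose transport via PEP:Pyr PTS", lb = 0, ub = 1000,
             gpr = "ptsG", sbo = "SBO:0000655"),
    rxn_spec("EMP",
             c(g6p_c = -1, adp_c = -1, pi_c = -2, nad_c = -2,
               pep_c = 2, atp_c = 1, nadh_c = 2, h2o_c = 2, h_c = 3),
             "glycolysis lump (G6P to 2 PEP)", lb = 0, ub = 1000,
             gpr = "pfkA", sbo = "SBO:0000176"),
    rxn_spec("PYK", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
             "pyruvate kinase", lb = 0, ub = 1000, gpr = "pyk",
             sbo = "SBO:0000176"),
    rxn_spec("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1,
                      accoa_c = 1, co2_c = 1, nadh_c = 1),
             "pyruvate dehydrogenase", lb = 0, ub = 1000,
             gpr = "aceE and aceF and lpd", sbo = "SBO:0000176"),
    rxn_spec("PPC", c(pep_c = -1, co2_c = -1, h2o_c = -1,
                      oaa_c = 1, pi_c = 1, h_c = 1),
             "phosphoenolpyruvate carboxylase", lb = 0, ub = 1000,
             gpr = "ppc", sbo = "SBO:0000176"),
    rxn_spec("PC", c(pyr_c = -1, atp_c = -1, co2_c = -1, h2o_c = -1,
                     oaa_c = 1, adp_c = 1, pi_c = 1, h_c = 2),
             "pyruvate carboxylase", lb = 0, ub = 1000,
             gpr = "pyc", sbo = "SBO:0000176"),
    rxn_spec("CS", c(accoa_c = -1, h2o_c = -1, oaa_c = -1,
                     cit_c = 1, coa_c = 1, h_c = 1),
             "citrate synthase", lb = 0, ub = 1000, gpr = "gltA",
             sbo = "SBO:0000176"),
    rxn_spec("ACONT", c(cit_c = -1, icit_c = 1), "aconitate hydratase",
             lb = -1000, ub = 1000, gpr = "acn", sbo = "SBO:0000176"),
    rxn_spec("ICDHyr", c(icit_c = -1, nadp_c = -1,
                         akg_c = 1, co2_c = 1, nadph_c = 1),
             "isocitrate dehydrogenase (NADP)", lb = -1000, ub = 1000,
             gpr = "icd", sbo = "SBO:0000176"),
    rxn_spec("GDH", c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1,
                      glu__L_c = 1, h2o_c = 1, nadp_c = 1),
             "glutamate dehydrogenase (NADPH)", lb = 0, ub = 1000,
             gpr = "gdh", sbo = "SBO:0000176"),
    rxn_spec("NADHOX",
             c(nadh_c = -1, o2_c = -0.5, adp_c = -2.5, pi_c = -2.5,
               h_c = -3.5, nad_c = 1, atp_c = 2.5, h2o_c = 3.5),
             "respiratory chain lump (P/O 2.5)", lb = 0, ub = 1000,
             gpr = "ndh and atpA", sbo = "SBO:0000176"),
    rxn_spec("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
             "ATP maintenance", lb = 0, ub = 1000, sbo = "SBO:0000630"),
    rxn_spec("O2t", c(o2_e = -1, o2_c = 1), "oxygen diffusion",
             lb = -1000, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("CO2t", c(co2_c = -1, co2_e = 1), "carbon dioxide diffusion",
             lb = -1000, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("NH4t", c(nh4_e = -1, nh4_c = 1), "ammonium transport",
             lb = 0, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("PIt", c(pi_e = -1, pi_c = 1), "phosphate transport",
             lb = -1000, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("Ht", c(h_c = -1, h_e = 1), "proton diffusion",
             lb = -1000, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("H2Ot", c(h2o_c = -1, h2o_e = 1), "water diffusion",
             lb = -1000, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("GLUt", c(glu__L_c = -1, glu__L_e = 1), "L-glutamate export",
             lb = 0, ub = 1000, sbo = "SBO:0000655"),
    rxn_spec("BIOMASS_core",
             c(glu__L_c = -0.0149, atp_c = -40, h2o_c = -40,
               adp_c = 40, pi_c = 40, h_c = 40),
             "biomass objective function", lb = 0, ub = 1000,
             sbo = "SBO:0000629")
  )
  gem_model("glutamate_core", mets, rxns, objective = "BIOMASS_core")
}

#' Plant a verifiable defect into a model
#'
#' Introduces exactly one class of model defect so the corresponding
#' quality-audit detector can be validated. Each kind is designed not to
#' trip any *other* detector. The reaction/metabolite ids affected are
#' recorded in the `"planted"` attribute of the returned model, because a
#' formula perturbation imbalances every audited reaction the metabolite
#' participates in.
#'
#' * `imbalance`: adds one hydrogen to the formula of `target` (default: a
#'   metabolite consumed only by pseudo-reactions, if any, else the last
#'   metabolite); `planted` lists the audited reactions now imbalanced.
#' * `dead_end`: adds a produced-but-never-consumed metabolite.
#' * `orphan`: adds a consumed-but-never-produced metabolite.
#' * `egc`: adds a cost-free charging reaction for an energy carrier
#'   (e.g. `adp + pi + h -> atp + h2o`) and, if the model lacks a
#'   hydrolysis counterpart, the reverse route -- together an
#'   energy-generating cycle among internal reactions.
#' * `loop`: duplicates an internal reaction in reversed, reversible form,
#'   creating a thermodynamically infeasible two-reaction flux cycle (the
#'   loopless-FVA test case).
#'
#' @param model a `gem_model`.
#' @param kind one of `"imbalance"`, `"dead_end"`, `"orphan"`, `"egc"`,
#'   `"loop"`.
#' @param target metabolite id (`imbalance`, `dead_end`, `orphan` anchor,
#'   `egc` carrier) or reaction id (`loop`); sensible defaults per kind.
#' @param tag suffix making planted ids unique when planting repeatedly.
#' @return the defective model, with attribute `"planted"` naming the ids a
#'   detector must flag.
#' @export
plant_defect <- function(model, kind = c("imbalance", "dead_end", "orphan",
                                         "egc", "loop"),
                         target = NULL, tag = "1") {
  kind <- match.arg(kind)
  pseudo <- is_pseudo_reaction(model)
  switch(kind,
    imbalance = {
      if (is.null(target)) {
        # prefer a metabolite whose only consumers are pseudo-reactions so a
        # single audited reaction is hit
        cand <- model$metabolites$id
        naudit <- vapply(cand, function(mid) {
          sum(vapply(seq_along(model$stoichiometry), function(j) {
            !pseudo[j] && mid %in% names(model$stoichiometry[[j]])
          }, logical(1)))
        }, integer(1))
        target <- cand[naudit > 0][which.min(naudit[naudit > 0])]
      }
      i <- match(target, model$metabolites$id)
      if (is.na(i)) stop("unknown metabolite '", target, "'")
      tl <- parse_formula(model$metabolites$formula[i])
      h <- if ("H" %in% names(tl)) unclass(tl)[["H"]] else 0
      tl2 <- unclass(tl); tl2["H"] <- h + 1
      model$metabolites$formula[i] <- format_formula(tl2)
      affected <- model$reactions$id[vapply(seq_along(model$stoichiometry),
        function(j) !pseudo[j] && target %in% names(model$stoichiometry[[j]]),
        logical(1))]
      attr(model, "planted") <- list(kind = kind, reactions = affected,
                                     metabolite = target)
      model
    },
    dead_end = {
      if (is.null(target)) target <- model$metabolites$id[1]
      i <- match(target, model$metabolites$id)
      if (is.na(i)) stop("unknown metabolite '", target, "'")
      newid <- paste0("deadend", tag, "_c")
      model$metabolites <- rbind(model$metabolites, data.frame(
        id = newid, name = "planted dead end", compartment = "c",
        formula = model$metabolites$formula[i],
        charge = model$metabolites$charge[i], sbo = "SBO:0000247"))
      rid <- paste0("DE", tag)
      model$reactions <- rbind(model$reactions, data.frame(
        id = rid, name = "dead-end producer", lower_bound = 0,
        upper_bound = 1000, gpr = NA_character_, sbo = "SBO:0000176"))
      model$stoichiometry[[rid]] <- stats::setNames(c(-1, 1), c(target, newid))
      attr(model, "planted") <- list(kind = kind, metabolite = newid,
                                     reactions = rid)
      model
    },
    orphan = {
      if (is.null(target)) target <- model$metabolites$id[1]
      i <- match(target, model$metabolites$id)
      if (is.na(i)) stop("unknown metabolite '", target, "'")
      newid <- paste0("orphan", tag, "_c")
      model$metabolites <- rbind(model$metabolites, data.frame(
        id = newid, name = "planted orphan", compartment = "c",
        formula = model$metabolites$formula[i],
        charge = model$metabolites$charge[i], sbo = "SBO:0000247"))
      rid <- paste0("OR", tag)
      model$reactions <- rbind(model$reactions, data.frame(
        id = rid, name = "orphan consumer", lower_bound = 0,
        upper_bound = 1000, gpr = NA_character_, sbo = "SBO:0000176"))
      model$stoichiometry[[rid]] <- stats::setNames(c(-1, 1), c(newid, target))
      attr(model, "planted") <- list(kind = kind, metabolite = newid,
                                     reactions = rid)
      model
    },
    egc = {
      carrier <- target %||% "atp"
      needed <- c("atp_c", "adp_c", "pi_c", "h_c", "h2o_c")
      if (!identical(carrier, "atp") || !all(needed %in% model$metabolites$id)) {
        stop("energy-generating-cycle planting requires the ATP/ADP couple ",
             "in the model", call. = FALSE)
      }
      charge_id <- paste0("EGC_CHARGE", tag)
      model$reactions <- rbind(model$reactions, data.frame(
        id = charge_id, name = "cost-free ATP charging",
        lower_bound = 0, upper_bound = 1000, gpr = NA_character_,
        sbo = "SBO:0000176"))
      model$stoichiometry[[charge_id]] <- c(adp_c = -1, pi_c = -1, h_c = -1,
                                            atp_c = 1, h2o_c = 1)
      planted <- charge_id
      has_hydrolysis <- any(vapply(seq_along(model$stoichiometry), function(j) {
        st <- model$stoichiometry[[j]]
        !pseudo[j] && isTRUE(st["atp_c"] < 0) && isTRUE(st["adp_c"] > 0)
      }, logical(1)))
      if (!has_hydrolysis) {
        dis_id <- paste0("EGC_DISCHARGE", tag)
        model$reactions <- rbind(model$reactions, data.frame(
          id = dis_id, name = "ATP hydrolysis route",
          lower_bound = 0, upper_bound = 1000, gpr = NA_character_,
          sbo = "SBO:0000176"))
        model$stoichiometry[[dis_id]] <- c(atp_c = -1, h2o_c = -1,
                                           adp_c = 1, pi_c = 1, h_c = 1)
        planted <- c(planted, dis_id)
      }
      attr(model, "planted") <- list(kind = kind, carrier = "atp",
                                     reactions = planted)
      model
    },
    loop = {
      if (is.null(target)) {
        internal <- which(is_internal_reaction(model))
        if (length(internal) == 0L) stop("no internal reaction to loop")
        target <- model$reactions$id[internal[1]]
      }
      j <- rxn_index(model, target)
      rid <- paste0("LOOP", tag)
      model$reactions <- rbind(model$reactions, data.frame(
        id = rid, name = paste("reversed duplicate of", target),
        lower_bound = -1000, upper_bound = 1000, gpr = NA_character_,
        sbo = "SBO:0000176"))
      model$stoichiometry[[rid]] <- -model$stoichiometry[[target]]
      attr(model, "planted") <- list(kind = kind, reactions = c(target, rid))
      model
    }
  )
}

#' Build a synthetic model from a generator specification
#'
#' The structured-config entry point for the generators: a list (e.g. read
#' from YAML) with `kind` ("chain" or "glutamate_core"), optional `n_chain`,
#' `uptake`, `require_o2`, and a `defects` list of
#' `{kind, target?, count?}` entries. Generation is fully deterministic:
#' identical specs yield identical models (and hence byte-identical SBML).
#'
#' @param spec list or path to a YAML file.
#' @return a `gem_model` (with `"planted"` attributes merged into one list).
#' @export
generate_model <- function(spec) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  kind <- spec$kind %||% "chain"
  model <- switch(kind,
    chain = make_linear_chain(n_chain = spec$n_chain %||% 3,
                              uptake = spec$uptake %||% 10,
                              require_o2 = isTRUE(spec$require_o2)),
    glutamate_core = make_glutamate_core(),
    stop("unknown generator kind '", kind, "'")
  )
  planted <- list()
  for (d in spec$defects %||% list()) {
    count <- d$count %||% 1L
    for (k in seq_len(count)) {
      model <- plant_defect(model, kind = d$kind, target = d$target,
                            tag = paste0(length(planted) + 1L))
      planted[[length(planted) + 1L]] <- attr(model, "planted")
    }
  }
  attr(model, "planted") <- planted
  validate_model(model)
  model
}
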