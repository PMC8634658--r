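#' BiGG identifiers of the 20 canonical amino acids
#'
#' Cytosolic BiGG ids used by [amino_acid_profile()]; shipped as data in
#' `extdata/amino_acids.csv` (three-letter code, name, metabolite id).
#'
#' @return data.frame with columns `code`, `name`, `metabolite_id`.
#' @export
amino_acid_ids <- function() {
  path <- system.file("extdata", "amino_acids.csv", package = "gemfba")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Deterministic sink-reaction id for a metabolite
#' @param metabolite_id metabolite id with compartment suffix.
#' @return the sink id, e.g. `"sink_glu__L"` for `"glu__L_c"`.
#' @export
sink_id <- function(metabolite_id) {
  paste0("sink_", sub("_[cpe]$", "", metabolite_id))
}

#' Add an irreversible sink (drain) reaction for a metabolite
#'
#' Adds `met -> nothing` with bounds 0/1000 and sink SBO term, named by
#' [sink_id()]. Adding a sink that already exists is a no-op (idempotent).
#' A bare metabolite id without compartment suffix resolves to the
#' cytosolic form.
#'
#' @param model a `gem_model`.
#' @param metabolite_id metabolite to drain.
#' @return the model containing the sink.
#' @export
add_sink <- function(model, metabolite_id) {
  if (!(metabolite_id %in% model$metabolites$id)) {
    alt <- paste0(metabolite_id, "_c")
    if (alt %in% model$metabolites$id) {
      metabolite_id <- alt
    } else {
      stop("unknown metabolite '", metabolite_id, "'", call. = FALSE)
    }
  }
  rid <- sink_id(metabolite_id)
  if (rid %in% model$reactions$id) return(model)
  model$reactions <- rbind(model$reactions, data.frame(
    id = rid, name = paste("sink reaction for", metabolite_id),
    lower_bound = 0, upper_bound = 1000, gpr = NA_character_,
    sbo = "SBO:0000632", stringsAsFactors = FALSE))
  model$stoichiometry[[rid]] <- stats::setNames(-1, metabolite_id)
  model
}

# Net ATP production rate: per reaction, only positive (coefficient of
# cytosolic ATP x flux) contributions are summed, so transport
# phosphorylation counts where it nets ATP in the cytosol.
atp_production_rate <- function(model, fluxes, atp_id = "atp_c") {
  tot <- 0
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    if (!(atp_id %in% names(st))) next
    contrib <- st[[atp_id]] * fluxes[[model$reactions$id[j]]]
    if (isTRUE(contrib > 0)) tot <- tot + contrib
  }
  tot
}

production_record <- function(metabolite, sol, model, glucose_uptake,
                              co2_id = "EX_co2_e") {
  if (sol$status != "optimal") {
    return(data.frame(metabolite = metabolite, status = sol$status,
                      production_rate = NA_real_, yield_on_glucose = NA_real_,
                      co2_rate = NA_real_, atp_rate = NA_real_,
                      stringsAsFactors = FALSE))
  }
  co2 <- if (co2_id %in% names(sol$fluxes)) max(sol$fluxes[[co2_id]], 0) else NA_real_
  data.frame(metabolite = metabolite, status = "optimal",
             production_rate = sol$objective,
             yield_on_glucose = sol$objective / glucose_uptake,
             co2_rate = co2,
             atp_rate = atp_production_rate(model, sol$fluxes),
             stringsAsFactors = FALSE)
}

prepare_production_model <- function(model, medium = NULL, aerobic = TRUE,
                                     glucose_uptake = 10,
                                     glucose_id = "EX_glc__D_e",
                                     growth_fix = 0.4) {
  if (!is.null(medium)) model <- apply_medium(model, medium, aerobic = aerobic)
  if (glucose_id %in% model$reactions$id) {
    model <- set_bounds(model, glucose_id, lb = -glucose_uptake)
  }
  if (!is.null(growth_fix)) {
    model <- fix_flux(model, model$objective, growth_fix)
    probe <- fba(model, model$objective)
    if (probe$status != "optimal") {
      stop("model infeasible with growth fixed to ", growth_fix,
           " on the given medium", call. = FALSE)
    }
  }
  model
}

#' Amino-acid production profile
#'
#' For each amino acid: restrict glucose uptake, fix the growth rate (to
#' keep the cell viable while producing), add a sink for the amino acid,
#' maximise the sink, and record the production economics at that optimum:
#' the production rate, the molar yield on glucose (production rate divided
#' by glucose uptake), the CO2 production rate (efflux of the CO2
#' exchange), and the ATP production rate (summed positive cytosolic-ATP
#' contributions over all reactions). CO2 and ATP rates are read off one
#' optimal vertex; alternative optima may shift them (never the production
#' rate itself).
#'
#' @param model a `gem_model` able to grow at `growth_fix`.
#' @param medium optional [medium()] applied first (e.g. CGXII); `NULL`
#'   uses the model's current bounds.
#' @param aerobic passed to [apply_medium()].
#' @param glucose_uptake glucose availability, default 10 mmol/gDW/h.
#' @param growth_fix fixed growth rate, default 0.4 mmol/gDW/h.
#' @param amino_acids metabolite ids to profile; defaults to the canonical
#'   20 (intersected with the model's metabolites).
#' @param glucose_id id of the glucose exchange.
#' @return data.frame of production records, one row per amino acid.
#' @export
amino_acid_profile <- function(model, medium = NULL, aerobic = TRUE,
                               glucose_uptake = 10, growth_fix = 0.4,
                               amino_acids = NULL,
                               glucose_id = "EX_glc__D_e") {
  if (is.null(amino_acids)) {
    amino_acids <- intersect(amino_acid_ids()$metabolite_id,
                             model$metabolites$id)
  }
  if (length(amino_acids) == 0L) stop("no amino-acid metabolites in model")
  base <- prepare_production_model(model, medium, aerobic, glucose_uptake,
                                   glucose_id, growth_fix)
  rows <- lapply(amino_acids, function(aa) {
    m <- add_sink(base, aa)
    sol <- fba(m, sink_id(aa), "max")
    production_record(aa, sol, m, glucose_uptake)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth-production trade-off curve
#'
#' Fixes the biomass flux to each value of a growth-rate grid and maximises
#' the product sink, tracing the trade-off between growing and producing.
#' By LP parametric theory the curve is non-increasing and concave in the
#' fixed growth rate; grid points beyond feasibility are recorded as
#' infeasible rather than dropped.
#'
#' @param model a `gem_model`.
#' @param product metabolite id to produce (sink added automatically).
#' @param mu_grid growth-rate grid; default 30 evenly spaced values from 0
#'   to the model's maximal growth rate.
#' @param medium,aerobic,glucose_uptake,glucose_id as in
#'   [amino_acid_profile()].
#' @return data.frame with `mu`, `production`, `status`.
#' @export
tradeoff_curve <- function(model, product = "glu__L_c", mu_grid = NULL,
                           medium = NULL, aerobic = TRUE, glucose_uptake = 10,
                           glucose_id = "EX_glc__D_e") {
  base <- prepare_production_model(model, medium, aerobic, glucose_uptake,
                                   glucose_id, growth_fix = NULL)
  if (is.null(mu_grid)) {
    mumax <- fba(base, base$objective)
    if (mumax$status != "optimal") stop("cannot determine maximal growth rate")
    mu_grid <- seq(0, mumax$objective, length.out = 30)
  }
  base <- add_sink(base, product)
  sid <- sink_id(if (product %in% base$metabolites$id) product
                 else paste0(product, "_c"))
  rows <- lapply(mu_grid, function(mu) {
    res <- tryCatch({
      m <- fix_flux(base, base$objective, mu)
      sol <- fba(m, sid, "max")
      list(p = if (sol$status == "optimal") sol$objective else NA_real_,
           status = sol$status)
    }, error = function(e) list(p = NA_real_, status = "infeasible"))
    data.frame(mu = mu, production = res$p, status = res$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Knock-out experiment under fixed growth
#'
#' Runs the production pipeline twice under identical constraints -- wild
#' type and with `reaction_id` knocked out -- maximising the product sink
#' with growth fixed, and returns both production records plus the paired
#' flux distributions for pathway-map comparison. A knock-out that makes
#' the fixed growth rate infeasible is reported in the record's status, not
#' raised.
#'
#' @param model a `gem_model`.
#' @param reaction_id reaction (or gene) to knock out, e.g. the pyruvate
#'   carboxylase.
#' @param product metabolite whose sink is maximised.
#' @param growth_fix fixed growth rate.
#' @param medium,aerobic,glucose_uptake,glucose_id as in
#'   [amino_acid_profile()].
#' @return list with `before`, `after` (production records) and `fluxes`
#'   (data.frame `id`, `flux_wt`, `flux_ko`).
#' @export
knockout_experiment <- function(model, reaction_id = "PC",
                                product = "glu__L_c", growth_fix = 0.4,
                                medium = NULL, aerobic = TRUE,
                                glucose_uptake = 10,
                                glucose_id = "EX_glc__D_e") {
  base <- prepare_production_model(model, medium, aerobic, glucose_uptake,
                                   glucose_id, growth_fix)
  base <- add_sink(base, product)
  sid <- sink_id(if (product %in% base$metabolites$id) product
                 else paste0(product, "_c"))
  run1 <- fba(base, sid, "max")
  ko <- knockout(base, reaction_id)
  run2 <- fba(ko, sid, "max")
  fluxes <- data.frame(id = base$reactions$id,
                       flux_wt = unname(run1$fluxes),
                       flux_ko = unname(run2$fluxes),
                       stringsAsFactors = FALSE)
  list(before = production_record(product, run1, base, glucose_uptake),
       after = production_record(product, run2, ko, glucose_uptake),
       fluxes = fluxes)
}

#' Pinned reactions for a production objective
#'
#' Reactions whose flux is fully determined at the production optimum:
#' growth is fixed, the product sink is maximised and then fixed at its
#' optimum, a (by default loopless) FVA is run over *all* reactions
#' including pseudo-reactions, and a reaction is *pinned* iff
#' `|max - min| <= abs_tol + rel_tol * max(|max|, |min|)`. Pinned reactions
#' mark the rigid backbone of the production route.
#'
#' @param model a `gem_model`.
#' @param product metabolite whose sink is the objective.
#' @param growth_fix fixed growth rate.
#' @param rel_tol,abs_tol closeness tolerances (defaults 1e-5 and 1e-8).
#' @param loopless use loopless FVA (plain FVA is exposed for speed
#'   comparisons).
#' @param medium,aerobic,glucose_uptake,glucose_id as in
#'   [amino_acid_profile()].
#' @return list with `pinned` (reaction ids) and `ranges` (the full FVA
#'   table with a logical `pinned` column).
#' @export
pinned_reactions <- function(model, product = "glu__L_c", growth_fix = 0.4,
                             rel_tol = 1e-5, abs_tol = 1e-8, loopless = TRUE,
                             medium = NULL, aerobic = TRUE,
                             glucose_uptake = 10,
                             glucose_id = "EX_glc__D_e") {
  base <- prepare_production_model(model, medium, aerobic, glucose_uptake,
                                   glucose_id, growth_fix)
  base <- add_sink(base, product)
  sid <- sink_id(if (product %in% base$metabolites$id) product
                 else paste0(product, "_c"))
  opt <- fba(base, sid, "max")
  if (opt$status != "optimal") {
    stop("production optimum not attainable: ", opt$status, call. = FALSE)
  }
  fixed <- fix_flux(base, sid, opt$objective)
  rng <- fva(fixed, loopless = loopless)
  rng$pinned <- abs(rng$max - rng$min) <=
    abs_tol + rel_tol * pmax(abs(rng$max), abs(rng$min))
  list(pinned = rng$id[rng$pinned], ranges = rng)
}
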