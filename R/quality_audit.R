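#' Elemental and charge balance audit
#'
#' For every non-pseudo reaction, sums element tallies and charges over the
#' stoichiometry (products minus reactants). Pseudo-reactions (exchange,
#' demand, sink, biomass) are excluded: they move matter across the system
#' boundary by design. A reaction is *unverifiable* on the mass side when
#' any participant lacks a formula or carries pseudo-elements (R/X), and on
#' the charge side when any participant lacks a charge; missing data is
#' never imputed as zero, so "imbalanced" and "unverifiable" stay distinct.
#'
#' Element residuals are compared at 1e-6 (coefficients may be fractional);
#' charge residuals at zero (charges are integers).
#'
#' @param model a `gem_model`.
#' @return data.frame with one row per audited reaction: `id`,
#'   `charge_residual`, `verdict` (one of `balanced`, `mass_imbalanced`,
#'   `charge_imbalanced`, `both`, `unverifiable`), and a list column
#'   `element_residuals` (named numeric per reaction).
#' @export
balance_audit <- function(model) {
  pseudo <- is_pseudo_reaction(model)
  idx <- which(!pseudo)
  mids <- model$metabolites$id
  tallies <- lapply(model$metabolites$formula, function(f) {
    if (is.na(f)) NULL else parse_formula(f)
  })
  names(tallies) <- mids
  rows <- lapply(idx, function(j) {
    st <- model$stoichiometry[[j]]
    part <- names(st)
    tl <- tallies[part]
    mass_unver <- any(vapply(tl, is.null, logical(1))) ||
      any(vapply(tl, function(t) !isTRUE(attr(t, "balanceable")), logical(1)))
    elem <- NULL
    mass_state <- "unverifiable"
    if (!mass_unver) {
      allsym <- unique(unlist(lapply(tl, names)))
      resid <- stats::setNames(numeric(length(allsym)), allsym)
      for (k in seq_along(part)) {
        t <- unclass(tl[[k]])
        resid[names(t)] <- resid[names(t)] + st[k] * t
      }
      elem <- resid
      mass_state <- if (any(abs(resid) > 1e-6)) "imbalanced" else "ok"
    }
    ch <- model$metabolites$charge[match(part, mids)]
    if (any(is.na(ch))) {
      charge_state <- "unverifiable"; charge_resid <- NA_real_
    } else {
      charge_resid <- sum(st * ch)
      charge_state <- if (abs(charge_resid) > 1e-9) "imbalanced" else "ok"
    }
    verdict <- if (mass_state == "imbalanced" && charge_state == "imbalanced") {
      "both"
    } else if (mass_state == "imbalanced") {
      "mass_imbalanced"
    } else if (charge_state == "imbalanced") {
      "charge_imbalanced"
    } else if (mass_state == "unverifiable" || charge_state == "unverifiable") {
      "unverifiable"
    } else {
      "balanced"
    }
    list(id = model$reactions$id[j], charge_residual = charge_resid,
         verdict = verdict, element_residuals = elem)
  })
  out <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    charge_residual = vapply(rows, `[[`, 0, "charge_residual"),
    verdict = vapply(rows, `[[`, "", "verdict"),
    stringsAsFactors = FALSE
  )
  out$element_residuals <- lapply(rows, `[[`, "element_residuals")
  out
}

#' Dead-end and orphan metabolites
#'
#' An *orphan* metabolite is never produced by any reaction; a *dead-end*
#' metabolite is never consumed. Reversibility is respected: a reactant of
#' a reaction with a negative lower bound counts as producible, and vice
#' versa. Exchange and sink reactions count as producers/consumers, so a
#' freely exchanged species is neither orphan nor dead end.
#'
#' @param model a `gem_model`.
#' @return list with character vectors `dead_end` and `orphan`.
#' @export
find_dead_ends <- function(model) {
  mids <- model$metabolites$id
  produced <- stats::setNames(logical(length(mids)), mids)
  consumed <- produced
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    fw <- ub[j] > 0; bw <- lb[j] < 0
    prod <- names(st)[(st > 0 & fw) | (st < 0 & bw)]
    cons <- names(st)[(st < 0 & fw) | (st > 0 & bw)]
    produced[prod] <- TRUE
    consumed[cons] <- TRUE
  }
  list(dead_end = mids[!consumed], orphan = mids[!produced])
}

#' Stoichiometric consistency
#'
#' A model is stoichiometrically consistent when every metabolite can be
#' assigned a strictly positive conserved mass `m` with `S_int' m = 0` over
#' the internal (non-pseudo) reactions. Because the feasible set is a
#' convex cone, the set of metabolites that can carry positive mass
#' *simultaneously* equals the union of those that can individually, so a
#' single LP suffices (no integer program): maximise the sum of auxiliary
#' variables `z_i <= min(m_i, eps)`; a metabolite is consistent iff its
#' `z` reaches `eps` (= 1e-4).
#'
#' @param model a `gem_model`.
#' @return list with `consistent_fraction` (share of metabolites in [0,1])
#'   and `inconsistent_metabolites` (ids).
#' @export
stoichiometric_consistency <- function(model) {
  eps <- 1e-4
  S <- build_matrix(model)
  keep <- !is_pseudo_reaction(model)
  Si <- S[, keep, drop = FALSE]
  nm <- nrow(Si)
  if (nm == 0L) {
    return(list(consistent_fraction = 1, inconsistent_metabolites = character(0)))
  }
  # variables: m (nm), z (nm)
  Aeq <- cbind(t(as.matrix(Si)), matrix(0, ncol(Si), nm))
  Aub <- cbind(-diag(1, nm), diag(1, nm))         # z - m <= 0
  obj <- c(rep(0, nm), rep(1, nm))
  res <- lp_solve(obj, Aeq = Aeq, beq = rep(0, nrow(Aeq)),
                  Aub = Aub, bub = rep(0, nm),
                  lb = c(rep(0, nm), rep(0, nm)),
                  ub = c(rep(1e6, nm), rep(eps, nm)), maximize = TRUE)
  if (res$status != "optimal") stop("consistency LP did not solve")
  z <- res$x[nm + seq_len(nm)]
  ok <- z >= eps * (1 - 1e-6)
  list(consistent_fraction = mean(ok),
       inconsistent_metabolites = model$metabolites$id[!ok])
}

#' Molecular weight of the biomass reaction
#'
#' The net mass drained by the biomass pseudo-reaction per unit flux,
#' `(sum of reactant coeff x MW - sum of product coeff x MW) / 1000` in
#' g/mmol. When this is close to 1 g/mmol the growth rate in mmol/gDW/h is
#' numerically comparable to an experimental rate in 1/h (the model's
#' biomass is then "standardized").
#'
#' @param model a `gem_model`.
#' @param biomass_id biomass reaction id; defaults to the model objective.
#' @return weight in g/mmol.
#' @export
biomass_weight <- function(model, biomass_id = model$objective) {
  j <- rxn_index(model, biomass_id)
  st <- model$stoichiometry[[j]]
  part <- names(st)
  i <- match(part, model$metabolites$id)
  formulas <- model$metabolites$formula[i]
  bad <- part[is.na(formulas)]
  tl <- lapply(formulas[!is.na(formulas)], parse_formula)
  bad <- c(bad, part[!is.na(formulas)][!vapply(tl, function(t)
    isTRUE(attr(t, "balanceable")), logical(1))])
  if (length(bad)) {
    stop("biomass weight unverifiable; participants lack usable formulas: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  mw <- vapply(formulas, molecular_weight, 0)
  -sum(st * mw) / 1000
}

# Canonical energy-dissipation reactions for the 13 carrier metabolites.
# The model gives the carriers; the hydrolysis/reoxidation stoichiometries
# are the canonical ones, with protons balanced in the carrier's own
# compartment (cytosol). Each entry: required species -> coefficient.
egc_carrier_table <- function() {
  ntp <- function(tri, di) stats::setNames(
    c(-1, -1, 1, 1, 1), paste0(c(tri, "h2o", di, "pi", "h"), "_c"))
  redox <- function(red, ox) stats::setNames(
    c(-1, 1, 1), paste0(c(red, ox, "h"), "_c"))
  quinol <- function(red, ox) stats::setNames(
    c(-1, 1, 2), paste0(c(red, ox, "h"), "_c"))
  list(
    atp = ntp("atp", "adp"),
    ctp = ntp("ctp", "cdp"),
    gtp = ntp("gtp", "gdp"),
    utp = ntp("utp", "udp"),
    itp = ntp("itp", "idp"),
    nadh = redox("nadh", "nad"),
    nadph = redox("nadph", "nadp"),
    fmnh2 = quinol("fmnh2", "fmn"),
    fadh2 = quinol("fadh2", "fad"),
    mql8 = quinol("mql8", "mqn8"),
    `2dmmql8` = quinol("2dmmql8", "2dmmq8"),
    accoa = stats::setNames(c(-1, -1, 1, 1, 1),
                            paste0(c("accoa", "h2o", "ac", "coa", "h"), "_c")),
    glu__L = stats::setNames(c(-1, -1, 1, 1, 2),
                             paste0(c("glu__L", "h2o", "akg", "nh4", "h"), "_c"))
  )
}

#' Energy-generating-cycle scan
#'
#' Detects thermodynamically infeasible cycles that charge an energy or
#' redox carrier with all exchanges closed. For each of the 13 standard
#' carriers (ATP, CTP, GTP, UTP, ITP, NADH, NADPH, FMNH2, FADH2,
#' menaquinol-8, 2-demethylmenaquinol-8, acetyl-CoA, L-glutamate): close
#' every exchange reaction to zero flux, add the carrier's canonical
#' dissipation reaction (one at a time), maximise its flux. A non-zero
#' optimum means an energy-generating cycle exists; the reactions carrying
#' flux in that optimum are reported as the cycle support. A
#' cytosol-periplasm proton shuttle is added for models with a periplasm
#' so that proton-motive cycles are not masked.
#'
#' Carriers whose species are absent from the model are reported with
#' status `"absent"` (and a warning) rather than an error.
#'
#' @param model a `gem_model`.
#' @param carriers subset of carrier keys to test (default: all 13).
#' @param tol flux threshold for the support set.
#' @return data.frame with `carrier`, `dissipation_flux`, `status`, and a
#'   list column `cycle_support` of reaction ids.
#' @export
egc_scan <- function(model, carriers = names(egc_carrier_table()), tol = 1e-6) {
  tab <- egc_carrier_table()
  unknown <- setdiff(carriers, names(tab))
  if (length(unknown)) stop("unknown carrier(s): ", paste(unknown, collapse = ", "))
  closed <- model
  ex <- is_exchange_reaction(closed)
  closed$reactions$lower_bound[ex] <- 0
  closed$reactions$upper_bound[ex] <- 0
  if (all(c("h_c", "h_p") %in% closed$metabolites$id)) {
    closed$reactions <- rbind(closed$reactions, data.frame(
      id = "EGC_Hshuttle", name = "cytosol-periplasm proton exchange",
      lower_bound = -1000, upper_bound = 1000, gpr = NA_character_,
      sbo = "SBO:0000655"))
    closed$stoichiometry[["EGC_Hshuttle"]] <- c(h_c = -1, h_p = 1)
  }
  rows <- lapply(carriers, function(cr) {
    st <- tab[[cr]]
    missing <- setdiff(names(st), closed$metabolites$id)
    if (length(missing)) {
      warning("carrier '", cr, "' skipped; species absent: ",
              paste(missing, collapse = ", "), call. = FALSE)
      return(list(carrier = cr, dissipation_flux = NA_real_,
                  status = "absent", cycle_support = character(0)))
    }
    test <- closed
    rid <- paste0("DISSIPATION_", cr)
    test$reactions <- rbind(test$reactions, data.frame(
      id = rid, name = paste("energy dissipation for", cr),
      lower_bound = 0, upper_bound = 1000, gpr = NA_character_,
      sbo = "SBO:0000176"))
    test$stoichiometry[[rid]] <- st
    sol <- fba(test, rid, "max")
    support <- if (sol$status == "optimal" && sol$objective > tol) {
      ids <- names(sol$fluxes)[abs(sol$fluxes) > tol]
      setdiff(ids, rid)
    } else {
      character(0)
    }
    flux <- if (sol$status == "optimal") sol$objective else 0
    list(carrier = cr, dissipation_flux = flux, status = sol$status,
         cycle_support = support)
  })
  out <- data.frame(
    carrier = vapply(rows, `[[`, "", "carrier"),
    dissipation_flux = vapply(rows, `[[`, 0, "dissipation_flux"),
    status = vapply(rows, `[[`, "", "status"),
    stringsAsFactors = FALSE
  )
  out$cycle_support <- lapply(rows, `[[`, "cycle_support")
  out
}

#' Annotation and SBO-term coverage
#'
#' Deterministic counting of database cross-references and SBO terms per
#' entity class; no network access, presence only.
#'
#' @param model a `gem_model`.
#' @return list with per-class elements (`metabolites`, `reactions`,
#'   `genes`), each holding `fraction_annotated` and `databases`, plus
#'   `n_databases` (distinct across classes) and `sbo_histogram`.
#' @export
annotation_coverage <- function(model) {
  class_cov <- function(ids, ann) {
    has <- vapply(ids, function(i) {
      a <- ann[[i]]
      !is.null(a) && length(a) > 0L
    }, logical(1))
    dbs <- sort(unique(unlist(lapply(ann[ids], names))))
    list(fraction_annotated = if (length(ids)) mean(has) else 0,
         databases = dbs %||% character(0))
  }
  mets <- class_cov(model$metabolites$id, model$annotations$metabolites)
  rxns <- class_cov(model$reactions$id, model$annotations$reactions)
  genes <- class_cov(model$genes$id, model$annotations$genes)
  list(metabolites = mets, reactions = rxns, genes = genes,
       n_databases = length(unique(c(mets$databases, rxns$databases,
                                     genes$databases))),
       sbo_histogram = model_summary(model)$sbo_histogram)
}

#' Run the full quality audit
#'
#' Convenience wrapper producing one structured report: balance audit
#' summary, dead-ends/orphans, stoichiometric consistency, biomass weight
#' (when computable), energy-generating-cycle scan, and annotation
#' coverage. `n_defects` counts findings a curator must act on.
#'
#' @param model a `gem_model`.
#' @return list report; see components.
#' @export
quality_audit <- function(model) {
  bal <- balance_audit(model)
  de <- find_dead_ends(model)
  cons <- stoichiometric_consistency(model)
  bw <- tryCatch(
    if (!is.na(model$objective)) biomass_weight(model) else NA_real_,
    error = function(e) NA_real_)
  egc <- suppressWarnings(egc_scan(model))
  imbalanced <- bal$id[!(bal$verdict %in% c("balanced", "unverifiable"))]
  egc_hits <- egc$carrier[egc$status == "optimal" & egc$dissipation_flux > 1e-6]
  list(
    balance = bal,
    imbalanced_reactions = imbalanced,
    dead_end = de$dead_end,
    orphan = de$orphan,
    consistency = cons,
    biomass_weight = bw,
    egc = egc,
    egc_carriers_hit = egc_hits,
    annotation = annotation_coverage(model),
    n_defects = length(imbalanced) + length(de$dead_end) + length(de$orphan) +
      length(egc_hits)
  )
}
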