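#' Construct a metabolite specification
#'
#' @param id metabolite id; by BiGG convention the id carries a compartment
#'   suffix (`_c` cytosol, `_p` periplasm, `_e` extracellular).
#' @param name human-readable name.
#' @param formula chemical formula string or `NA` (unknown; never imputed).
#' @param charge integer charge or `NA` (unknown).
#' @param compartment single-letter compartment code; inferred from the id
#'   suffix when missing.
#' @param sbo SBO accession (e.g. `"SBO:0000247"`) or `NA`.
#' @return a list row usable in [gem_model()].
#' @export
met_spec <- function(id, name = id, formula = NA_character_,
                     charge = NA_integer_, compartment = NULL,
                     sbo = NA_character_) {
  if (is.null(compartment)) {
    compartment <- sub(".*_([a-z])$", "\\1", id)
    if (compartment == id) compartment <- "c"
  }
  list(id = id, name = name, formula = as.character(formula),
       charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
       compartment = compartment, sbo = as.character(sbo))
}

#' Construct a reaction specification
#'
#' @param id reaction id.
#' @param stoich named numeric vector: metabolite id -> signed coefficient
#'   (negative = consumed, positive = produced).
#' @param name human-readable name.
#' @param lb,ub flux bounds in mmol/gDW/h. Defaults follow the BiGG
#'   convention: reversible -1000/1000 (set `lb` explicitly for
#'   irreversible reactions).
#' @param gpr gene-protein-reaction rule string or `NA`.
#' @param sbo SBO accession or `NA`.
#' @return a list row usable in [gem_model()].
#' @export
rxn_spec <- function(id, stoich, name = id, lb = -1000, ub = 1000,
                     gpr = NA_character_, sbo = NA_character_) {
  stopifnot(is.numeric(stoich))
  list(id = id, name = name, stoich = stoich, lb = as.numeric(lb),
       ub = as.numeric(ub), gpr = as.character(gpr), sbo = as.character(sbo))
}

#' Assemble a genome-scale metabolic model
#'
#' The in-memory representation used throughout the package: metabolite and
#' reaction tables, a stoichiometry list, gene products, subsystem groups,
#' the objective (biomass) reaction, and the unit declarations
#' (extent mmol/gDW, time h, volume fl).
#'
#' @param id model identifier.
#' @param metabolites list of [met_spec()] rows.
#' @param reactions list of [rxn_spec()] rows.
#' @param genes data.frame with columns `id`, `label`, or `NULL`; when
#'   `NULL`, genes are collected from the GPR rules.
#' @param groups named list: group name -> character vector of reaction ids.
#' @param objective id of the objective (biomass) reaction, or `NA`.
#' @param annotations list with elements `metabolites`, `reactions`,
#'   `genes`; each a named list id -> named list(database -> identifiers).
#' @param validate run [validate_model()] on the result.
#' @return an object of class `gem_model`.
#' @export
gem_model <- function(id, metabolites = list(), reactions = list(),
                      genes = NULL, groups = list(),
                      objective = NA_character_,
                      annotations = NULL, validate = TRUE) {
  mets <- if (length(metabolites)) {
    do.call(rbind, lapply(metabolites, function(m) {
      data.frame(id = m$id, name = m$name, compartment = m$compartment,
                 formula = m$formula, charge = m$charge, sbo = m$sbo,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(0), name = character(0),
               compartment = character(0), formula = character(0),
               charge = integer(0), sbo = character(0))
  }
  rxns <- if (length(reactions)) {
    do.call(rbind, lapply(reactions, function(r) {
      data.frame(id = r$id, name = r$name, lower_bound = r$lb,
                 upper_bound = r$ub, gpr = r$gpr, sbo = r$sbo,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(0), name = character(0),
               lower_bound = numeric(0), upper_bound = numeric(0),
               gpr = character(0), sbo = character(0))
  }
  stoich <- stats::setNames(lapply(reactions, function(r) r$stoich), rxns$id)
  if (is.null(genes)) {
    gids <- unique(unlist(lapply(rxns$gpr, function(g) gpr_genes(parse_gpr(g)))))
    genes <- data.frame(id = as.character(gids %||% character(0)),
                        label = as.character(gids %||% character(0)),
                        stringsAsFactors = FALSE)
  }
  if (is.null(annotations)) {
    annotations <- list(metabolites = list(), reactions = list(), genes = list())
  }
  model <- structure(list(
    id = id, metabolites = mets, reactions = rxns, stoichiometry = stoich,
    genes = genes, groups = groups, objective = objective,
    annotations = annotations,
    units = list(extent = "mmol_per_gDW", time = "h", volume = "fl")
  ), class = "gem_model")
  if (validate) validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the internal consistency of a model
#'
#' Checks id uniqueness, resolution of all cross-references (stoichiometry,
#' groups, GPR genes, objective), bound ordering, and the compartment set.
#'
#' @param model a `gem_model`.
#' @return the model, invisibly; stops with an informative message on the
#'   first violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gem_model"))
  mids <- model$metabolites$id
  rids <- model$reactions$id
  if (anyDuplicated(mids)) stop("duplicate metabolite ids: ",
                                paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  bad_comp <- setdiff(unique(model$metabolites$compartment), c("c", "p", "e"))
  if (length(bad_comp)) stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "))
  for (rid in rids) {
    st <- model$stoichiometry[[rid]]
    missing <- setdiff(names(st), mids)
    if (length(missing)) {
      stop("reaction '", rid, "' references undefined species: ",
           paste(missing, collapse = ", "))
    }
  }
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                     paste(rids[bad], collapse = ", "))
  if (!is.na(model$objective) && !(model$objective %in% rids)) {
    stop("objective reaction '", model$objective, "' not in model")
  }
  gids <- model$genes$id
  for (i in seq_along(rids)) {
    gg <- gpr_genes(parse_gpr(model$reactions$gpr[i]))
    missing <- setdiff(gg, gids)
    if (length(missing)) {
      stop("reaction '", rids[i], "' GPR references unknown gene(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (g in names(model$groups)) {
    missing <- setdiff(model$groups[[g]], rids)
    if (length(missing)) {
      stop("group '", g, "' references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(model)
}

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (any(is.na(i))) {
    stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Set the flux bounds of a reaction
#' @param model a `gem_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model (copy; models are immutable values).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}

#' Identify pseudo-reactions (exchange, demand, sink, biomass)
#'
#' A reaction is considered a pseudo-reaction when its id carries one of the
#' conventional prefixes (`EX_`, `DM_`, `SK_`, `sink_`) or its SBO term marks
#' it as exchange (SBO:0000627), demand (SBO:0000628), sink (SBO:0000632) or
#' biomass production (SBO:0000629) -- the union of both signals, since
#' deposited models vary in which convention they follow.
#'
#' @param model a `gem_model`.
#' @return logical vector along `model$reactions`.
#' @export
is_pseudo_reaction <- function(model) {
  id <- model$reactions$id
  sbo <- model$reactions$sbo
  pre <- grepl("^(EX_|DM_|SK_|sink_)", id)
  term <- !is.na(sbo) & sbo %in% c("SBO:0000627", "SBO:0000628",
                                   "SBO:0000632", "SBO:0000629")
  pre | term
}

#' Identify boundary reactions for the thermodynamic loop law
#'
#' A reaction is *internal* iff it moves no species across the system
#' boundary. Boundary reactions are the pseudo-reactions plus any reaction
#' whose participants all appear with the same sign (pure creation or
#' drain). Only internal reactions are subject to the loop-law constraints
#' of loopless FVA.
#'
#' @param model a `gem_model`.
#' @return logical vector: `TRUE` for internal reactions.
#' @export
is_internal_reaction <- function(model) {
  one_sided <- vapply(model$stoichiometry, function(st) {
    length(st) == 0L || all(st > 0) || all(st < 0)
  }, logical(1))
  !(is_pseudo_reaction(model) | one_sided)
}

#' Identify exchange reactions
#'
#' Exchange reactions connect the model to the environment: a single
#' extracellular species consumed or produced from nothing, conventionally
#' prefixed `EX_` or carrying SBO:0000627.
#'
#' @param model a `gem_model`.
#' @return logical vector along `model$reactions`.
#' @export
is_exchange_reaction <- function(model) {
  id <- model$reactions$id
  sbo <- model$reactions$sbo
  grepl("^EX_", id) | (!is.na(sbo) & sbo == "SBO:0000627")
}

#' Summary counts for a model
#'
#' Entity counts plus the reaction SBO-term histogram (the basis for
#' SBO-prevalence plots in model reports).
#'
#' @param model a `gem_model`.
#' @return list with `n_metabolites`, `n_reactions`, `n_genes`, `n_groups`
#'   and `sbo_histogram` (named integer vector, accession -> count).
#' @export
model_summary <- function(model) {
  sbo <- model$reactions$sbo
  sbo <- sbo[!is.na(sbo)]
  hist <- if (length(sbo)) {
    tab <- table(sbo)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(n_metabolites = nrow(model$metabolites),
       n_reactions = nrow(model$reactions),
       n_genes = nrow(model$genes),
       n_groups = length(model$groups),
       sbo_histogram = hist)
}

#' @export
print.gem_model <- function(x, ...) {
  s <- model_summary(x)
  cat("<gem_model> ", x$id, "\n",
      "  metabolites: ", s$n_metabolites,
      "  reactions: ", s$n_reactions,
      "  genes: ", s$n_genes,
      "  groups: ", s$n_groups, "\n",
      "  objective: ", ifelse(is.na(x$objective), "<none>", x$objective), "\n",
      sep = "")
  invisible(x)
}
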