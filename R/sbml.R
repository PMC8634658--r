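SBML_NS <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  groups = "http://www.sbml.org/sbml/level3/version1/groups/version1",
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  bqbiol = "http://biomodels.net/biology-qualifiers/"
)

# SBML ids conventionally prefix metabolites/reactions/genes with M_/R_/G_
# (also required because ids like "2dmmql8_c" are not valid SBML SIds).
sbml_mid <- function(id) paste0("M_", id)
sbml_rid <- function(id) paste0("R_", id)
sbml_gid <- function(id) paste0("G_", gsub("[^A-Za-z0-9_]", "_", id))
strip_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

num_attr <- function(x) format(x, scientific = FALSE, digits = 15)

#' Write a model to SBML Level 3 Version 1 with fbc and groups
#'
#' Emits SBML L3V1 with the fbc (version 2) and groups (version 1)
#' extensions: species with chemical formula and charge, reactions with
#' flux-bound parameters in mmol/gDW/h, gene products and gene-product
#' associations, subsystem groups with members, the active maximisation
#' objective, SBO terms, and MIRIAM-style annotation bags. The model
#' element declares `extentUnits`/`timeUnits` (mmol/gDW and h) and
#' `substanceUnits`/`volumeUnits` (mmol/gDW and fl), so every reaction and
#' bound carries the flux unit mmol/gDW/h.
#'
#' Shared parameters are emitted for the default bounds (-1000, 0, 1000);
#' any other bound value gets a per-reaction parameter. Models that fail
#' [validate_model()] (unresolved references) are refused.
#'
#' @param model a `gem_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS[["s"]], "xmlns:fbc" = SBML_NS[["fbc"]],
    "xmlns:groups" = SBML_NS[["groups"]],
    level = "3", version = "1",
    "fbc:required" = "false", "groups:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
    id = model$id, name = model$id,
    substanceUnits = "mmol_per_gDW", timeUnits = "h",
    extentUnits = "mmol_per_gDW", volumeUnits = "fl",
    "fbc:strict" = "true")

  # unit definitions: mmol/gDW, hour, mmol/gDW/h, femtolitre
  uds <- xml2::xml_add_child(mdl, "listOfUnitDefinitions")
  add_unit <- function(parent, kind, exponent, scale, multiplier) {
    xml2::xml_add_child(parent, "unit", kind = kind,
                        exponent = num_attr(exponent), scale = num_attr(scale),
                        multiplier = num_attr(multiplier))
  }
  u1 <- xml2::xml_add_child(uds, "unitDefinition", id = "mmol_per_gDW")
  l1 <- xml2::xml_add_child(u1, "listOfUnits")
  add_unit(l1, "mole", 1, -3, 1); add_unit(l1, "gram", -1, 0, 1)
  u2 <- xml2::xml_add_child(uds, "unitDefinition", id = "h")
  l2 <- xml2::xml_add_child(u2, "listOfUnits")
  add_unit(l2, "second", 1, 0, 3600)
  u3 <- xml2::xml_add_child(uds, "unitDefinition", id = "mmol_per_gDW_per_h")
  l3 <- xml2::xml_add_child(u3, "listOfUnits")
  add_unit(l3, "mole", 1, -3, 1); add_unit(l3, "gram", -1, 0, 1)
  add_unit(l3, "second", -1, 0, 3600)
  u4 <- xml2::xml_add_child(uds, "unitDefinition", id = "fl")
  l4 <- xml2::xml_add_child(u4, "listOfUnits")
  add_unit(l4, "litre", 1, -15, 1)

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  comp_names <- c(c = "cytosol", p = "periplasm", e = "extracellular space")
  for (cid in sort(unique(model$metabolites$compartment))) {
    xml2::xml_add_child(comps, "compartment", id = cid,
                        name = comp_names[[cid]], spatialDimensions = "3",
                        size = "1", units = "fl", constant = "true")
  }

  add_annotation <- function(node, metaid, ann) {
    if (is.null(ann) || length(ann) == 0L) return(invisible())
    xml2::xml_set_attr(node, "metaid", metaid)
    an <- xml2::xml_add_child(node, "annotation")
    lis <- unlist(lapply(names(ann), function(db) {
      vapply(ann[[db]], function(acc) sprintf(
        '<rdf:li rdf:resource="https://identifiers.org/%s/%s"/>', db, acc), "")
    }))
    rdf_txt <- paste0(
      '<rdf:RDF xmlns:rdf="', SBML_NS[["rdf"]], '" xmlns:bqbiol="',
      SBML_NS[["bqbiol"]], '"><rdf:Description rdf:about="#', metaid,
      '"><bqbiol:is><rdf:Bag>', paste(lis, collapse = ""),
      '</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF>')
    xml2::xml_add_child(an, xml2::read_xml(rdf_txt))
    invisible()
  }

  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(spl, "species",
      id = sbml_mid(m$id), name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$sbo)) xml2::xml_set_attr(sp, "sboTerm", m$sbo)
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", num_attr(m$charge))
    add_annotation(sp, paste0("meta_", sbml_mid(m$id)),
                   model$annotations$metabolites[[m$id]])
  }

  # flux-bound parameters: shared for the conventional defaults,
  # per-reaction otherwise
  shared <- c(default_lb = -1000, zero_bound = 0, default_ub = 1000)
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (pn in names(shared)) {
    xml2::xml_add_child(pl, "parameter", id = pn,
                        value = num_attr(shared[[pn]]), constant = "true",
                        units = "mmol_per_gDW_per_h", sboTerm = "SBO:0000626")
  }
  bound_param <- function(rid, value, side) {
    hit <- names(shared)[shared == value]
    if (length(hit)) return(hit[1])
    pid <- paste0(sbml_rid(rid), "_", side)
    xml2::xml_add_child(pl, "parameter", id = pid, value = num_attr(value),
                        constant = "true", units = "mmol_per_gDW_per_h",
                        sboTerm = "SBO:0000625")
    pid
  }

  write_gpr_node <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = sbml_gid(tree))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (a in tree$args) write_gpr_node(node, a)
    }
  }

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    rx <- xml2::xml_add_child(rl, "reaction",
      id = sbml_rid(r$id), name = r$name,
      reversible = tolower(as.character(r$lower_bound < 0)), fast = "false",
      "fbc:lowerFluxBound" = bound_param(r$id, r$lower_bound, "lower_bound"),
      "fbc:upperFluxBound" = bound_param(r$id, r$upper_bound, "upper_bound"))
    if (!is.na(r$sbo)) xml2::xml_set_attr(rx, "sboTerm", r$sbo)
    add_annotation(rx, paste0("meta_", sbml_rid(r$id)),
                   model$annotations$reactions[[r$id]])
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sbml_mid(names(reac)[k]),
                            stoichiometry = num_attr(-reac[[k]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sbml_mid(names(prod)[k]),
                            stoichiometry = num_attr(prod[[k]]),
                            constant = "true")
      }
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      write_gpr_node(gpa, tree)
    }
  }

  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = sbml_rid(model$objective),
                        "fbc:coefficient" = "1")
  }

  if (nrow(model$genes) > 0L) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(model$genes))) {
      g <- model$genes[i, ]
      gp <- xml2::xml_add_child(lg, "fbc:geneProduct",
                                "fbc:id" = sbml_gid(g$id),
                                "fbc:label" = g$label, sboTerm = "SBO:0000243")
      add_annotation(gp, paste0("meta_", sbml_gid(g$id)),
                     model$annotations$genes[[g$id]])
    }
  }

  if (length(model$groups) > 0L) {
    lgr <- xml2::xml_add_child(mdl, "groups:listOfGroups")
    for (k in seq_along(model$groups)) {
      gr <- xml2::xml_add_child(lgr, "groups:group",
                                "groups:id" = paste0("group", k),
                                "groups:name" = names(model$groups)[k],
                                "groups:kind" = "partonomy",
                                sboTerm = "SBO:0000633")
      lm <- xml2::xml_add_child(gr, "groups:listOfMembers")
      for (rid in model$groups[[k]]) {
        xml2::xml_add_child(lm, "groups:member",
                            "groups:idRef" = sbml_rid(rid))
      }
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

# namespace-normalised attribute lookup: xml_attrs with a prefix map
# renames attribute namespaces to our canonical prefixes
ns_attr <- function(node, name, ns = SBML_NS) {
  at <- xml2::xml_attrs(node, ns)
  if (name %in% names(at)) unname(at[[name]]) else NA_character_
}

read_gpr_node <- function(node, ns = SBML_NS) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(strip_prefix(ns_attr(node, "fbc:geneProduct"), "G_"))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./*", ns)
    return(list(op = nm, args = lapply(kids, read_gpr_node, ns = ns)))
  }
  if (nm == "geneProductAssociation") {
    kids <- xml2::xml_find_all(node, "./*", ns)
    return(read_gpr_node(kids[[1]], ns))
  }
  stop("unexpected node '", nm, "' in gene-product association")
}

read_annotation <- function(node, ns = SBML_NS) {
  lis <- xml2::xml_find_all(node, ".//rdf:li", ns)
  if (length(lis) == 0L) return(NULL)
  uris <- vapply(lis, function(li) ns_attr(li, "rdf:resource"), "")
  m <- regmatches(uris, regexec("identifiers\\.org/([^/]+)/(.+)$", uris))
  out <- list()
  for (g in m) {
    if (length(g) == 3L) out[[g[2]]] <- c(out[[g[2]]], g[3])
  }
  if (length(out)) out else NULL
}

#' Read a model from SBML Level 3 Version 1 with fbc
#'
#' Parses SBML L3V1 with the fbc (flux bounds, charges, formulas, gene
#' products, objective) and groups (subsystems) extensions into a
#' `gem_model`. SBO terms, MIRIAM annotation cross-references and group
#' memberships are preserved. Missing formulas and charges are recorded as
#' absent (`NA`), never as zero. The conventional `M_`/`R_`/`G_` id
#' prefixes are stripped.
#'
#' Integrity violations are raised as errors: malformed XML (with parser
#' line information), reactions referencing undeclared species, and
#' reactions whose flux-bound attribute names no declared parameter.
#'
#' @param path SBML file.
#' @return a `gem_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- SBML_NS
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in '", path, "'")
  model_id <- xml2::xml_attr(mdl, "id")

  params <- xml2::xml_find_all(mdl, "./s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    as.numeric(vapply(params, function(p) xml2::xml_attr(p, "value"), "")),
    vapply(params, function(p) xml2::xml_attr(p, "id"), ""))

  sp_nodes <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", ns)
  ann_m <- list()
  mets <- lapply(sp_nodes, function(sp) {
    sid <- strip_prefix(xml2::xml_attr(sp, "id"), "M_")
    ch <- ns_attr(sp, "fbc:charge")
    a <- read_annotation(sp, ns)
    if (!is.null(a)) ann_m[[sid]] <<- a
    met_spec(sid,
             name = xml2::xml_attr(sp, "name") %na% sid,
             formula = ns_attr(sp, "fbc:chemicalFormula"),
             charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
             compartment = xml2::xml_attr(sp, "compartment"),
             sbo = xml2::xml_attr(sp, "sboTerm"))
  })
  mids <- vapply(mets, `[[`, "", "id")

  rx_nodes <- xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction", ns)
  ann_r <- list()
  rxns <- lapply(rx_nodes, function(rx) {
    rid <- strip_prefix(xml2::xml_attr(rx, "id"), "R_")
    get_bound <- function(which) {
      pid <- ns_attr(rx, paste0("fbc:", which, "FluxBound"))
      if (is.na(pid) || !(pid %in% names(pvals))) {
        stop("reaction '", rid, "': missing or undeclared ", which,
             " flux-bound parameter", call. = FALSE)
      }
      pvals[[pid]]
    }
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rx, xp, ns)
      if (length(nodes) == 0L) return(stats::setNames(numeric(0), character(0)))
      ids <- strip_prefix(vapply(nodes, function(n) xml2::xml_attr(n, "species"), ""), "M_")
      co <- as.numeric(vapply(nodes, function(n) xml2::xml_attr(n, "stoichiometry"), ""))
      stats::setNames(sign * co, ids)
    }
    st <- c(refs("./s:listOfReactants/s:speciesReference", -1),
            refs("./s:listOfProducts/s:speciesReference", +1))
    if (anyDuplicated(names(st))) {
      st <- tapply(st, names(st), sum)
      st <- stats::setNames(as.numeric(st), names(st))
    }
    missing <- setdiff(names(st), mids)
    if (length(missing)) {
      stop("reaction '", rid, "' references species not in listOfSpecies: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) NA_character_ else
      deparse_gpr(read_gpr_node(gpa, ns))
    a <- read_annotation(rx, ns)
    if (!is.null(a)) ann_r[[rid]] <<- a
    rxn_spec(rid, st,
             name = xml2::xml_attr(rx, "name") %na% rid,
             lb = get_bound("lower"), ub = get_bound("upper"),
             gpr = gpr, sbo = xml2::xml_attr(rx, "sboTerm"))
  })

  gp_nodes <- xml2::xml_find_all(mdl, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  ann_g <- list()
  genes <- if (length(gp_nodes)) {
    data.frame(
      id = vapply(gp_nodes, function(g) strip_prefix(ns_attr(g, "fbc:id"), "G_"), ""),
      label = vapply(gp_nodes, function(g) ns_attr(g, "fbc:label") %na% "", ""),
      stringsAsFactors = FALSE)
  } else {
    NULL
  }
  for (g in gp_nodes) {
    a <- read_annotation(g, ns)
    if (!is.null(a)) ann_g[[strip_prefix(ns_attr(g, "fbc:id"), "G_")]] <- a
  }

  fo <- xml2::xml_find_first(
    mdl, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  objective <- if (inherits(fo, "xml_missing")) NA_character_ else
    strip_prefix(ns_attr(fo, "fbc:reaction"), "R_")

  grp_nodes <- xml2::xml_find_all(mdl, "./groups:listOfGroups/groups:group", ns)
  groups <- list()
  for (g in grp_nodes) {
    gname <- ns_attr(g, "groups:name") %na% ns_attr(g, "groups:id")
    members <- xml2::xml_find_all(g, "./groups:listOfMembers/groups:member", ns)
    groups[[gname]] <- strip_prefix(
      vapply(members, function(m) ns_attr(m, "groups:idRef"), ""), "R_")
  }

  gem_model(model_id %na% "model", mets, rxns, genes = genes, groups = groups,
            objective = objective,
            annotations = list(metabolites = ann_m, reactions = ann_r,
                               genes = ann_g))
}

`%na%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
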