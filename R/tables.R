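REACTION_ARROWS <- c("<=>", "<->", "⇌", "-->", "->", "→")

#' Parse a reaction equation string
#'
#' Accepts equations of the form `"accoa_c + h2o_c + oaa_c -> cit_c +
#' coa_c + h_c"` with optional leading coefficients (`"2 pep_c"`). The
#' arrow determines reversibility: `<=>`, `<->` and the unicode
#' equilibrium arrow are reversible; `->`, `-->` and the unicode right
#' arrow are irreversible. Either side may be empty (exchange/sink
#' notation); the empty-set sign is tolerated.
#'
#' @param text equation string.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(text) {
  arrow <- NULL
  for (a in REACTION_ARROWS) {
    if (grepl(a, text, fixed = TRUE)) { arrow <- a; break }
  }
  if (is.null(arrow)) {
    stop("no reaction arrow found in equation: '", text, "'", call. = FALSE)
  }
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) {
    stop("more than one arrow in equation: '", text, "'", call. = FALSE)
  }
  parse_side <- function(side, sign) {
    side <- gsub("∅", "", side)           # tolerate the empty-set sign
    side <- trimws(side)
    if (side == "") return(stats::setNames(numeric(0), character(0)))
    if (grepl("(^\\+)|(\\+\\s*$)|(\\+\\s*\\+)", side)) {
      stop("empty term in equation side: '", side, "'", call. = FALSE)
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") {
        stop("empty term in equation side: '", side, "'", call. = FALSE)
      }
      toks <- strsplit(tm, "\\s+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2L &&
                 grepl("^\\(?[0-9.]+\\)?$", toks[1])) {
        coef <- as.numeric(gsub("[()]", "", toks[1])); met <- toks[2]
      } else {
        stop("cannot parse equation term: '", tm, "'", call. = FALSE)
      }
      if (is.na(coef)) stop("bad coefficient in term: '", tm, "'", call. = FALSE)
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
  }
  st <- st[st != 0]
  list(stoich = st, reversible = arrow %in% c("<=>", "<->", "⇌"))
}

#' Build a model from CSV tables
#'
#' Converts the spreadsheet-style representation many reconstructions are
#' distributed in into a proper model. Comma-separated, UTF-8, header row
#' required.
#'
#' Metabolites table columns: `id`, `name`, `formula`, `charge`
#' (`compartment` optional, inferred from the id suffix). Reactions table
#' columns: `id`, `name`, `equation`, plus optional `lower_bound`,
#' `upper_bound`, `gpr`, `subsystem`. Genes table (optional): `id`,
#' `label`. Blank bounds default to 0/1000 for irreversible and
#' -1000/1000 for reversible equations (BiGG convention); explicit bounds
#' win over the arrow. Subsystems become groups. Errors are row-level and
#' name the offending reaction and token.
#'
#' @param reactions_csv,metabolites_csv,genes_csv file paths; `genes_csv`
#'   may be `NULL`.
#' @param model_id id for the resulting model.
#' @return a `gem_model`.
#' @export
from_tables <- function(reactions_csv, metabolites_csv, genes_csv = NULL,
                        model_id = "converted_model") {
  mt <- utils::read.csv(metabolites_csv, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  rt <- utils::read.csv(reactions_csv, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(what, " table lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  need(mt, c("id", "name"), "metabolites")
  need(rt, c("id", "name", "equation"), "reactions")
  if (anyDuplicated(mt$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(mt$id[duplicated(mt$id)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rt$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rt$id[duplicated(rt$id)]), collapse = ", "), call. = FALSE)
  }
  blank_na <- function(x) {
    if (is.null(x)) return(NULL)
    x[!is.na(x) & trimws(as.character(x)) == ""] <- NA
    x
  }
  mets <- lapply(seq_len(nrow(mt)), function(i) {
    ch <- blank_na(mt$charge)[i] %||% NA
    met_spec(mt$id[i], name = mt$name[i],
             formula = (blank_na(mt$formula)[i] %||% NA_character_),
             charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
             compartment = if ("compartment" %in% names(mt))
               blank_na(mt$compartment)[i] else NULL,
             sbo = "SBO:0000247")
  })
  rxns <- list()
  groups <- list()
  for (i in seq_len(nrow(rt))) {
    eq <- tryCatch(parse_equation(rt$equation[i]), error = function(e) {
      stop("reactions table row ", i, " ('", rt$id[i], "'): ",
           conditionMessage(e), call. = FALSE)
    })
    lb <- blank_na(rt$lower_bound)[i] %||% NA
    ub <- blank_na(rt$upper_bound)[i] %||% NA
    lb <- if (is.na(lb)) (if (eq$reversible) -1000 else 0) else as.numeric(lb)
    ub <- if (is.na(ub)) 1000 else as.numeric(ub)
    gpr <- blank_na(rt$gpr)[i] %||% NA_character_
    sbo <- if (grepl("^EX_", rt$id[i])) "SBO:0000627" else
           if (grepl("^(sink_|SK_)", rt$id[i])) "SBO:0000632" else
           if (grepl("^DM_", rt$id[i])) "SBO:0000628" else
           if (grepl("biomass", rt$id[i], ignore.case = TRUE)) "SBO:0000629" else
           "SBO:0000176"
    rxns[[length(rxns) + 1L]] <-
      rxn_spec(rt$id[i], eq$stoich, name = rt$name[i], lb = lb, ub = ub,
               gpr = as.character(gpr), sbo = sbo)
    subsys <- blank_na(rt$subsystem)[i] %||% NA
    if (!is.na(subsys)) groups[[subsys]] <- c(groups[[subsys]], rt$id[i])
  }
  genes <- NULL
  if (!is.null(genes_csv)) {
    gt <- utils::read.csv(genes_csv, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
    need(gt, "id", "genes")
    genes <- data.frame(id = gt$id,
                        label = if ("label" %in% names(gt)) gt$label else gt$id,
                        stringsAsFactors = FALSE)
  }
  objective <- NA_character_
  bio <- grep("biomass", rt$id, ignore.case = TRUE, value = TRUE)
  if (length(bio)) objective <- bio[1]
  gem_model(model_id, mets, rxns, genes = genes, groups = groups,
            objective = objective)
}
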