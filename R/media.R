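#' Define a growth medium
#'
#' A medium is a named set of exchange reactions with uptake magnitudes
#' (positive numbers, mmol/gDW/h); applying it opens exactly those uptakes
#' and closes all others. Media are data, not code: see [read_medium()] for
#' the YAML file format shipped under `inst/extdata/media/`.
#'
#' @param name medium name.
#' @param components named numeric vector: exchange reaction id -> uptake
#'   magnitude (> 0). The conventional default magnitude is 10.
#' @param carbon_source id of the designated carbon-source exchange (used
#'   by [swap_carbon_source()]), or `NA`.
#' @param notes free-text provenance notes.
#' @return an object of class `medium`.
#' @export
medium <- function(name, components, carbon_source = NA_character_,
                   notes = NULL) {
  stopifnot(is.numeric(components))
  if (length(components) > 0L && is.null(names(components))) {
    stop("components must be named by exchange reaction id")
  }
  if (any(components <= 0)) stop("uptake magnitudes must be positive")
  if (!is.na(carbon_source) && !(carbon_source %in% names(components))) {
    stop("carbon source '", carbon_source, "' is not a medium component")
  }
  structure(list(name = name, components = components,
                 carbon_source = carbon_source, notes = notes),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> ", x$name, " (", length(x$components), " components",
      if (!is.na(x$carbon_source)) paste0(", carbon source ", x$carbon_source),
      ")\n", sep = "")
  invisible(x)
}

#' Read a medium definition from YAML
#'
#' Expected structure:
#' ```yaml
#' name: CGXII
#' carbon_source: EX_glc__D_e
#' components:
#'   EX_glc__D_e: 10
#'   EX_nh4_e: 10
#' ```
#' @param path YAML file.
#' @return a [medium()].
#' @export
read_medium <- function(path) {
  y <- yaml::read_yaml(path)
  medium(y$name, unlist(y$components),
         carbon_source = y$carbon_source %||% NA_character_,
         notes = y$notes)
}

#' Write a medium definition to YAML
#' @param med a [medium()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  yaml::write_yaml(list(name = med$name,
                        carbon_source = if (is.na(med$carbon_source)) NULL
                                        else med$carbon_source,
                        components = as.list(med$components),
                        notes = med$notes), path)
  invisible(path)
}

#' Load a medium shipped with the package
#' @param name file stem under `extdata/media` (e.g. `"cgxii"`,
#'   `"m9"`, `"lb_approximation"`, `"glutamate_core"`).
#' @return a [medium()].
#' @export
shipped_medium <- function(name) {
  path <- system.file("extdata", "media", paste0(name, ".yaml"),
                      package = "gemfba")
  if (path == "") stop("no shipped medium '", name, "'")
  read_medium(path)
}

#' Constrain a model to a medium
#'
#' Sets the lower bound of each exchange listed in the medium to minus its
#' uptake magnitude and the lower bound of every other exchange to zero.
#' Secretion (upper) bounds are untouched. The oxygen exchange is governed
#' by the `aerobic` flag, overriding the medium list: open at the medium's
#' oxygen magnitude (or `default_magnitude` when unlisted) if aerobic,
#' closed otherwise.
#'
#' @param model a `gem_model`.
#' @param med a [medium()].
#' @param aerobic logical.
#' @param o2_id id of the oxygen exchange.
#' @param default_magnitude uptake used for oxygen when the medium does not
#'   list it.
#' @return the constrained model copy.
#' @export
apply_medium <- function(model, med, aerobic = TRUE, o2_id = "EX_o2_e",
                         default_magnitude = 10) {
  ex <- is_exchange_reaction(model)
  ex_ids <- model$reactions$id[ex]
  unknown <- setdiff(names(med$components), ex_ids)
  if (length(unknown)) {
    stop("medium '", med$name, "' lists non-exchange or missing reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  model$reactions$lower_bound[ex] <- 0
  i <- match(names(med$components), model$reactions$id)
  model$reactions$lower_bound[i] <- -unname(med$components)
  if (o2_id %in% model$reactions$id) {
    mag <- if (o2_id %in% names(med$components)) {
      med$components[[o2_id]]
    } else {
      default_magnitude
    }
    model <- set_bounds(model, o2_id, lb = if (aerobic) -mag else 0)
  }
  model
}

#' Swap the carbon source of a medium
#'
#' Returns the medium with the previous carbon-source exchange removed and
#' the new one added at the default magnitude of 10 mmol/gDW/h; all other
#' components are unchanged. Swapping to the current source is a no-op.
#'
#' @param med a [medium()] with a designated carbon source.
#' @param new_source_exchange_id exchange id of the new carbon source.
#' @param magnitude uptake magnitude for the new source.
#' @return the modified [medium()].
#' @export
swap_carbon_source <- function(med, new_source_exchange_id, magnitude = 10) {
  if (is.na(med$carbon_source)) {
    stop("medium '", med$name, "' has no designated carbon source slot")
  }
  if (!grepl("^EX_", new_source_exchange_id)) {
    stop("'", new_source_exchange_id, "' is not an exchange reaction id")
  }
  if (identical(new_source_exchange_id, med$carbon_source)) return(med)
  comp <- med$components
  comp <- comp[names(comp) != med$carbon_source]
  comp[new_source_exchange_id] <- magnitude
  medium(med$name, comp, carbon_source = new_source_exchange_id,
         notes = med$notes)
}

#' Growth simulation across media, conditions and carbon sources
#'
#' One FBA per cell of the (medium or carbon source) x condition matrix.
#' Growth rates below 1e-6 are reported as 0 ("no growth"); per-cell errors
#' and infeasibilities are recorded in `status`, never aborting the matrix.
#'
#' @param model a `gem_model` with a biomass objective.
#' @param media list of [medium()] objects (used as given), or a single
#'   medium when `carbon_sources` is supplied.
#' @param conditions subset of `c("aerobic", "anaerobic")`.
#' @param carbon_sources optional character vector of carbon-source
#'   exchange ids; each is swapped into the single `media` medium.
#' @return data.frame with `medium`, `aerobic`, `carbon_source`, `mu`,
#'   `status`.
#' @export
growth_matrix <- function(model, media, conditions = c("aerobic", "anaerobic"),
                          carbon_sources = NULL) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (inherits(media, "medium")) media <- list(media)
  cells <- list()
  if (!is.null(carbon_sources)) {
    if (length(media) != 1L) {
      stop("carbon-source scans need exactly one base medium")
    }
    for (src in carbon_sources) {
      cells[[length(cells) + 1L]] <- list(
        med = swap_carbon_source(media[[1L]], src), src = src)
    }
  } else {
    for (med in media) {
      cells[[length(cells) + 1L]] <- list(med = med, src = "as-defined")
    }
  }
  rows <- list()
  for (cell in cells) {
    for (cond in conditions) {
      res <- tryCatch({
        m <- apply_medium(model, cell$med, aerobic = (cond == "aerobic"))
        sol <- fba(m)
        mu <- if (sol$status == "optimal") sol$objective else 0
        if (mu < 1e-6) mu <- 0
        list(mu = mu, status = sol$status)
      }, error = function(e) list(mu = 0, status = paste0("error: ",
                                                          conditionMessage(e))))
      rows[[length(rows) + 1L]] <- data.frame(
        medium = cell$med$name, aerobic = (cond == "aerobic"),
        carbon_source = cell$src, mu = res$mu, status = res$status,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
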