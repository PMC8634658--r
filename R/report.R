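#' Write a data frame as TSV
#'
#' Tab-separated, no quoting, no row names -- the exchange format for all
#' tabular reports (flux tables, growth matrices, production profiles).
#' List columns are flattened to `;`-separated strings.
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  flat <- df
  for (cn in names(flat)) {
    if (is.list(flat[[cn]])) {
      flat[[cn]] <- vapply(flat[[cn]], function(x)
        paste(unlist(x), collapse = ";"), "")
    }
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a nested report as JSON
#' @param x report list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Reproducibility manifest for a run
#'
#' Echoes the exact configuration used plus package and R versions and the
#' wall time, so any report can be tied back to its inputs. Timestamps
#' live only here, keeping report payloads byte-reproducible.
#'
#' @param config named list of the settings used.
#' @param started `proc.time()` snapshot from the start of the run.
#' @return manifest list.
#' @export
run_manifest <- function(config, started = NULL) {
  list(config = config,
       package = as.character(utils::packageVersion("gemfba")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       wall_time_s = if (!is.null(started))
         unname((proc.time() - started)["elapsed"]) else NA_real_)
}

#' Run the quality audit and serialize its report
#'
#' Library-level backend of the `audit` command-line subcommand: runs
#' [quality_audit()], writes the balance table as TSV and the full report
#' as JSON with a manifest.
#'
#' @param model a `gem_model`.
#' @param out_dir output directory (created if needed).
#' @param config configuration echoed into the manifest.
#' @return the audit report, invisibly; the number of defects found is in
#'   `$n_defects` (drives the CI exit code of the CLI).
#' @export
audit_report <- function(model, out_dir, config = list()) {
  started <- proc.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- quality_audit(model)
  write_tsv(rep$balance, file.path(out_dir, "balance.tsv"))
  write_tsv(rep$egc, file.path(out_dir, "egc.tsv"))
  json <- list(
    model = model$id,
    summary = model_summary(model),
    imbalanced_reactions = rep$imbalanced_reactions,
    dead_end = rep$dead_end, orphan = rep$orphan,
    consistency = rep$consistency,
    biomass_weight = rep$biomass_weight,
    egc_carriers_hit = rep$egc_carriers_hit,
    annotation = rep$annotation,
    n_defects = rep$n_defects,
    manifest = run_manifest(config, started))
  write_report_json(json, file.path(out_dir, "audit.json"))
  invisible(rep)
}
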