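# File-in/file-out pipeline stages behind the command-line front end
# (inst/cli/pdactrials.R). Each stage is pure with respect to its declared
# inputs and outputs; progress is logged with message() (standard error),
# results go only to files.

#' Curate a registry file
#'
#' Reads a registry, validates every record, applies the curation funnel,
#' and writes the curated registry plus the funnel report.
#'
#' @param input Path to a registry file.
#' @param out_dir Output directory (created if needed); receives
#'   `curated.<dialect>` and `curation_report.csv`.
#' @param filters Optional path to a filter-spec JSON; defaults to the
#'   packaged default filters.
#' @param dialect Registry dialect of `input` and of the curated output.
#' @return Invisibly, a list with `curated` (the curated tibble) and
#'   `report`.  Validation failures abort with the violations listed.
#' @export
run_curate <- function(input, out_dir, filters = NULL, dialect = c("json", "csv")) {
  dialect <- arg_match(dialect)
  spec <- if (is.null(filters)) filter_spec() else read_filter_spec(filters)
  trials <- read_registry(input, dialect)
  violations <- validate_trials(trials)
  if (nrow(violations) > 0L) {
    abort(paste0(
      "registry failed validation:\n",
      paste(sprintf("  %s [%s/%s]: %s", violations$registry_id, violations$field,
                    violations$rule, violations$message), collapse = "\n")
    ), class = "pdactrials_validation_error")
  }
  curated <- apply_filters(trials, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_registry(as_trials(curated), file.path(out_dir, paste0("curated.", dialect)), dialect)
  write_curation_report(curated, file.path(out_dir, "curation_report.csv"))
  rep <- curation_report(curated)
  message(sprintf("curate: %d records in, %d excluded (%s), %d out",
                  attr(curated, "input_count"), sum(rep$n_excluded),
                  paste(sprintf("%s=%d", rep$rule, rep$n_excluded), collapse = ", "),
                  attr(curated, "output_count")))
  invisible(list(curated = curated, report = rep))
}

#' Tabulate a census facet from a curated registry file
#'
#' @param input Path to a curated registry file.
#' @param facet,denominator,mode,granularity See [tabulate_landscape()].
#' @param out_dir Output directory; receives `landscape_<facet>.csv` and
#'   `landscape_<facet>.md`.
#' @param dialect Registry dialect of `input`.
#' @return Invisibly, the `landscape_table`.
#' @export
run_aggregate <- function(input, facet, out_dir, denominator = NULL,
                          mode = "half_up", granularity = 1,
                          dialect = c("json", "csv")) {
  dialect <- arg_match(dialect)
  facet <- arg_match(facet, .facets)
  trials <- read_registry(input, dialect)
  data <- if (facet %in% c("category", "mechanism")) expand_interventions(trials) else trials
  table <- tabulate_landscape(data, facet, denominator, mode = mode,
                              granularity = granularity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape_csv(table, file.path(out_dir, paste0("landscape_", facet, ".csv")))
  writeLines(format_landscape_md(table),
             file.path(out_dir, paste0("landscape_", facet, ".md")))
  message(sprintf("aggregate: facet=%s denominator=%s total=%d",
                  facet, attr(table, "denominator"), attr(table, "total")))
  invisible(table)
}

#' Score and rank rubric assignments from files
#'
#' @param assignments Path to an assignment CSV (see [read_assignments()]).
#' @param out Path of the scored/ranked output CSV (ordered by rank, with
#'   per-criterion points).
#' @param rubric Optional path to a rubric CSV; defaults to the packaged
#'   rubric.
#' @return Invisibly, the ranked `scored_trials` tibble.
#' @export
run_score <- function(assignments, out, rubric = NULL) {
  rub <- impact_rubric(rubric)
  asn <- read_assignments(assignments)
  ranked <- rank_trials(score_assignments(asn, rub))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(ranked), out)
  message(sprintf("score: %d trials scored; top total %s", nrow(ranked),
                  if (nrow(ranked)) ranked$total[1L] else "NA"))
  invisible(ranked)
}

#' Generate a synthetic registry to files
#'
#' @param out_dir Output directory; receives `registry.json`,
#'   `registry.csv` and `assignments.csv`.
#' @param config Optional path to a generator-config JSON.
#' @param seed Integer seed (overrides the config file's seed).
#' @return Invisibly, the generated trial tibble.
#' @export
run_generate <- function(out_dir, config = NULL, seed = 1L) {
  cfg <- if (is.null(config)) generator_config(seed = seed)
         else read_generator_config(config, seed = seed)
  reg <- generate_registry(cfg)
  asn <- generate_assignments(apply_filters(reg), cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_registry(reg, file.path(out_dir, "registry.json"), "json")
  write_registry(reg, file.path(out_dir, "registry.csv"), "csv")
  readr::write_csv(asn, file.path(out_dir, "assignments.csv"), na = "")
  message(sprintf("generate: %d records (%d decoys), %d late-phase assignments, seed %d",
                  nrow(reg), sum(reg$is_net | !reg$is_therapeutic), nrow(asn), cfg$seed))
  invisible(reg)
}
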