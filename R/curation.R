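#' Build a curation filter specification
#'
#' The defaults re-enact the registry query behind the curated snapshot:
#' phase I-III interventional trials that are recruiting, active but not
#' recruiting, or enrolling by invitation, with pancreatic neuroendocrine
#' tumor (NET) trials and non-therapeutic trials (imaging, detection)
#' excluded.
#'
#' @param allowed_phases Phase tokens retained.
#' @param allowed_statuses Recruitment-status tokens retained.
#' @param study_type Study type retained.
#' @param exclude_net Drop trials flagged `is_net`.
#' @param exclude_non_therapeutic Drop trials flagged `!is_therapeutic`.
#' @return An object of class `filter_spec`.
#' @seealso [apply_filters()], [read_filter_spec()]
#' @export
filter_spec <- function(allowed_phases = .phase_levels,
                        allowed_statuses = c("recruiting", "active_not_recruiting",
                                             "enrolling_by_invitation"),
                        study_type = "interventional",
                        exclude_net = TRUE,
                        exclude_non_therapeutic = TRUE) {
  if (!length(allowed_phases) || !length(allowed_statuses)) {
    abort("allowed_phases and allowed_statuses must be non-empty")
  }
  check_enum(allowed_phases, .phase_levels, "allowed_phases", allowed_phases)
  check_enum(allowed_statuses, .status_levels, "allowed_statuses", allowed_statuses)
  check_enum(study_type, .study_type_levels, "study_type", study_type)
  structure(
    list(allowed_phases = allowed_phases, allowed_statuses = allowed_statuses,
         study_type = study_type, exclude_net = isTRUE(exclude_net),
         exclude_non_therapeutic = isTRUE(exclude_non_therapeutic)),
    class = "filter_spec"
  )
}

#' Read a filter specification from a JSON configuration file
#'
#' @param path Path to a JSON file with keys `allowed_phases`,
#'   `allowed_statuses`, `study_type`, `exclude_net`,
#'   `exclude_non_therapeutic` (all optional; defaults as in
#'   [filter_spec()]).  The packaged default lives at
#'   `system.file("extdata", "filters_default.json", package = "pdactrials")`.
#' @return A `filter_spec` object.
#' @export
read_filter_spec <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- filter_spec()
  filter_spec(
    allowed_phases = cfg$allowed_phases %||% defaults$allowed_phases,
    allowed_statuses = cfg$allowed_statuses %||% defaults$allowed_statuses,
    study_type = cfg$study_type %||% defaults$study_type,
    exclude_net = cfg$exclude_net %||% defaults$exclude_net,
    exclude_non_therapeutic = cfg$exclude_non_therapeutic %||% defaults$exclude_non_therapeutic
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>\n")
  cat("  phases:  ", paste(x$allowed_phases, collapse = ", "), "\n")
  cat("  statuses:", paste(x$allowed_statuses, collapse = ", "), "\n")
  cat("  type:    ", x$study_type, "\n")
  cat("  exclude NET:", x$exclude_net, " exclude non-therapeutic:",
      x$exclude_non_therapeutic, "\n")
  invisible(x)
}

# Fixed attribution order: a record failing several rules is counted under
# the first one, so the funnel report is deterministic.
.filter_rules <- c("status", "study_type", "phase", "net", "non_therapeutic")

#' Apply the curation funnel to a registry
#'
#' Retains exactly the records passing every filter and attributes each
#' exclusion to the first failing rule in the fixed order status, study
#' type, phase, NET focus, non-therapeutic.  The funnel always conserves
#' counts: input = output + sum of exclusions.
#'
#' @param trials A trial-record tibble.
#' @param spec A [filter_spec()].
#' @return The curated tibble (class `curated_trials`) with the funnel
#'   report attached; retrieve it with [curation_report()] or [tidy()],
#'   and the in/out totals with [glance()].
#' @examples
#' reg <- generate_registry(generator_config(seed = 1))
#' curated <- apply_filters(reg, filter_spec())
#' glance(curated)
#' @export
apply_filters <- function(trials, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  trials <- as_tibble(trials)
  n_in <- nrow(trials)
  fail <- rep(NA_character_, n_in)
  mark <- function(fail, bad, rule) if_else(is.na(fail) & bad, rule, fail)
  fail <- mark(fail, !(trials$recruitment_status %in% spec$allowed_statuses), "status")
  fail <- mark(fail, trials$study_type != spec$study_type, "study_type")
  fail <- mark(fail, !(trials$phase %in% spec$allowed_phases), "phase")
  if (spec$exclude_net) fail <- mark(fail, trials$is_net, "net")
  if (spec$exclude_non_therapeutic) fail <- mark(fail, !trials$is_therapeutic, "non_therapeutic")

  kept <- trials[is.na(fail), , drop = FALSE]
  report <- tibble(
    rule = .filter_rules,
    n_excluded = map_int(.filter_rules, function(r) sum(fail == r, na.rm = TRUE))
  )
  structure(kept,
            class = c("curated_trials", class(kept)),
            curation_report = report,
            input_count = n_in,
            output_count = nrow(kept))
}

#' Funnel report of a curated registry
#'
#' @param curated The result of [apply_filters()].
#' @return A tibble with one row per exclusion rule (`rule`, `n_excluded`)
#'   plus attributes carried by the curated object.
#' @export
curation_report <- function(curated) {
  rep <- attr(curated, "curation_report")
  if (is.null(rep)) abort("not a curated registry: run apply_filters() first")
  rep
}

#' @exportS3Method generics::tidy
tidy.curated_trials <- function(x, ...) curation_report(x)

#' @exportS3Method generics::glance
glance.curated_trials <- function(x, ...) {
  tibble(
    input_count = attr(x, "input_count"),
    excluded = sum(curation_report(x)$n_excluded),
    output_count = attr(x, "output_count")
  )
}

#' Write a curation funnel report as CSV
#'
#' @param curated The result of [apply_filters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(curated, path) {
  rep <- curation_report(curated)
  out <- bind_rows(
    tibble(rule = "input", n_excluded = NA_integer_, count = attr(curated, "input_count")),
    mutate(rep, count = NA_integer_),
    tibble(rule = "output", n_excluded = NA_integer_, count = attr(curated, "output_count"))
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Expand multi-arm trials into one record per intervention
#'
#' Trials with multiple arms testing distinct interventions are separated
#' into per-intervention records for the census analyses; each record is
#' tagged with its source `registry_id` and arm index so trial-level
#' structure can be reconstructed exactly.
#'
#' @param trials A trial-record tibble.
#' @return A tibble with one row per intervention: `registry_id`,
#'   `arm_index`, `name`, `category_code`, `mechanism_code`, `is_systemic`.
#' @examples
#' expand_interventions(phase3_trials())
#' @export
expand_interventions <- function(trials) {
  trials <- as_tibble(trials)
  empty <- map_lgl(trials$interventions, function(a) is.null(a) || nrow(a) == 0L)
  if (any(empty)) {
    abort(sprintf("trial %s has no interventions", trials$registry_id[which(empty)[1L]]),
          class = "pdactrials_validation_error")
  }
  if (nrow(trials) == 0L) {
    return(tibble(registry_id = character(), arm_index = integer(),
                  name = character(), category_code = character(),
                  mechanism_code = character(), is_systemic = logical()))
  }
  trials |>
    select("registry_id", "interventions") |>
    mutate(interventions = map(.data$interventions, function(a) {
      mutate(as_arms(a), arm_index = row_number())
    })) |>
    tidyr::unnest("interventions") |>
    mutate(is_systemic = !(.data$category_code %in% .non_systemic_categories)) |>
    select("registry_id", "arm_index", "name", "category_code",
           "mechanism_code", "is_systemic")
}

#' Count late-phase trials by novelty group
#'
#' Phase II/III and III trials carry a curated novelty-group annotation:
#' testing a genuinely novel intervention, manipulating chemotherapeutics
#' already used in PDAC or other cancers, studying a technical treatment
#' strategy, or focusing on pain management.  Groups absent from the data
#' are reported with count 0.
#'
#' @param trials A trial-record tibble.
#' @return A tibble with columns `novelty_group` and `n`, one row per
#'   group in fixed vocabulary order.
#' @examples
#' group_phase3(phase3_trials())
#' @export
group_phase3 <- function(trials) {
  trials <- as_tibble(trials)
  late <- trials[trials$phase %in% .late_phases, , drop = FALSE]
  missing_annot <- is.na(late$novelty_group)
  if (any(missing_annot)) {
    abort(sprintf("phase II/III and III record(s) missing novelty_group: %s",
                  paste(late$registry_id[missing_annot], collapse = ", ")),
          class = "pdactrials_validation_error")
  }
  counts <- table(factor(late$novelty_group, levels = .novelty_levels))
  tibble(novelty_group = .novelty_levels, n = as.integer(counts))
}
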