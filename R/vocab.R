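# Controlled vocabularies for trial records. Combined phases (I/II, II/III)
# are first-class tokens and are never split across two bins.

.phase_levels <- c("I", "I_II", "II", "II_III", "III")
.status_levels <- c(
  "recruiting", "active_not_recruiting", "enrolling_by_invitation",
  "completed", "terminated", "suspended", "withdrawn", "unknown"
)
.study_type_levels <- c("interventional", "observational")
.stage_levels <- c(
  "advanced_metastatic", "localized_resectable", "localized_borderline",
  "localized_unresectable", "localized_any", "unspecified"
)
.line_levels <- c("first", "second_or_later", "unspecified")
.endpoint_levels <- c(
  "survival", "quality_of_life", "pain", "complication", "sequelae",
  "infection"
)
.novelty_levels <- c(
  "novel_intervention", "conventional_manipulation", "technical_procedure",
  "pain_management"
)
.novelty_sub_levels <- c(
  "efficacy_other_cancer", "repurposed_non_cancer", "novel_to_all"
)

# Late-phase bins whose records carry the novelty-group annotation.
.late_phases <- c("II_III", "III")

#' Controlled vocabularies for trial record fields
#'
#' Returns the closed token sets accepted for each enumerated field of a
#' trial record.  Unknown tokens are rejected by [read_registry()] and
#' reported by [validate_trials()]; they are never coerced.
#'
#' @return A named list of character vectors, one per enumerated field:
#'   `phase`, `recruitment_status`, `study_type`, `disease_stage`,
#'   `line_of_therapy`, `endpoint_class`, `novelty_group`,
#'   `novelty_subgroup`.
#' @examples
#' trial_vocabulary()$phase
#' @export
trial_vocabulary <- function() {
  list(
    phase = .phase_levels,
    recruitment_status = .status_levels,
    study_type = .study_type_levels,
    disease_stage = .stage_levels,
    line_of_therapy = .line_levels,
    endpoint_class = .endpoint_levels,
    novelty_group = .novelty_levels,
    novelty_subgroup = .novelty_sub_levels
  )
}

# Abort unless all non-NA values of `x` are in `allowed`; errors name the
# offending field and record ID so bad files are easy to fix.
check_enum <- function(x, allowed, field, ids, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & !(x %in% allowed) else !(x %in% allowed)
  bad[is.na(bad)] <- !allow_na
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(
      "invalid token '%s' in field '%s' for record %s (allowed: %s)",
      as.character(x[i]), field, ids[i] %||% i, paste(allowed, collapse = ", ")
    ), class = "pdactrials_validation_error")
  }
  invisible(x)
}
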