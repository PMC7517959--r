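#' Validate trial records against the type invariants and taxonomies
#'
#' Violations are data, not exceptions: the return value has one row per
#' violated rule, naming the record, field and rule.  An empty result means
#' every record satisfies all invariants:
#'
#' * `registry_id` matches `NCT` + 8 digits and is unique in the registry;
#' * every enumerated field holds a known token;
#' * at least one intervention per trial;
#' * every `category_code` / `mechanism_code` resolves in the shipped
#'   taxonomies;
#' * a systemic intervention carries exactly one mechanism code, and a
#'   non-systemic one (radiation, procedure, pain/QoL) carries none —
#'   the single-mechanism annotation rule;
#' * the novelty-group annotation appears only on phase II/III and III
#'   records.
#'
#' @param trials A trial-record tibble.
#' @param category_taxonomy,mechanism_taxonomy Taxonomy tibbles, defaulting
#'   to the packaged trees.
#' @return A tibble with columns `registry_id`, `field`, `rule`, `message`;
#'   zero rows when all records are valid.
#' @examples
#' validate_trials(phase3_trials())
#' @export
validate_trials <- function(trials,
                            category_taxonomy = trial_taxonomy("category"),
                            mechanism_taxonomy = trial_taxonomy("mechanism")) {
  trials <- as_tibble(trials)
  violations <- list()
  add <- function(id, field, rule, message) {
    violations[[length(violations) + 1L]] <<-
      tibble(registry_id = id, field = field, rule = rule, message = message)
  }
  voc <- trial_vocabulary()

  bad_id <- !grepl("^NCT[0-9]{8}$", trials$registry_id)
  for (i in which(bad_id)) {
    add(trials$registry_id[i], "registry_id", "id_pattern",
        "registry_id must match NCT + 8 digits")
  }
  dup <- duplicated(trials$registry_id)
  for (i in which(dup)) {
    add(trials$registry_id[i], "registry_id", "id_unique",
        "registry_id duplicated within registry")
  }

  enum_fields <- c("study_type", "phase", "recruitment_status",
                   "disease_stage", "line_of_therapy", "endpoint_class")
  for (field in enum_fields) {
    bad <- is.na(trials[[field]]) | !(trials[[field]] %in% voc[[field]])
    for (i in which(bad)) {
      add(trials$registry_id[i], field, "enum",
          sprintf("unknown token '%s'", trials[[field]][i]))
    }
  }
  for (field in c("novelty_group", "novelty_subgroup")) {
    bad <- !is.na(trials[[field]]) & !(trials[[field]] %in% voc[[field]])
    for (i in which(bad)) {
      add(trials$registry_id[i], field, "enum",
          sprintf("unknown token '%s'", trials[[field]][i]))
    }
  }

  late <- trials$phase %in% .late_phases
  stray <- !late & !is.na(trials$novelty_group)
  for (i in which(stray)) {
    add(trials$registry_id[i], "novelty_group", "novelty_phase",
        "novelty_group is a phase II/III and III annotation only")
  }

  for (i in seq_len(nrow(trials))) {
    id <- trials$registry_id[i]
    arms <- trials$interventions[[i]]
    if (is.null(arms) || nrow(arms) == 0L) {
      add(id, "interventions", "nonempty", "trial must have at least one intervention")
      next
    }
    for (j in seq_len(nrow(arms))) {
      cat_code <- arms$category_code[j]
      mech_code <- arms$mechanism_code[j]
      if (is.na(cat_code) || !(cat_code %in% category_taxonomy$code)) {
        add(id, "category_code", "taxonomy",
            sprintf("arm %d: unknown category code '%s'", j, cat_code))
        next
      }
      systemic <- !(cat_code %in% .non_systemic_categories)
      if (systemic && is.na(mech_code)) {
        add(id, "mechanism_code", "systemic_requires_mechanism",
            sprintf("arm %d: systemic intervention requires exactly one mechanism code", j))
      }
      if (!systemic && !is.na(mech_code)) {
        add(id, "mechanism_code", "non_systemic_no_mechanism",
            sprintf("arm %d: %s intervention must not carry a mechanism code", j, cat_code))
      }
      if (!is.na(mech_code) && !(mech_code %in% mechanism_taxonomy$code)) {
        add(id, "mechanism_code", "taxonomy",
            sprintf("arm %d: unknown mechanism code '%s'", j, mech_code))
      }
    }
  }

  if (length(violations) == 0L) {
    tibble(registry_id = character(), field = character(),
           rule = character(), message = character())
  } else {
    bind_rows(violations)
  }
}
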