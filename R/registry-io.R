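# Readers and writers for the two registry dialects.
#
# JSON dialect ("pdac-registry", versioned; schema in
# inst/extdata/registry_schema.json): one object per study, interventions
# nested, optional fields omitted rather than null.
#
# CSV dialect: flat, one row per trial arm with trial-level fields repeated;
# optional fields are empty cells.

.trial_columns <- c(
  "registry_id", "title", "study_type", "phase", "recruitment_status",
  "is_net", "is_therapeutic", "disease_stage", "line_of_therapy",
  "endpoint_class", "novelty_group", "novelty_subgroup"
)
.arm_columns <- c("name", "category_code", "mechanism_code")

# Empty canonical trials tibble (used for zero-record files).
empty_trials <- function() {
  tibble(
    registry_id = character(), title = character(), study_type = character(),
    phase = character(), recruitment_status = character(),
    is_net = logical(), is_therapeutic = logical(),
    disease_stage = character(), line_of_therapy = character(),
    endpoint_class = character(), novelty_group = character(),
    novelty_subgroup = character(), interventions = list()
  )
}

empty_arms <- function() {
  tibble(name = character(), category_code = character(), mechanism_code = character())
}

# Coerce a data frame of arms to the canonical arm tibble.
as_arms <- function(df) {
  df <- as_tibble(df)
  for (col in .arm_columns) if (!col %in% names(df)) df[[col]] <- NA_character_
  df <- df[.arm_columns]
  df$name <- as.character(df$name)
  df$category_code <- as.character(df$category_code)
  df$mechanism_code <- as.character(df$mechanism_code)
  df
}

#' Coerce a data frame to the canonical trial-record tibble
#'
#' Ensures column set, column order and types, including the
#' `interventions` list-column of arm tibbles (`name`, `category_code`,
#' `mechanism_code`).  Enum fields are checked against
#' [trial_vocabulary()]; unknown tokens abort with the field and record
#' named.
#'
#' @param x A data frame with the trial-record columns; `interventions`
#'   may be a list of data frames.
#' @return A tibble with one row per trial.
#' @export
as_trials <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(setdiff(.trial_columns, c("novelty_group", "novelty_subgroup")), names(x))
  if (length(missing_cols)) {
    abort(paste0("missing trial columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"novelty_group" %in% names(x)) x$novelty_group <- NA_character_
  if (!"novelty_subgroup" %in% names(x)) x$novelty_subgroup <- NA_character_
  if (!"interventions" %in% names(x)) {
    abort("missing 'interventions' list-column")
  }
  x <- x[c(.trial_columns, "interventions")]
  for (col in setdiff(.trial_columns, c("is_net", "is_therapeutic"))) {
    x[[col]] <- as.character(x[[col]])
  }
  x$is_net <- as.logical(x$is_net)
  x$is_therapeutic <- as.logical(x$is_therapeutic)
  x$interventions <- map(x$interventions, as_arms)
  check_trial_enums(x)
  x
}

check_trial_enums <- function(trials) {
  voc <- trial_vocabulary()
  ids <- trials$registry_id
  check_enum(trials$study_type, voc$study_type, "study_type", ids)
  check_enum(trials$phase, voc$phase, "phase", ids)
  check_enum(trials$recruitment_status, voc$recruitment_status, "recruitment_status", ids)
  check_enum(trials$disease_stage, voc$disease_stage, "disease_stage", ids)
  check_enum(trials$line_of_therapy, voc$line_of_therapy, "line_of_therapy", ids)
  check_enum(trials$endpoint_class, voc$endpoint_class, "endpoint_class", ids)
  check_enum(trials$novelty_group, voc$novelty_group, "novelty_group", ids, allow_na = TRUE)
  check_enum(trials$novelty_subgroup, voc$novelty_subgroup, "novelty_subgroup", ids, allow_na = TRUE)
  invisible(trials)
}

#' Read a registry snapshot
#'
#' Reads trial records from the JSON dialect (nested interventions) or the
#' flat CSV dialect (one row per arm, trial fields repeated).  All enum
#' fields are validated against [trial_vocabulary()]; unknown tokens are
#' rejected with an error naming the field and record, never coerced.
#'
#' @param path Path to the registry file.
#' @param dialect `"json"` or `"csv"`.
#' @return A tibble of trial records with an `interventions` list-column.
#' @seealso [write_registry()], [validate_trials()]
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_registry(phase3_trials(), f)
#' nrow(read_registry(f))
#' @export
read_registry <- function(path, dialect = c("json", "csv")) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  if (dialect == "json") read_registry_json(path) else read_registry_csv(path)
}

read_registry_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("malformed JSON registry '%s': %s", path, conditionMessage(e)))
  )
  if (!is.list(doc) || is.null(doc$trials)) {
    abort(sprintf("malformed registry '%s': missing top-level 'trials' array", path))
  }
  if (length(doc$trials) == 0L) return(empty_trials())
  get_chr <- function(rec, field, i, required = TRUE) {
    v <- rec[[field]]
    if (is.null(v)) {
      if (required) abort(sprintf("record %d ('%s'): missing field '%s'",
                                  i, rec$registry_id %||% "?", field))
      return(NA_character_)
    }
    as.character(v)
  }
  rows <- imap(doc$trials, function(rec, i) {
    arms <- rec$interventions
    if (is.null(arms) || length(arms) == 0L) {
      arms_tbl <- empty_arms()
    } else {
      arms_tbl <- tibble(
        name = map_chr(arms, function(a) as.character(a$name %||% NA_character_)),
        category_code = map_chr(arms, function(a) as.character(a$category_code %||% NA_character_)),
        mechanism_code = map_chr(arms, function(a) as.character(a$mechanism_code %||% NA_character_))
      )
    }
    tibble(
      registry_id = get_chr(rec, "registry_id", i),
      title = get_chr(rec, "title", i),
      study_type = get_chr(rec, "study_type", i),
      phase = get_chr(rec, "phase", i),
      recruitment_status = get_chr(rec, "recruitment_status", i),
      is_net = as.logical(rec$is_net %||% NA),
      is_therapeutic = as.logical(rec$is_therapeutic %||% NA),
      disease_stage = get_chr(rec, "disease_stage", i),
      line_of_therapy = get_chr(rec, "line_of_therapy", i),
      endpoint_class = get_chr(rec, "endpoint_class", i),
      novelty_group = get_chr(rec, "novelty_group", i, required = FALSE),
      novelty_subgroup = get_chr(rec, "novelty_subgroup", i, required = FALSE),
      interventions = list(arms_tbl)
    )
  })
  as_trials(bind_rows(rows))
}

read_registry_csv <- function(path) {
  flat <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      is_net = readr::col_logical(),
      is_therapeutic = readr::col_logical(),
      .default = readr::col_character()
    ), progress = FALSE),
    error = function(e) abort(sprintf("malformed CSV registry '%s': %s", path, conditionMessage(e)))
  )
  problems <- readr::problems(flat)
  if (nrow(problems)) {
    abort(sprintf("malformed CSV registry '%s': parse problem at line %d",
                  path, problems$row[1L]))
  }
  needed <- c(setdiff(.trial_columns, c("novelty_group", "novelty_subgroup")),
              "arm_name", "category_code")
  missing_cols <- setdiff(needed, names(flat))
  if (length(missing_cols)) {
    abort(sprintf("malformed CSV registry '%s': missing columns %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(flat) == 0L) return(empty_trials())
  if (!"novelty_group" %in% names(flat)) flat$novelty_group <- NA_character_
  if (!"novelty_subgroup" %in% names(flat)) flat$novelty_subgroup <- NA_character_
  if (!"mechanism_code" %in% names(flat)) flat$mechanism_code <- NA_character_
  nested <- flat |>
    mutate(.order = row_number()) |>
    tidyr::nest(interventions = c("arm_name", "category_code", "mechanism_code", ".order")) |>
    mutate(interventions = map(.data$interventions, function(a) {
      a <- arrange(a, .data$.order)
      tibble(name = a$arm_name, category_code = a$category_code,
             mechanism_code = a$mechanism_code)
    }))
  as_trials(nested)
}

#' Write a registry snapshot
#'
#' Writes trial records in either dialect so that [read_registry()]
#' recovers them with full fidelity (round-trip identity, including the
#' absence of optional fields).
#'
#' @param trials A trial-record tibble as returned by [read_registry()] or
#'   [as_trials()].
#' @param path Output file path.
#' @param dialect `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(trials, path, dialect = c("json", "csv")) {
  dialect <- arg_match(dialect)
  trials <- as_trials(trials)
  if (dialect == "json") {
    recs <- pmap(trials, function(...) {
      row <- list(...)
      arms <- as_arms(row$interventions)
      rec <- list(
        registry_id = row$registry_id, title = row$title,
        study_type = row$study_type, phase = row$phase,
        recruitment_status = row$recruitment_status,
        is_net = row$is_net, is_therapeutic = row$is_therapeutic,
        disease_stage = row$disease_stage,
        line_of_therapy = row$line_of_therapy,
        endpoint_class = row$endpoint_class
      )
      if (!is.na(row$novelty_group)) rec$novelty_group <- row$novelty_group
      if (!is.na(row$novelty_subgroup)) rec$novelty_subgroup <- row$novelty_subgroup
      rec$interventions <- pmap(arms, function(name, category_code, mechanism_code) {
        a <- list(name = name, category_code = category_code)
        if (!is.na(mechanism_code)) a$mechanism_code <- mechanism_code
        a
      })
      rec
    })
    doc <- list(dialect = "pdac-registry", version = "1.0", trials = recs)
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, na = "null"), path)
  } else {
    flat <- if (nrow(trials) == 0L) {
      tibble(!!!setNames(rep(list(character()), length(.trial_columns)), .trial_columns),
             arm_name = character(), category_code = character(),
             mechanism_code = character())
    } else {
      trials |>
        mutate(interventions = map(.data$interventions, function(a) {
          rename(as_arms(a), arm_name = "name")
        })) |>
        tidyr::unnest("interventions")
    }
    readr::write_csv(flat, path, na = "")
  }
  invisible(path)
}
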