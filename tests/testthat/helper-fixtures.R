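# Fixture builders shared across the suite. Everything is constructed in
# code; no binary fixtures.

# A minimal valid trial record as a one-row tibble.
make_trial <- function(registry_id = "NCT00000001",
                       phase = "I",
                       recruitment_status = "recruiting",
                       study_type = "interventional",
                       is_net = FALSE,
                       is_therapeutic = TRUE,
                       disease_stage = "advanced_metastatic",
                       line_of_therapy = "first",
                       endpoint_class = "survival",
                       novelty_group = NA_character_,
                       novelty_subgroup = NA_character_,
                       arms = list(tibble::tibble(
                         name = "Arm 1",
                         category_code = "small_molecule",
                         mechanism_code = "checkpoint"
                       ))) {
  as_trials(tibble::tibble(
    registry_id = registry_id, title = paste("Trial", registry_id),
    study_type = study_type, phase = phase,
    recruitment_status = recruitment_status,
    is_net = is_net, is_therapeutic = is_therapeutic,
    disease_stage = disease_stage, line_of_therapy = line_of_therapy,
    endpoint_class = endpoint_class, novelty_group = novelty_group,
    novelty_subgroup = novelty_subgroup, interventions = arms
  ))
}

# Two hand-built records (one phase I, one phase III) written as raw JSON,
# used to pin the JSON dialect field-by-field.
two_record_json <- function(path) {
  writeLines('{
  "dialect": "pdac-registry",
  "version": "1.0",
  "trials": [
    {
      "registry_id": "NCT01111111",
      "title": "Phase I checkpoint study",
      "study_type": "interventional",
      "phase": "I",
      "recruitment_status": "recruiting",
      "is_net": false,
      "is_therapeutic": true,
      "disease_stage": "advanced_metastatic",
      "line_of_therapy": "second_or_later",
      "endpoint_class": "survival",
      "interventions": [
        {"name": "Anti-PD-1 antibody", "category_code": "monoclonal_antibody",
         "mechanism_code": "checkpoint"}
      ]
    },
    {
      "registry_id": "NCT02222222",
      "title": "Phase III chemo comparison",
      "study_type": "interventional",
      "phase": "III",
      "recruitment_status": "active_not_recruiting",
      "is_net": false,
      "is_therapeutic": true,
      "disease_stage": "localized_resectable",
      "line_of_therapy": "first",
      "endpoint_class": "survival",
      "novelty_group": "conventional_manipulation",
      "interventions": [
        {"name": "FOLFIRINOX", "category_code": "pdac_combination_or_delivery",
         "mechanism_code": "dna_cell_cycle"},
        {"name": "Radiation boost", "category_code": "radiation"}
      ]
    }
  ]
}', path)
  path
}

# Independent scoring oracle: all 5,832 level combinations of the rubric
# (4*3*3*3*3*3*3*2) with totals computed by direct point addition from the
# rubric table, bypassing score_assignments().
rubric_grid <- function(rubric = impact_rubric()) {
  criteria <- c("novelty", "promise", "allocation", "pfs", "os",
                "susceptibility", "impact", "status")
  levels <- lapply(criteria, function(cr) rubric$level[rubric$criterion == cr])
  names(levels) <- criteria
  grid <- expand.grid(levels, stringsAsFactors = FALSE)
  pts <- mapply(function(cr, lev) {
    rubric$points[rubric$criterion == cr][match(lev, rubric$level[rubric$criterion == cr])]
  }, criteria, grid[criteria], SIMPLIFY = TRUE)
  grid$total <- as.integer(rowSums(pts))
  grid
}

# Random level assignments (uniform over levels) for property tests.
random_assignments <- function(n, seed, rubric = impact_rubric()) {
  criteria <- c("novelty", "promise", "allocation", "pfs", "os",
                "susceptibility", "impact", "status")
  withr::with_seed(seed, {
    out <- tibble::tibble(registry_id = sprintf("NCT%08d", seq_len(n)))
    for (cr in criteria) {
      out[[cr]] <- sample(rubric$level[rubric$criterion == cr], n, replace = TRUE)
    }
    out
  })
}

# Brute-force largest-remainder oracle: enumerate every way of granting the
# required increments one-per-cell and keep the allocations with minimal
# total deviation from the exact percentages.
lr_oracle <- function(counts, denominator, granularity, target_total) {
  exact <- 100 * counts / denominator
  floors <- floor(round(exact / granularity, 9)) * granularity
  k <- as.integer(round((target_total - sum(floors)) / granularity))
  stopifnot(k >= 0, k <= length(counts))
  if (k == 0) return(list(floors))
  combos <- utils::combn(length(counts), k, simplify = FALSE)
  allocs <- lapply(combos, function(idx) {
    out <- floors
    out[idx] <- out[idx] + granularity
    out
  })
  dev <- vapply(allocs, function(a) sum(abs(a - exact)), numeric(1))
  allocs[abs(dev - min(dev)) < 1e-9]
}
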