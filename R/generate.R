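# Seeded synthetic registry generator.
#
# Quota (exact-count) sampling, not multinomial: each facet's marginal
# counts are hit exactly for every seed, so census tests are exact rather
# than statistical. Joint structure across facets is independent-by-shuffle
# (the census publishes only marginals, so no correlation is modeled).

.default_assignment_probs <- list(
  novelty = c(novel_mechanism_pdac = 0.30, novel_drug_or_indication_pdac = 0.25,
              beyond_standard_of_care = 0.30, established = 0.15),
  promise = c(phase3_success_other = 0.15, untested_or_under_investigation = 0.75,
              any_phase_failure_other = 0.10),
  allocation = c(randomized = 0.50, not_applicable = 0.20, non_randomized = 0.30),
  pfs = c(gt6mo = 0.15, one_to_6mo = 0.35, lt1mo = 0.50),
  os = c(gt6mo = 0.15, one_to_6mo = 0.35, lt1mo = 0.50),
  susceptibility = c(gt30pct = 0.50, pct5_to_30 = 0.30, lt5pct = 0.20),
  impact = c(direct_treat = 0.70, procedural_or_sequencing = 0.20,
             symptoms_or_sequelae = 0.10),
  status = c(active = 0.95, terminated_and_published = 0.05)
)

#' Configure the synthetic registry generator
#'
#' Defaults are the [census_quotas()] of the curated snapshot (430 trials,
#' 590 interventions across 11 leaf categories, 515 systemic therapies
#' across 22 leaf mechanisms) plus 41 pancreatic-NET and 10
#' non-therapeutic decoys, so `apply_filters()` on a default registry
#' removes exactly the 51 decoys.
#'
#' @param n_trials Number of curated (post-filter) trials.
#' @param phase_quota,stage_quota,line_quota Named integer vectors over the
#'   respective vocabularies, each summing to `n_trials`.
#' @param category_quota Named integer vector over leaf therapeutic
#'   categories; its sum is the interventions total.
#' @param mechanism_quota Named integer vector over leaf mechanisms; must
#'   sum to the systemic interventions implied by `category_quota`.
#' @param novelty_quota Named integer vector over novelty groups, summing
#'   to the phase II/III + III count.
#' @param n_net_decoys,n_nontherapeutic_decoys Decoy counts.
#' @param assignment_probs Named list of per-criterion level probabilities
#'   used by [generate_assignments()].
#' @param seed Integer seed; fixes registry IDs, joint assignments and
#'   rubric draws.
#' @return A `generator_config` object (validated; inconsistent quotas
#'   abort before any generation).
#' @examples
#' generator_config(seed = 42)
#' @export
generator_config <- function(n_trials = 430L,
                             phase_quota = census_quotas()$phase,
                             stage_quota = census_quotas()$stage,
                             line_quota = census_quotas()$line,
                             category_quota = census_quotas()$category,
                             mechanism_quota = census_quotas()$mechanism,
                             novelty_quota = NULL,
                             n_net_decoys = 41L,
                             n_nontherapeutic_decoys = 10L,
                             assignment_probs = .default_assignment_probs,
                             seed = 1L) {
  check_quota <- function(q, allowed, what, total = NULL) {
    if (is.null(names(q)) || !all(names(q) %in% allowed)) {
      abort(sprintf("%s quota has unknown names", what))
    }
    if (any(q < 0) || any(q != round(q))) {
      abort(sprintf("%s quota must be non-negative integers", what))
    }
    if (!is.null(total) && sum(q) != total) {
      abort(sprintf("%s quota sums to %d, expected %d", what, sum(q), total))
    }
    setNames(as.integer(q), names(q))
  }
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) abort("n_trials must be positive")
  phase_quota <- check_quota(phase_quota, .phase_levels, "phase", n_trials)
  stage_quota <- check_quota(stage_quota, .stage_levels, "stage", n_trials)
  line_quota <- check_quota(line_quota, .line_levels, "line", n_trials)

  cat_tax <- trial_taxonomy("category")
  mech_tax <- trial_taxonomy("mechanism")
  category_quota <- check_quota(category_quota, taxonomy_leaves(cat_tax), "category")
  n_interventions <- sum(category_quota)
  if (n_interventions < n_trials || n_interventions > 3L * n_trials) {
    abort(sprintf(
      "category quota implies %d interventions for %d trials; arm counts must stay in 1..3",
      n_interventions, n_trials))
  }
  n_systemic <- sum(category_quota[!(names(category_quota) %in% .non_systemic_categories)])
  mechanism_quota <- check_quota(mechanism_quota, taxonomy_leaves(mech_tax),
                                 "mechanism", n_systemic)

  n_late <- sum(phase_quota[names(phase_quota) %in% .late_phases])
  novelty_quota <- novelty_quota %||% default_novelty_quota(n_late)
  novelty_quota <- check_quota(novelty_quota, .novelty_levels, "novelty", n_late)

  stopifnot(is.list(assignment_probs),
            all(.criteria %in% names(assignment_probs)))
  structure(
    list(n_trials = n_trials, phase_quota = phase_quota,
         stage_quota = stage_quota, line_quota = line_quota,
         category_quota = category_quota, mechanism_quota = mechanism_quota,
         novelty_quota = novelty_quota,
         n_net_decoys = as.integer(n_net_decoys),
         n_nontherapeutic_decoys = as.integer(n_nontherapeutic_decoys),
         assignment_probs = assignment_probs,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Scale the census novelty proportions (14/13/7/3 of 37) to n_late trials
# with largest-remainder apportionment so the quota is exact.
default_novelty_quota <- function(n_late) {
  base <- census_quotas()$novelty
  if (n_late == sum(base)) return(base)
  if (n_late == 0L) return(setNames(rep(0L, length(base)), names(base)))
  exact <- n_late * base / sum(base)
  floors <- floor(exact)
  extra <- n_late - sum(floors)
  grant <- head(order(exact - floors, decreasing = TRUE), extra)
  floors[grant] <- floors[grant] + 1
  setNames(as.integer(floors), names(base))
}

#' Read a generator configuration from a JSON file
#'
#' @param path Path to a JSON file whose keys mirror the
#'   [generator_config()] arguments (all optional).
#' @param seed Seed overriding any seed in the file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path, seed = NULL) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  to_quota <- function(x) if (is.null(x)) NULL else unlist(x)
  generator_config(
    n_trials = cfg$n_trials %||% 430L,
    phase_quota = to_quota(cfg$phase_quota) %||% census_quotas()$phase,
    stage_quota = to_quota(cfg$stage_quota) %||% census_quotas()$stage,
    line_quota = to_quota(cfg$line_quota) %||% census_quotas()$line,
    category_quota = to_quota(cfg$category_quota) %||% census_quotas()$category,
    mechanism_quota = to_quota(cfg$mechanism_quota) %||% census_quotas()$mechanism,
    novelty_quota = to_quota(cfg$novelty_quota),
    n_net_decoys = cfg$n_net_decoys %||% 41L,
    n_nontherapeutic_decoys = cfg$n_nontherapeutic_decoys %||% 10L,
    seed = seed %||% cfg$seed %||% 1L
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d trials + %d NET / %d non-therapeutic decoys, %d interventions, seed %d\n",
              x$n_trials, x$n_net_decoys, x$n_nontherapeutic_decoys,
              sum(x$category_quota), x$seed))
  invisible(x)
}

#' Generate a synthetic registry snapshot
#'
#' Produces trial records hitting every configured facet quota exactly
#' (quota sampling with seeded shuffling for the joint assignment), with
#' unique pattern-valid registry IDs, arm counts allocated so that
#' expanding the curated trials yields exactly the configured
#' interventions total, and the configured number of NET and
#' non-therapeutic decoys (flagged via `is_net` / `is_therapeutic`).
#' Identical seeds give identical registries; different seeds give the
#' same marginals with different joint assignments and IDs.
#'
#' @param config A [generator_config()].
#' @return A trial-record tibble of `n_trials` curated records plus the
#'   decoys; every record passes [validate_trials()].
#' @examples
#' reg <- generate_registry(generator_config(seed = 7))
#' nrow(apply_filters(reg))
#' @export
generate_registry <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cat_tax <- trial_taxonomy("category")
  n <- config$n_trials
  n_decoy <- config$n_net_decoys + config$n_nontherapeutic_decoys
  n_all <- n + n_decoy

  withr::with_seed(config$seed, {
    id_start <- (config$seed %% (99999999L - n_all)) + 1L
    ids <- sprintf("NCT%08d", id_start + seq_len(n_all) - 1L)

    phase <- sample(rep(names(config$phase_quota), config$phase_quota))
    stage <- sample(rep(names(config$stage_quota), config$stage_quota))
    line <- sample(rep(names(config$line_quota), config$line_quota))
    status <- sample(c("recruiting", "active_not_recruiting", "enrolling_by_invitation"),
                     n, replace = TRUE, prob = c(0.6, 0.3, 0.1))

    novelty <- rep(NA_character_, n)
    late <- which(phase %in% .late_phases)
    novelty[late] <- sample(rep(names(config$novelty_quota), config$novelty_quota))

    # Arm counts: everyone gets one arm; extras go one at a time to the
    # lexicographically first trials (so counts stay within 1..3).
    n_interventions <- sum(config$category_quota)
    arm_counts <- rep(1L, n)
    extra <- n_interventions - n
    if (extra > 0L) {
      arm_counts[seq_len(min(extra, n))] <- arm_counts[seq_len(min(extra, n))] + 1L
      if (extra > n) arm_counts[seq_len(extra - n)] <- arm_counts[seq_len(extra - n)] + 1L
    }

    categories <- sample(rep(names(config$category_quota), config$category_quota))
    systemic <- !(categories %in% .non_systemic_categories)
    mechanisms <- rep(NA_character_, n_interventions)
    mechanisms[systemic] <- sample(rep(names(config$mechanism_quota), config$mechanism_quota))

    arm_end <- cumsum(arm_counts)
    arm_start <- arm_end - arm_counts + 1L
    cat_labels <- setNames(cat_tax$label, cat_tax$code)
    interventions <- map2(arm_start, arm_end, function(a, b) {
      idx <- seq(a, b)
      tibble(
        name = sprintf("%s arm %d", cat_labels[categories[idx]], seq_along(idx)),
        category_code = categories[idx],
        mechanism_code = mechanisms[idx]
      )
    })

    real <- tibble(
      registry_id = ids[seq_len(n)],
      title = sprintf("Synthetic PDAC interventional trial %s", ids[seq_len(n)]),
      study_type = "interventional",
      phase = phase,
      recruitment_status = status,
      is_net = FALSE,
      is_therapeutic = TRUE,
      disease_stage = stage,
      line_of_therapy = line,
      endpoint_class = "survival",
      novelty_group = novelty,
      novelty_subgroup = NA_character_,
      interventions = interventions
    )

    decoys <- if (n_decoy > 0L) {
      is_net <- c(rep(TRUE, config$n_net_decoys), rep(FALSE, config$n_nontherapeutic_decoys))
      tibble(
        registry_id = ids[n + seq_len(n_decoy)],
        title = if_else(is_net,
                        sprintf("Synthetic pancreatic NET trial %s", ids[n + seq_len(n_decoy)]),
                        sprintf("Synthetic non-therapeutic study %s", ids[n + seq_len(n_decoy)])),
        study_type = "interventional",
        phase = "II",
        recruitment_status = "recruiting",
        is_net = is_net,
        is_therapeutic = is_net,   # NET decoys are therapeutic; the others are not
        disease_stage = "unspecified",
        line_of_therapy = "unspecified",
        endpoint_class = "survival",
        novelty_group = NA_character_,
        novelty_subgroup = NA_character_,
        interventions = map(seq_len(n_decoy), function(i) {
          tibble(name = "Decoy arm 1", category_code = "small_molecule",
                 mechanism_code = "dna_cell_cycle")
        })
      )
    } else {
      empty_trials()
    }

    as_trials(bind_rows(real, decoys))
  })
}

#' Generate rubric assignments for late-phase records
#'
#' Draws one assignment per phase II/III and III curated record, with
#' criterion levels sampled from the configured categorical distributions
#' and raw survival deltas / susceptible fractions drawn consistently with
#' their binned level (unreported deltas stay `NA` and bin to the bottom
#' level).  Seeded and deterministic.
#'
#' @param trials A trial-record tibble (typically from
#'   [generate_registry()] after [apply_filters()]; decoys are skipped).
#' @param config The [generator_config()] holding `assignment_probs` and
#'   the seed.
#' @return An assignment tibble suitable for [score_assignments()].
#' @examples
#' cfg <- generator_config(seed = 3)
#' reg <- apply_filters(generate_registry(cfg))
#' asn <- generate_assignments(reg, cfg)
#' range(score_assignments(asn)$total)
#' @export
generate_assignments <- function(trials, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  trials <- as_tibble(trials)
  late <- filter(trials, .data$phase %in% .late_phases,
                 .data$is_therapeutic, !.data$is_net)
  n <- nrow(late)
  probs <- config$assignment_probs
  withr::with_seed((config$seed %% 2000000000L) + 1L, {
    draw <- function(crit) {
      p <- probs[[crit]]
      if (n == 0L) return(character())
      sample(names(p), n, replace = TRUE, prob = p)
    }
    asn <- tibble(
      registry_id = late$registry_id,
      novelty = draw("novelty"), promise = draw("promise"),
      allocation = draw("allocation"), pfs = draw("pfs"), os = draw("os"),
      susceptibility = draw("susceptibility"), impact = draw("impact"),
      status = draw("status")
    )
    delta_for <- function(level) {
      dplyr::case_when(
        level == "gt6mo" ~ stats::runif(n, 6.5, 12),
        level == "one_to_6mo" ~ stats::runif(n, 1, 6),
        TRUE ~ NA_real_
      )
    }
    asn$pfs_delta <- delta_for(asn$pfs)
    asn$os_delta <- delta_for(asn$os)
    asn$susceptible_fraction <- dplyr::case_when(
      asn$susceptibility == "gt30pct" ~ stats::runif(n, 0.31, 1),
      asn$susceptibility == "pct5_to_30" ~ stats::runif(n, 0.05, 0.30),
      TRUE ~ stats::runif(n, 0.005, 0.049)
    )
    asn
  })
}
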