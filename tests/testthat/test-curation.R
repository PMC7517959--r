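test_that("the curation funnel reproduces the snapshot counts", {
  reg <- generate_registry(generator_config(seed = 2))
  expect_equal(nrow(reg), 481L)
  curated <- apply_filters(reg)
  expect_equal(nrow(curated), 430L)
  rep <- curation_report(curated)
  expect_equal(rep$n_excluded[rep$rule == "net"], 41L)
  expect_equal(rep$n_excluded[rep$rule == "non_therapeutic"], 10L)
})

test_that("exclusions are attributed to the first failing rule in fixed order", {
  done <- make_trial("NCT00000001", recruitment_status = "completed")
  obs <- make_trial("NCT00000002", study_type = "observational")
  # fails both status and NET: must be counted under status
  both <- make_trial("NCT00000003", recruitment_status = "terminated", is_net = TRUE)
  net <- make_trial("NCT00000004", is_net = TRUE)
  ok <- make_trial("NCT00000005")
  curated <- apply_filters(dplyr::bind_rows(done, obs, both, net, ok))
  rep <- curation_report(curated)
  expect_equal(rep$n_excluded, c(2L, 1L, 0L, 1L, 0L))
  expect_equal(curated$registry_id, "NCT00000005")
})

test_that("empty input curates to empty output with a zero report", {
  curated <- apply_filters(phase3_trials()[0, ])
  expect_equal(nrow(curated), 0L)
  expect_true(all(curation_report(curated)$n_excluded == 0L))
  expect_equal(glance(curated)$input_count, 0L)
})

test_that("funnel conserves counts and is idempotent across random registries", {
  for (seed in c(3, 17, 202)) {
    reg <- generate_registry(generator_config(seed = seed))
    # randomize some statuses so the status rule fires too
    reg2 <- reg
    withr::with_seed(seed, {
      flip <- sample(nrow(reg2), 40)
      reg2$recruitment_status[flip] <- sample(
        c("completed", "terminated", "withdrawn"), 40, replace = TRUE)
    })
    curated <- apply_filters(reg2)
    expect_equal(attr(curated, "input_count"),
                 nrow(curated) + sum(curation_report(curated)$n_excluded))
    again <- apply_filters(tibble::as_tibble(curated))
    expect_equal(as.data.frame(again), as.data.frame(curated), ignore_attr = TRUE)
    expect_true(all(curation_report(again)$n_excluded == 0L))
  }
})

test_that("intervention expansion conserves per-trial arm structure", {
  reg <- apply_filters(generate_registry(generator_config(seed = 4)))
  iv <- expand_interventions(reg)
  expect_equal(nrow(iv), sum(vapply(reg$interventions, nrow, integer(1))))
  regrouped <- dplyr::count(iv, registry_id)
  arm_counts <- tibble::tibble(
    registry_id = reg$registry_id,
    n = vapply(reg$interventions, nrow, integer(1))
  )
  expect_equal(dplyr::arrange(regrouped, registry_id),
               dplyr::arrange(arm_counts, registry_id))
  # single-arm trial expands to exactly one record
  expect_equal(nrow(expand_interventions(make_trial())), 1L)
  # two novel agents as separate arms expand to two records
  two_arm <- make_trial(arms = list(tibble::tibble(
    name = c("Agent A", "Agent B"),
    category_code = c("small_molecule", "monoclonal_antibody"),
    mechanism_code = c("pi3k_akt_mtor", "checkpoint")
  )))
  expect_equal(nrow(expand_interventions(two_arm)), 2L)
  # zero-arm trials are a validation error
  bad <- make_trial()
  bad$interventions[[1]] <- bad$interventions[[1]][0, ]
  expect_error(expand_interventions(bad), "no interventions")
})

test_that("phase III novelty grouping counts all four groups with zeros", {
  counts <- group_phase3(phase3_trials())
  expect_equal(counts$n[match(c("novel_intervention", "conventional_manipulation",
                                "technical_procedure", "pain_management"),
                              counts$novelty_group)],
               c(14L, 13L, 7L, 3L))
  expect_equal(group_phase3(phase3_trials()[0, ])$n, rep(0L, 4))
  pains <- dplyr::bind_rows(
    make_trial("NCT00000001", phase = "III", novelty_group = "pain_management"),
    make_trial("NCT00000002", phase = "III", novelty_group = "pain_management"),
    make_trial("NCT00000003", phase = "II_III", novelty_group = "pain_management")
  )
  counts <- group_phase3(pains)
  expect_equal(counts$n[counts$novelty_group == "pain_management"], 3L)
  expect_equal(sum(counts$n), 3L)
  # missing annotation on an eligible record is an error naming the record
  un <- make_trial("NCT09999999", phase = "III")
  expect_error(group_phase3(un), "NCT09999999")
})
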