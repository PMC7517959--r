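test_that("generated registries hit every configured quota exactly", {
  for (seed in c(1, 77)) {
    cfg <- generator_config(seed = seed)
    curated <- apply_filters(generate_registry(cfg))
    expect_equal(nrow(curated), cfg$n_trials)
    for (facet in c("phase", "stage", "line")) {
      tab <- tabulate_landscape(curated, facet)
      quota <- cfg[[paste0(facet, "_quota")]]
      # compare at the leaf rows of the facet (quota names)
      expect_equal(setNames(tab$count[match(names(quota), tab$code)], names(quota)),
                   quota, info = paste(facet, seed))
    }
    iv <- expand_interventions(curated)
    cat_tab <- tabulate_landscape(iv, "category")
    expect_equal(cat_tab$count[match(names(cfg$category_quota), cat_tab$code)],
                 unname(cfg$category_quota))
    mech_tab <- tabulate_landscape(iv, "mechanism")
    expect_equal(mech_tab$count[match(names(cfg$mechanism_quota), mech_tab$code)],
                 unname(cfg$mechanism_quota))
  }
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_registry(generator_config(seed = 10))
  b <- generate_registry(generator_config(seed = 10))
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_registry(a, f1, "json"); write_registry(b, f2, "json")
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output

  c_reg <- generate_registry(generator_config(seed = 11))
  expect_false(identical(a$registry_id, c_reg$registry_id))
  # same marginals regardless of seed
  expect_equal(table(a$phase), table(c_reg$phase))
})

test_that("a singleton config generates exactly one quota-carrying record", {
  cfg <- generator_config(
    n_trials = 1, phase_quota = c(III = 1),
    stage_quota = c(advanced_metastatic = 1), line_quota = c(first = 1),
    category_quota = c(small_molecule = 1), mechanism_quota = c(checkpoint = 1),
    n_net_decoys = 0, n_nontherapeutic_decoys = 0, seed = 8)
  reg <- generate_registry(cfg)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$phase, "III")
  expect_equal(reg$disease_stage, "advanced_metastatic")
  expect_false(is.na(reg$novelty_group))
  expect_equal(reg$interventions[[1]]$mechanism_code, "checkpoint")
})

test_that("inconsistent quotas abort before generation", {
  expect_error(generator_config(phase_quota = c(I = 100)), "sums to")
  expect_error(generator_config(mechanism_quota = c(checkpoint = 100)), "sums to")
  expect_error(generator_config(category_quota = c(small_molecule = 10),
                                n_trials = 430), "arm counts")
  expect_error(generator_config(phase_quota = c(IX = 430)), "unknown names")
})

test_that("every generated record passes validation", {
  reg <- generate_registry(generator_config(seed = 21))
  expect_equal(nrow(validate_trials(reg)), 0L)
})

test_that("generated assignments respect rubric bounds and level consistency", {
  cfg <- generator_config(seed = 31)
  curated <- apply_filters(generate_registry(cfg))
  asn <- generate_assignments(curated, cfg)
  expect_equal(nrow(asn), sum(curated$phase %in% c("II_III", "III")))
  scored <- score_assignments(asn)   # also checks raw/level consistency
  expect_true(all(scored$total >= -7 & scored$total <= 18))
  # deterministic
  expect_identical(generate_assignments(curated, cfg), asn)
})

test_that("a degenerate all-best distribution scores 18 everywhere", {
  point_mass <- list(
    novelty = c(novel_mechanism_pdac = 1), promise = c(phase3_success_other = 1),
    allocation = c(randomized = 1), pfs = c(gt6mo = 1), os = c(gt6mo = 1),
    susceptibility = c(gt30pct = 1), impact = c(direct_treat = 1),
    status = c(active = 1))
  cfg <- generator_config(seed = 5, assignment_probs = point_mass)
  curated <- apply_filters(generate_registry(cfg))
  scored <- score_assignments(generate_assignments(curated, cfg))
  expect_true(all(scored$total == 18L))
})

test_that("default assignment draws span the printed score range", {
  # 10,000 draws against a fake late-phase roster
  fake <- tibble::tibble(
    registry_id = sprintf("NCT%08d", seq_len(10000)),
    phase = "III", is_therapeutic = TRUE, is_net = FALSE
  )
  asn <- generate_assignments(fake, generator_config(seed = 12))
  totals <- score_assignments(asn)$total
  expect_true(min(totals) <= 0)
  expect_true(max(totals) >= 15)
  expect_true(all(totals >= -7 & totals <= 18))
})
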