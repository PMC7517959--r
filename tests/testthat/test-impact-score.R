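test_that("survival deltas bin on the printed thresholds", {
  expect_equal(bin_survival_delta(8.2), "gt6mo")    # 14.9 vs 6.7 months OS
  expect_equal(bin_survival_delta(4.6), "one_to_6mo") # 8.3 vs 3.7 months PFS
  expect_equal(bin_survival_delta(0.4), "lt1mo")
  expect_equal(bin_survival_delta(6.0), "one_to_6mo") # "> 6" is strict
  expect_equal(bin_survival_delta(1.0), "one_to_6mo") # range closed at 1
  expect_equal(bin_survival_delta(-2), "lt1mo")       # worse than control
  expect_equal(bin_survival_delta(NA, reported = FALSE), "lt1mo")
  expect_error(bin_survival_delta(NaN, reported = TRUE), "finite")
})

test_that("susceptible fractions bin on the printed thresholds", {
  expect_equal(bin_susceptibility(0.9), "gt30pct")
  expect_equal(bin_susceptibility(0.02), "lt5pct")
  expect_equal(bin_susceptibility(0.30), "pct5_to_30")  # "> 30%" is strict
  expect_equal(bin_susceptibility(0.05), "pct5_to_30")  # range closed at 5%
  expect_error(bin_susceptibility(0), "\\(0, 1\\]")
  expect_error(bin_susceptibility(1.2), "\\(0, 1\\]")
})

test_that("the published worked examples score 15 and 13", {
  panova <- tibble::tibble(
    registry_id = "NCT03377491",
    novelty = "novel_mechanism_pdac", promise = "phase3_success_other",
    allocation = "non_randomized",
    pfs = bin_survival_delta(8.3 - 3.7), os = bin_survival_delta(14.9 - 6.7),
    susceptibility = "gt30pct", impact = "direct_treat", status = "active"
  )
  expect_equal(score_assignments(panova)$total, 15L)

  avenger <- tibble::tibble(
    registry_id = "NCT03504423",
    novelty = "novel_mechanism_pdac", promise = "untested_or_under_investigation",
    allocation = "non_randomized",
    pfs = "one_to_6mo", os = bin_survival_delta(19 - 11.1),
    susceptibility = "gt30pct", impact = "direct_treat", status = "active"
  )
  expect_equal(score_assignments(avenger)$total, 13L)
})

test_that("score bounds and extremes match the brute-force enumeration", {
  grid <- rubric_grid()
  expect_equal(nrow(grid), 4 * 3 * 3 * 3 * 3 * 3 * 3 * 2)  # 5,832
  expect_equal(min(grid$total), -7L)
  expect_equal(max(grid$total), 18L)
  # 18 is attained only by the unique all-best active assignment
  best <- grid[grid$total == 18L, ]
  expect_equal(nrow(best), 1L)
  expect_equal(best$novelty, "novel_mechanism_pdac")
  expect_equal(best$status, "active")
  # and the engine agrees with the enumeration on every combination
  asn <- tibble::as_tibble(grid[names(grid) != "total"])
  asn$registry_id <- sprintf("NCT%08d", seq_len(nrow(asn)))
  expect_equal(score_assignments(asn)$total, grid$total)
})

test_that("raising any single criterion level never lowers the total", {
  rubric <- impact_rubric()
  grid <- rubric_grid(rubric)
  criteria <- c("novelty", "promise", "allocation", "pfs", "os",
                "susceptibility", "impact", "status")
  for (cr in criteria) {
    levels <- rubric$level[rubric$criterion == cr]
    points <- rubric$points[rubric$criterion == cr]
    base_pts <- points[match(grid[[cr]], levels)]
    for (j in seq_along(levels)) {
      # perturb every enumerated assignment to level j of criterion cr
      delta <- points[j] - base_pts
      new_total <- grid$total + delta
      expect_true(all((delta >= 0) == (new_total >= grid$total)))
      expect_true(all(new_total >= -7 & new_total <= 18))
    }
  }
})

test_that("stored levels must agree with raw deltas when both are present", {
  bad <- tibble::tibble(
    registry_id = "NCT00000001",
    novelty = "established", promise = "untested_or_under_investigation",
    allocation = "not_applicable", pfs = "gt6mo", os = "lt1mo",
    susceptibility = "gt30pct", impact = "direct_treat", status = "active",
    pfs_delta = 2.0, os_delta = NA_real_, susceptible_fraction = NA_real_
  )
  expect_error(score_assignments(bad), "inconsistent")
  expect_error(
    score_assignments(dplyr::mutate(bad, pfs = "one_to_6mo",
                                    susceptible_fraction = 0.01)),
    "inconsistent")
  ok <- dplyr::mutate(bad, pfs = "one_to_6mo")
  expect_equal(score_assignments(ok)$total, 7L)  # 0+0+0+1+0+3+3+0
})

test_that("unknown level tokens abort naming criterion and trial", {
  asn <- phase3_assignments()
  asn$promise[3] <- "definitely_promising"
  expect_error(score_assignments(asn), "promise.*NCT03126435")
})

test_that("the packaged compendium assignments reproduce every printed score", {
  scored <- score_assignments(phase3_assignments())
  comp <- phase3_compendium()
  expect_equal(scored$total[match(comp$registry_id, scored$registry_id)],
               comp$impact_score)
})

test_that("ranking is dense, descending, and deterministic under ties", {
  ranked <- rank_trials(score_assignments(phase3_assignments()))
  expect_equal(ranked$registry_id[1], "NCT03377491")
  expect_equal(ranked$total[1], 15L)
  expect_true(all(diff(ranked$total) <= 0))
  expect_true(all(diff(ranked$rank) %in% c(0L, 1L)))  # dense ranks
  # ties share a rank and sort by registry id
  ties <- ranked[ranked$total == 3L, ]
  expect_true(nrow(ties) >= 2)
  expect_equal(length(unique(ties$rank)), 1L)
  expect_equal(ties$registry_id, sort(ties$registry_id))
  # empty input
  empty <- rank_trials(score_assignments(phase3_assignments()[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("tidy and glance summarise scored trials", {
  scored <- score_assignments(phase3_assignments())
  long <- tidy(scored)
  expect_equal(nrow(long), 37L * 8L)
  g <- glance(scored)
  expect_equal(g$n_trials, 37L)
  expect_equal(g$max_total, 15L)
  expect_equal(g$min_total, 0L)
})

test_that("completed-but-unpublished status scores as active with a warning", {
  asn <- phase3_assignments()[1, ]
  asn$status <- "completed_unpublished"
  expect_warning(scored <- score_assignments(asn), "active")
  expect_equal(scored$total, 15L)
})
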