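curated_default <- function(seed = 1) {
  apply_filters(generate_registry(generator_config(seed = seed)))
}

test_that("stage table reproduces the census counts and percentages", {
  tab <- tabulate_landscape(curated_default(), "stage")
  expect_equal(attr(tab, "total"), 430L)
  adv <- tab[tab$code == "advanced_metastatic", ]
  expect_equal(adv$count, 265L)
  expect_equal(adv$exact_pct, 100 * 265 / 430, tolerance = 1e-9)
  expect_equal(adv$rendered_pct, "62%")
  loc <- tab[tab$code == "localized", ]
  expect_equal(loc$count, 135L)   # 60 + 19 + 46 + 10 rolled up
  expect_equal(tab$count[tab$depth == 1], c(60L, 19L, 46L, 10L))
  # complete top-level partition conserves the total
  expect_equal(sum(tab$count[tab$depth == 0]), 430L)
})

test_that("category and mechanism tables conserve hierarchical totals", {
  iv <- expand_interventions(curated_default())
  cat_tab <- tabulate_landscape(iv, "category")
  expect_equal(attr(cat_tab, "total"), 590L)
  expect_equal(sum(cat_tab$count[cat_tab$depth == 0]), 590L)
  expect_equal(nrow(cat_tab[cat_tab$depth == 0, ]), 7L)
  expect_equal(cat_tab$count[cat_tab$code == "drug"], 310L)

  mech_tab <- tabulate_landscape(iv, "mechanism", granularity = 0.5)
  expect_equal(attr(mech_tab, "total"), 515L)
  immune <- mech_tab[mech_tab$code == "immune", ]
  kids <- mech_tab$count[mech_tab$code %in%
    c("checkpoint", "adoptive_cell", "oncolytic_virus", "vaccine", "other_immune")]
  expect_equal(immune$count, 189L)
  expect_equal(immune$count, sum(kids))
  expect_equal(kids, c(73L, 33L, 10L, 28L, 45L))
})

test_that("systemic filter keeps exactly the mechanism-bearing subset", {
  iv <- expand_interventions(curated_default())
  sys <- systemic_filter(iv)
  expect_equal(nrow(iv), 590L)
  expect_equal(nrow(sys), 515L)
  expect_true(all(!is.na(sys$mechanism_code)))

  toy <- tibble::tibble(
    registry_id = sprintf("NCT%08d", 1:10), arm_index = 1L,
    name = letters[1:10],
    category_code = c(rep("radiation", 3), "procedure", "pain_qol",
                      rep("small_molecule", 5)),
    mechanism_code = c(rep(NA, 5), rep("checkpoint", 5)),
    is_systemic = c(rep(FALSE, 5), rep(TRUE, 5))
  )
  expect_equal(nrow(systemic_filter(toy)), 5L)
  only_rt <- toy[toy$category_code == "radiation", ]
  expect_equal(nrow(systemic_filter(only_rt)), 0L)
})

test_that("single-item input yields a 100 percent row", {
  tab <- tabulate_landscape(make_trial(phase = "II"), "phase")
  expect_equal(tab$exact_pct[tab$code == "II"], 100)
  expect_equal(tab$count[tab$code == "II"], 1L)
  expect_equal(sum(tab$count), 1L)
})

test_that("facet/denominator mismatches are usage errors", {
  reg <- curated_default()
  expect_error(tabulate_landscape(reg, "phase", denominator = "interventions"),
               "requires denominator")
  iv <- expand_interventions(reg)
  expect_error(tabulate_landscape(iv, "mechanism", denominator = "trials"),
               "requires denominator")
  expect_error(tabulate_landscape(reg, "mechanism"), "intervention records")
})

test_that("largest-remainder tables constrain children to parent values", {
  iv <- expand_interventions(curated_default())
  tab <- tabulate_landscape(iv, "mechanism", granularity = 0.5,
                            mode = "largest_remainder")
  num <- function(code) {
    as.numeric(sub("%", "", tab$rendered_pct[tab$code == code]))
  }
  top <- vapply(tab$code[tab$depth == 0], num, numeric(1))
  expect_equal(sum(top), 100)
  kids <- vapply(c("checkpoint", "adoptive_cell", "oncolytic_virus",
                   "vaccine", "other_immune"), num, numeric(1))
  expect_equal(sum(kids), num("immune"))
})

test_that("landscape tables export to CSV and markdown and plot", {
  tab <- tabulate_landscape(curated_default(), "stage")
  f <- withr::local_tempfile(fileext = ".csv")
  write_landscape_csv(tab, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$count, tab$count)
  md <- format_landscape_md(tab)
  expect_match(md[3], "Advanced/Metastatic.*265.*62%")
  expect_match(md[length(md)], "Total.*430")
  p <- ggplot2::autoplot(tab)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(score_assignments(phase3_assignments())), "ggplot")
})
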