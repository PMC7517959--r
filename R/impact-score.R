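# The Impact Score: an additive eight-criterion rubric ranking late-phase
# trials by novelty (A), prior promise (B), allocation design (C),
# progression-free and overall survival improvements (D, E), the fraction
# of tumors susceptible (F), desired impact (G), and trial status (H).
# Totals range from -7 (worst level everywhere, terminated) to 18 (best
# level everywhere, active).

.criteria <- c("novelty", "promise", "allocation", "pfs", "os",
               "susceptibility", "impact", "status")

#' The Impact Score rubric
#'
#' Loads the criterion/level/points table.  The packaged rubric encodes the
#' eight criteria with points: novelty 5/2/1/0; promise +2/0/-2; allocation
#' +1/0/-1; PFS and OS improvement 2/1/0; susceptible fraction 3/2/1;
#' desired impact 3/1/0; status 0/-5.
#'
#' @param path Optional path to a rubric CSV with columns
#'   `criterion,level,points` (extra label columns allowed); defaults to
#'   the packaged rubric.
#' @return A tibble with columns `criterion`, `criterion_label`, `level`,
#'   `level_label`, `points`.
#' @examples
#' impact_rubric()
#' @export
impact_rubric <- function(path = NULL) {
  path <- path %||% system.file("extdata", "impact_rubric.csv",
                                package = "pdactrials", mustWork = TRUE)
  rub <- readr::read_csv(path, col_types = readr::cols(
    points = readr::col_integer(), .default = readr::col_character()
  ))
  if (!all(c("criterion", "level", "points") %in% names(rub))) {
    abort("rubric file needs columns criterion, level, points")
  }
  missing_crit <- setdiff(.criteria, unique(rub$criterion))
  if (length(missing_crit)) {
    abort(paste0("rubric missing criteria: ", paste(missing_crit, collapse = ", ")))
  }
  if (anyDuplicated(paste(rub$criterion, rub$level))) {
    abort("duplicate criterion/level in rubric")
  }
  as_tibble(rub)
}

#' Bin a survival improvement into a rubric level
#'
#' Criteria D (progression-free survival) and E (overall survival) score
#' the improvement, in months, over the comparator of the preceding study
#' or interim report.  Thresholds follow the printed rubric: strictly more
#' than 6 months scores the top level, 1 to 6 months (closed range) the
#' middle, and less than 1 month — or an unreported delta — the bottom.
#' Negative deltas are allowed and fall in the bottom bin.
#'
#' @param delta Numeric vector of survival improvements in months; may
#'   contain `NA` where `reported` is `FALSE`.
#' @param reported Logical vector (recycled): was a delta reported at all?
#' @return Character vector of level tokens (`"gt6mo"`, `"one_to_6mo"`,
#'   `"lt1mo"`).
#' @examples
#' bin_survival_delta(c(8.2, 4.6, 0.4, 6.0))
#' @export
bin_survival_delta <- function(delta, reported = TRUE) {
  reported <- rep_len(as.logical(reported), length(delta))
  if (any(reported & (is.nan(delta) | is.infinite(delta)))) {
    abort("reported survival delta must be finite")
  }
  if (any(reported & is.na(delta))) {
    abort("reported survival delta must not be missing")
  }
  out <- rep("lt1mo", length(delta))
  out[reported & delta > 6] <- "gt6mo"
  out[reported & delta >= 1 & delta <= 6] <- "one_to_6mo"
  out
}

#' Bin a susceptible tumor fraction into a rubric level
#'
#' Criterion F scores the expected fraction of pancreatic tumors the
#' intervention applies to: strictly more than 30 percent scores 3 points,
#' 5 to 30 percent (closed range) 2 points, and below 5 percent 1 point.
#'
#' @param fraction Numeric vector in (0, 1].
#' @return Character vector of level tokens (`"gt30pct"`, `"pct5_to_30"`,
#'   `"lt5pct"`).
#' @examples
#' bin_susceptibility(c(0.9, 0.02, 0.30))
#' @export
bin_susceptibility <- function(fraction) {
  if (any(is.na(fraction) | fraction <= 0 | fraction > 1)) {
    abort("susceptible fraction must lie in (0, 1]")
  }
  if_else(fraction > 0.30, "gt30pct",
          if_else(fraction >= 0.05, "pct5_to_30", "lt5pct"))
}

#' Read rubric assignments from CSV
#'
#' An assignment holds one level token per criterion for one trial, plus
#' optional raw inputs (`pfs_delta`, `os_delta` in months,
#' `susceptible_fraction` in (0, 1]) whose binned levels must agree with
#' the stored levels.
#'
#' @param path Path to a CSV with columns `registry_id`, the eight
#'   criterion columns (`novelty`, `promise`, `allocation`, `pfs`, `os`,
#'   `susceptibility`, `impact`, `status`), and optionally the raw-input
#'   columns.
#' @return An assignment tibble.
#' @seealso [phase3_assignments()] for the packaged phase III fixture.
#' @export
read_assignments <- function(path) {
  asn <- readr::read_csv(path, col_types = readr::cols(
    pfs_delta = readr::col_double(), os_delta = readr::col_double(),
    susceptible_fraction = readr::col_double(),
    .default = readr::col_character()
  ))
  missing_cols <- setdiff(c("registry_id", .criteria), names(asn))
  if (length(missing_cols)) {
    abort(paste0("assignment file missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("pfs_delta", "os_delta", "susceptible_fraction")) {
    if (!col %in% names(asn)) asn[[col]] <- NA_real_
  }
  as_tibble(asn)
}

# Check stored levels against re-binned raw inputs; abort on disagreement.
check_assignment_consistency <- function(assignments) {
  for (i in seq_len(nrow(assignments))) {
    id <- assignments$registry_id[i]
    if (!is.na(assignments$pfs_delta[i])) {
      expect <- bin_survival_delta(assignments$pfs_delta[i])
      if (expect != assignments$pfs[i]) {
        abort(sprintf("%s: pfs level '%s' inconsistent with pfs_delta %.2f (bins to '%s')",
                      id, assignments$pfs[i], assignments$pfs_delta[i], expect))
      }
    }
    if (!is.na(assignments$os_delta[i])) {
      expect <- bin_survival_delta(assignments$os_delta[i])
      if (expect != assignments$os[i]) {
        abort(sprintf("%s: os level '%s' inconsistent with os_delta %.2f (bins to '%s')",
                      id, assignments$os[i], assignments$os_delta[i], expect))
      }
    }
    if (!is.na(assignments$susceptible_fraction[i])) {
      expect <- bin_susceptibility(assignments$susceptible_fraction[i])
      if (expect != assignments$susceptibility[i]) {
        abort(sprintf("%s: susceptibility level '%s' inconsistent with fraction %.2f (bins to '%s')",
                      id, assignments$susceptibility[i],
                      assignments$susceptible_fraction[i], expect))
      }
    }
  }
  invisible(assignments)
}

#' Score rubric assignments
#'
#' Looks up the points of each trial's level on each of the eight criteria
#' and sums them into the Impact Score total.  Unknown level tokens abort
#' with the criterion and trial named.  Where raw survival deltas or
#' susceptible fractions accompany an assignment, their binned levels are
#' checked against the stored levels.  The status level
#' `completed_unpublished` is accepted and scored as `active`, with a
#' warning.
#'
#' @param assignments An assignment tibble as from [read_assignments()] or
#'   [phase3_assignments()].
#' @param rubric A rubric tibble from [impact_rubric()].
#' @return A `scored_trials` tibble: `registry_id`, one points column per
#'   criterion (`novelty_pts`, ..., `status_pts`), and `total`.
#' @examples
#' scored <- score_assignments(phase3_assignments())
#' rank_trials(scored)
#' @export
score_assignments <- function(assignments, rubric = impact_rubric()) {
  assignments <- as_tibble(assignments)
  missing_cols <- setdiff(c("registry_id", .criteria), names(assignments))
  if (length(missing_cols)) {
    abort(paste0("assignments missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("pfs_delta", "os_delta", "susceptible_fraction")) {
    if (!col %in% names(assignments)) assignments[[col]] <- NA_real_
  }
  if (any(assignments$status == "completed_unpublished", na.rm = TRUE)) {
    warn("status 'completed_unpublished' scored as 'active' (no published result to penalize)")
    assignments$status[assignments$status == "completed_unpublished"] <- "active"
  }
  check_assignment_consistency(assignments)

  out <- tibble(registry_id = assignments$registry_id)
  for (crit in .criteria) {
    levels <- rubric$level[rubric$criterion == crit]
    points <- rubric$points[rubric$criterion == crit]
    idx <- match(assignments[[crit]], levels)
    if (anyNA(idx)) {
      i <- which(is.na(idx))[1L]
      abort(sprintf("unknown level '%s' for criterion '%s' (trial %s)",
                    assignments[[crit]][i], crit, assignments$registry_id[i]))
    }
    out[[paste0(crit, "_pts")]] <- points[idx]
  }
  out$total <- as.integer(rowSums(out[paste0(.criteria, "_pts")]))
  structure(out, class = c("scored_trials", class(out)))
}

#' Rank scored trials by Impact Score
#'
#' Orders trials by descending total.  Tied totals share a dense rank
#' (1, 2, 2, 3, ...) and are ordered by registry ID for determinism.
#'
#' @param scored A `scored_trials` tibble from [score_assignments()].
#' @return The same tibble ordered by rank, with a `rank` column.
#' @export
rank_trials <- function(scored) {
  scored <- as_tibble(scored)
  if (nrow(scored) == 0L) {
    out <- mutate(scored, rank = integer())
    return(structure(out, class = c("scored_trials", class(out))))
  }
  out <- scored |>
    arrange(desc(.data$total), .data$registry_id) |>
    mutate(rank = dplyr::dense_rank(desc(.data$total)))
  structure(out, class = c("scored_trials", class(out)))
}

#' @exportS3Method generics::tidy
tidy.scored_trials <- function(x, ...) {
  x |>
    as_tibble() |>
    tidyr::pivot_longer(cols = dplyr::ends_with("_pts"),
                        names_to = "criterion", values_to = "points") |>
    mutate(criterion = sub("_pts$", "", .data$criterion))
}

#' @exportS3Method generics::glance
glance.scored_trials <- function(x, ...) {
  tibble(
    n_trials = nrow(x),
    min_total = if (nrow(x)) min(x$total) else NA_integer_,
    median_total = if (nrow(x)) stats::median(x$total) else NA_real_,
    max_total = if (nrow(x)) max(x$total) else NA_integer_
  )
}

#' Plot Impact Score totals
#'
#' Bar chart of ranked Impact Score totals, highest first.
#'
#' @param object A `scored_trials` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scored_trials <- function(object, ...) {
  ranked <- rank_trials(object)
  ranked$registry_id <- factor(ranked$registry_id, levels = rev(ranked$registry_id))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$total, y = .data$registry_id)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Impact Score (range -7 to 18)", y = NULL,
                  title = "Late-phase trials ranked by Impact Score") +
    ggplot2::theme_minimal()
}
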