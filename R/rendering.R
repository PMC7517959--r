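# Percentage rendering. Census tables mix two conventions:
#  - half_up: each cell rounded independently to the nearest multiple of the
#    granularity, ties away from zero; exact values in (0, 1) percent print
#    as "< 1%". Cells need not sum to anything.
#  - largest_remainder: apportionment. Cells are floored to the granularity
#    and leftover steps are granted in decreasing fractional-remainder
#    order until the rendered values sum exactly to target_total (100 for a
#    top-level table, the parent's rendered value for a sub-table). Each
#    rendered value stays within one granularity step of the exact value.

#' Round percentages numerically
#'
#' The numeric core behind [render_percentages()]: returns rounded
#' percentage values without display formatting.
#'
#' @param counts Non-negative integer vector.
#' @param denominator Positive total the percentages are taken against.
#' @param granularity Rounding step in percentage points: `1` or `0.5`.
#' @param mode `"half_up"` (independent nearest-step rounding, ties away
#'   from zero) or `"largest_remainder"` (sum-constrained apportionment).
#' @param target_total Required for `largest_remainder`: the value the
#'   rounded cells must sum to.
#' @return Numeric vector of rounded percentages, same length as `counts`.
#' @examples
#' round_percentages(c(134, 94, 165, 5, 32), 430,
#'                   mode = "largest_remainder", target_total = 100)
#' @export
round_percentages <- function(counts, denominator, granularity = 1,
                              mode = c("half_up", "largest_remainder"),
                              target_total = NULL) {
  mode <- arg_match(mode)
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    abort("counts must be non-negative numbers")
  }
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0) {
    abort("denominator must be a single positive number")
  }
  if (!granularity %in% c(1, 0.5)) abort("granularity must be 1 or 0.5")
  exact <- 100 * counts / denominator

  if (mode == "half_up") {
    return(floor(exact / granularity + 0.5) * granularity)
  }

  if (is.null(target_total)) {
    abort("largest_remainder mode requires target_total")
  }
  floors <- floor(round(exact / granularity, 9)) * granularity
  steps_needed <- (target_total - sum(floors)) / granularity
  if (abs(steps_needed - round(steps_needed)) > 1e-9) {
    abort("target_total is not reachable on the granularity grid")
  }
  steps_needed <- as.integer(round(steps_needed))
  if (steps_needed < 0L || steps_needed > length(counts)) {
    abort("target_total unreachable within one granularity step per cell")
  }
  remainder <- exact - floors
  grant <- head(order(remainder, decreasing = TRUE), steps_needed)
  out <- floors
  out[grant] <- out[grant] + granularity
  out
}

#' Render percentages as display tokens
#'
#' Formats census percentages the way the landscape tables print them:
#' `"31%"`, `"6.5%"`, and — in `half_up` mode — `"< 1%"` for nonzero exact
#' values below one percent.
#'
#' @inheritParams round_percentages
#' @return Character vector of display tokens.
#' @examples
#' render_percentages(134, 430)                       # "31%"
#' render_percentages(33, 515, granularity = 0.5)     # "6.5%"
#' render_percentages(3, 515)                         # "< 1%"
#' @export
render_percentages <- function(counts, denominator, granularity = 1,
                               mode = c("half_up", "largest_remainder"),
                               target_total = NULL) {
  mode <- arg_match(mode)
  rounded <- round_percentages(counts, denominator, granularity, mode, target_total)
  exact <- 100 * counts / denominator
  tokens <- format_pct(rounded)
  if (mode == "half_up") {
    tokens[exact > 0 & exact < 1] <- "< 1%"
  }
  tokens
}

format_pct <- function(x) {
  if_else(abs(x - round(x)) < 1e-9,
          sprintf("%d%%", as.integer(round(x))),
          sprintf("%.1f%%", x))
}
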