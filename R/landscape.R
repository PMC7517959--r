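# Landscape census tables (facet x denominator) with the two percentage
# rendering conventions.

.facets <- c("phase", "stage", "line", "category", "mechanism")
.denominators <- c("trials", "interventions", "systemic")

# Facet node tables for the trial-level facets. Stage is hierarchical:
# the four localized sub-stages roll up into a "localized" parent row.
facet_nodes <- function(facet) {
  switch(facet,
    phase = tibble(
      code = .phase_levels,
      label = c("Phase I", "Phase I/II", "Phase II", "Phase II/III", "Phase III"),
      parent = NA_character_
    ),
    stage = tibble(
      code = c("advanced_metastatic", "localized", "localized_resectable",
               "localized_borderline", "localized_unresectable",
               "localized_any", "unspecified"),
      label = c("Advanced/Metastatic", "Localized", "Resectable", "Borderline",
                "Unresectable", "Any", "Unspecified"),
      parent = c(NA, NA, "localized", "localized", "localized", "localized", NA)
    ),
    line = tibble(
      code = .line_levels,
      label = c("First", "Second or later", "Unspecified"),
      parent = NA_character_
    ),
    category = select(trial_taxonomy("category"), "code", "label", "parent"),
    mechanism = select(trial_taxonomy("mechanism"), "code", "label", "parent")
  )
}

#' Restrict interventions to the systemic subset
#'
#' Keeps the therapies that target tumor biology through pharmacologic,
#' cell-based, viral-based, or other systemic delivery — i.e. drops
#' radiation, procedure, and pain/quality-of-life interventions.  The
#' survivors are exactly the interventions that carry a mechanism code.
#'
#' @param interventions An intervention tibble from [expand_interventions()].
#' @return The systemic subset, same columns.
#' @examples
#' systemic_filter(expand_interventions(phase3_trials()))
#' @export
systemic_filter <- function(interventions) {
  interventions <- as_tibble(interventions)
  filter(interventions, !(.data$category_code %in% .non_systemic_categories))
}

#' Tabulate a landscape census table
#'
#' Counts trials or interventions along one facet and renders percentages
#' under the requested denominator convention:
#'
#' * facet `phase`, `stage` or `line` over trial records, denominator
#'   `"trials"`;
#' * facet `category` over intervention records, denominator
#'   `"interventions"`;
#' * facet `mechanism` over intervention records, denominator
#'   `"systemic"` (the [systemic_filter()] subset is taken internally).
#'
#' Hierarchical facets (stage, category, mechanism) emit parent and child
#' rows; a parent's count is the sum over its descendants, and with
#' `mode = "largest_remainder"` each sibling group is apportioned so it
#' sums exactly to its parent's rendered value (100 at the top level).
#' Rows follow fixed taxonomy order, not count order.
#'
#' @param data A trial-record tibble (trial facets) or an intervention
#'   tibble from [expand_interventions()] (category/mechanism facets).
#' @param facet One of `"phase"`, `"stage"`, `"line"`, `"category"`,
#'   `"mechanism"`.
#' @param denominator One of `"trials"`, `"interventions"`, `"systemic"`;
#'   defaults to the conventional denominator for the facet.
#' @param mode,granularity Percentage rendering controls; see
#'   [render_percentages()].
#' @return A `landscape_table` tibble with columns `code`, `label`,
#'   `depth`, `count`, `exact_pct`, `rendered_pct`, and attributes
#'   `facet`, `denominator`, `total`.
#' @examples
#' reg <- apply_filters(generate_registry(generator_config(seed = 1)))
#' tabulate_landscape(reg, "stage")
#' @export
tabulate_landscape <- function(data, facet = .facets, denominator = NULL,
                               mode = c("half_up", "largest_remainder"),
                               granularity = 1) {
  facet <- arg_match(facet, .facets)
  mode <- arg_match(mode)
  data <- as_tibble(data)
  default_denom <- switch(facet, phase = , stage = , line = "trials",
                          category = "interventions", mechanism = "systemic")
  denominator <- denominator %||% default_denom
  denominator <- arg_match(denominator, .denominators)
  if (denominator != default_denom) {
    abort(sprintf("facet '%s' requires denominator '%s', not '%s'",
                  facet, default_denom, denominator))
  }

  if (facet %in% c("phase", "stage", "line")) {
    if (!"phase" %in% names(data)) abort("trial facets need trial records")
    item_codes <- switch(facet, phase = data$phase, line = data$line_of_therapy,
                         stage = data$disease_stage)
  } else {
    if (!"category_code" %in% names(data)) {
      abort("category/mechanism facets need intervention records from expand_interventions()")
    }
    if (facet == "mechanism") data <- systemic_filter(data)
    item_codes <- if (facet == "category") data$category_code else data$mechanism_code
  }
  total <- nrow(data)

  nodes <- facet_nodes(facet)
  check_enum(item_codes, nodes$code, facet, ids = seq_along(item_codes))
  nodes$depth <- taxonomy_depth(nodes$code, nodes$parent)
  direct <- as.integer(table(factor(item_codes, levels = nodes$code)))
  # Node count = direct annotations + everything below it.
  nodes$count <- map_int(seq_len(nrow(nodes)), function(i) {
    in_subtree <- map_lgl(nodes$code, function(cd) {
      cd == nodes$code[i] || nodes$code[i] %in% taxonomy_ancestors(cd, nodes)
    })
    as.integer(sum(direct[in_subtree]))
  })
  nodes$exact_pct <- if (total > 0) 100 * nodes$count / total else rep(0, nrow(nodes))

  nodes$rendered_num <- NA_real_
  nodes$rendered_pct <- NA_character_
  if (total > 0) {
    if (mode == "half_up") {
      nodes$rendered_num <- round_percentages(nodes$count, total, granularity, "half_up")
      nodes$rendered_pct <- render_percentages(nodes$count, total, granularity, "half_up")
    } else {
      # Apportion each sibling group against its parent's rendered value,
      # parents first (depth order), top level against 100.
      for (d in sort(unique(nodes$depth))) {
        parents <- unique(nodes$parent[nodes$depth == d])
        for (p in parents) {
          sel <- nodes$depth == d &
            (if (is.na(p)) is.na(nodes$parent) else !is.na(nodes$parent) & nodes$parent == p)
          target <- if (is.na(p)) 100 else nodes$rendered_num[nodes$code == p]
          vals <- round_percentages(nodes$count[sel], total, granularity,
                                    "largest_remainder", target_total = target)
          nodes$rendered_num[sel] <- vals
          nodes$rendered_pct[sel] <- format_pct(vals)
        }
      }
    }
  }

  out <- select(nodes, "code", "label", "depth", "count", "exact_pct", "rendered_pct")
  structure(out,
            class = c("landscape_table", class(out)),
            facet = facet, denominator = denominator, total = total,
            mode = mode, granularity = granularity)
}

#' @exportS3Method generics::glance
glance.landscape_table <- function(x, ...) {
  tibble(facet = attr(x, "facet"), denominator = attr(x, "denominator"),
         total = attr(x, "total"), mode = attr(x, "mode"),
         granularity = attr(x, "granularity"))
}

#' @exportS3Method generics::tidy
tidy.landscape_table <- function(x, ...) {
  as_tibble(unclass_landscape(x))
}

unclass_landscape <- function(x) {
  class(x) <- setdiff(class(x), "landscape_table")
  x
}

#' Write a landscape table as CSV
#'
#' @param table A `landscape_table` from [tabulate_landscape()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(table, path) {
  readr::write_csv(tidy(table), path)
  invisible(path)
}

#' Format a landscape table as markdown
#'
#' Mirrors the census table layout: one row per taxonomy node in fixed
#' taxonomy order, child rows indented under their parent, with count and
#' rendered percentage columns, and a total row.
#'
#' @param table A `landscape_table` from [tabulate_landscape()].
#' @return A character vector of markdown lines.
#' @export
format_landscape_md <- function(table) {
  facet <- attr(table, "facet")
  indent <- strrep("  ", table$depth)
  bold <- table$depth == 0
  label <- ifelse(bold, paste0("**", table$label, "**"), paste0(indent, table$label))
  n_col <- ifelse(bold, paste0("**", table$count, "**"), as.character(table$count))
  p_col <- ifelse(bold, paste0("**", table$rendered_pct, "**"), table$rendered_pct)
  c(
    sprintf("| %s | n | %% (n = %d) |",
            paste0(toupper(substring(facet, 1, 1)), substring(facet, 2)),
            attr(table, "total")),
    "| --- | ---: | ---: |",
    sprintf("| %s | %s | %s |", label, n_col, p_col),
    sprintf("| **Total** | **%d** | **100%%** |", attr(table, "total"))
  )
}

#' @export
print.landscape_table <- function(x, ...) {
  cat(sprintf("# Landscape table: facet=%s denominator=%s total=%d\n",
              attr(x, "facet"), attr(x, "denominator"), attr(x, "total")))
  print(as_tibble(unclass_landscape(x)), n = nrow(x))
  invisible(x)
}

#' Plot a landscape table
#'
#' Horizontal bar chart of top-level census counts, in taxonomy order.
#'
#' @param object A `landscape_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.landscape_table <- function(object, ...) {
  top <- filter(as_tibble(unclass_landscape(object)), .data$depth == 0)
  top$label <- factor(top$label, levels = rev(top$label))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$count, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rendered_pct), hjust = -0.15, size = 3) +
    ggplot2::labs(
      x = sprintf("Count (n = %d %s)", attr(object, "total"), attr(object, "denominator")),
      y = NULL,
      title = sprintf("Landscape census by %s", attr(object, "facet"))
    ) +
    ggplot2::theme_minimal()
}
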