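#' Controlled taxonomies for therapeutic categories and mechanisms of action
#'
#' Two disjoint taxonomies ship with the package as plain CSV
#' (`code,label,parent`):
#'
#' * **category** — the therapeutic-category tree used to classify the 590
#'   interventions of the landscape census: novel drugs (small molecules,
#'   monoclonal antibodies, other pharmacologic agents), conventional or
#'   existing therapies (new combinations/delivery of established PDAC
#'   drugs, FDA-approved drugs for other cancers, radiation), gene therapy,
#'   cellular therapy, nutraceuticals, procedures, and pain/quality-of-life
#'   interventions.
#' * **mechanism** — the mechanism-of-action tree applied to the systemic
#'   subset: immune system (checkpoint inhibitors, adoptive cell transfer
#'   with T-cell and other branches, oncolytic viruses, cancer vaccines,
#'   other immune), DNA/cell cycle, cell signaling (RTK, KRAS/RAF/MEK/ERK,
#'   PI3K/AKT/mTOR, JAK-STAT, FAK/SRC, miscellaneous), metabolism,
#'   angiogenesis, hormone receptors, apoptosis, symptom-directed therapy
#'   (thrombosis, infection, enzyme supplementation), metastasis/invasion,
#'   and unknown.
#'
#' Annotation is curated input data: the package validates codes against
#' these trees, it never classifies free text.
#'
#' @param which `"category"` or `"mechanism"`.
#' @param path Optional path to a taxonomy CSV with columns
#'   `code,label,parent`; defaults to the packaged file.
#' @return A tibble with columns `code`, `label`, `parent` (`NA` for roots)
#'   and `depth` (0 for roots).
#' @examples
#' trial_taxonomy("category")
#' @export
trial_taxonomy <- function(which = c("category", "mechanism"), path = NULL) {
  which <- arg_match(which)
  path <- path %||% system.file(
    "extdata",
    paste0("taxonomy_", if (which == "category") "categories" else "mechanisms", ".csv"),
    package = "pdactrials", mustWork = TRUE
  )
  tax <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("code", "label", "parent") %in% names(tax)))
  if (anyDuplicated(tax$code)) {
    abort(sprintf("duplicate taxonomy code '%s'", tax$code[duplicated(tax$code)][1L]))
  }
  orphan <- !is.na(tax$parent) & !(tax$parent %in% tax$code)
  if (any(orphan)) {
    abort(sprintf("taxonomy parent '%s' is not a shipped code", tax$parent[orphan][1L]))
  }
  tax$depth <- taxonomy_depth(tax$code, tax$parent)
  as_tibble(tax)
}

# Depth per code; aborts on a parent cycle.
taxonomy_depth <- function(code, parent) {
  depth <- integer(length(code))
  for (i in seq_along(code)) {
    d <- 0L
    p <- parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      if (d > length(code)) abort("taxonomy parent links contain a cycle")
      p <- parent[match(p, code)]
    }
    depth[i] <- d
  }
  depth
}

# All ancestors of a code (closest first), as a character vector.
taxonomy_ancestors <- function(code, tax) {
  out <- character(0)
  p <- tax$parent[match(code, tax$code)]
  while (length(p) == 1 && !is.na(p)) {
    out <- c(out, p)
    p <- tax$parent[match(p, tax$code)]
  }
  out
}

# Leaf codes (codes that are nobody's parent).
taxonomy_leaves <- function(tax) {
  setdiff(tax$code, tax$parent[!is.na(tax$parent)])
}

# Categories delivered systemically: everything except radiation,
# procedures, and pain/quality-of-life interventions.  These are the
# interventions that carry a mechanism-of-action code.
.non_systemic_categories <- c("radiation", "procedure", "pain_qol")

#' Is a therapeutic-category code delivered systemically?
#'
#' Systemic interventions (pharmacologic, cell-based, viral-based, or other
#' systemic delivery) target tumor biology directly and carry exactly one
#' mechanism-of-action code.  Radiation, procedures, and pain/QoL
#' interventions are non-systemic and carry none.
#'
#' @param category_code Character vector of category codes (leaf or parent).
#' @param taxonomy Category taxonomy tibble, defaulting to the packaged one.
#' @return Logical vector.
#' @examples
#' is_systemic_category(c("small_molecule", "radiation"))
#' @export
is_systemic_category <- function(category_code, taxonomy = trial_taxonomy("category")) {
  check_enum(category_code, taxonomy$code, "category_code",
             ids = seq_along(category_code), allow_na = FALSE)
  !(category_code %in% .non_systemic_categories)
}
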