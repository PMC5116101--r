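#' Food groups and nutrients recognised by the analysis
#'
#' The analysis works on the seven food groups of the Australian Guide to
#' Healthy Eating (AGTHE) and on energy plus the five micronutrients of
#' greatest concern in pregnancy. Both sets are closed: every record row and
#' every composition row must reference one of these codes.
#'
#' @return `snaq_food_groups()` returns a character vector of the seven
#'   canonical group codes. `snaq_nutrients()` returns a tibble with one row
#'   per nutrient: `nutrient` (code), `column` (the column name used in wide
#'   profile tables) and `unit`.
#' @examples
#' snaq_food_groups()
#' snaq_nutrients()
#' @export
snaq_food_groups <- function() {
  c("grains", "vegetables", "fruit", "meat", "dairy", "fats_oils",
    "discretionary")
}

#' @rdname snaq_food_groups
#' @export
snaq_nutrients <- function() {
  tibble(
    nutrient = c("energy", "iron", "calcium", "folate_dfe", "iodine", "zinc"),
    column   = c("energy_kj", "iron_mg", "calcium_mg", "folate_dfe_ug",
                 "iodine_ug", "zinc_mg"),
    unit     = c("kJ", "mg", "mg", "µg DFE", "µg", "mg")
  )
}

# column names of a wide nutrient profile, in canonical order
profile_columns <- function() snaq_nutrients()$column

nutrient_for_column <- function(column) {
  nn <- snaq_nutrients()
  nn$nutrient[match(column, nn$column)]
}

column_for_nutrient <- function(nutrient) {
  nn <- snaq_nutrients()
  nn$column[match(nutrient, nn$nutrient)]
}

# Accepted spellings for group labels in input files.  Matching is
# case-insensitive and ignores surrounding whitespace.
group_aliases <- function() {
  c(
    "grains" = "grains",
    "grains and cereals" = "grains",
    "grain" = "grains",
    "cereals" = "grains",
    "vegetables" = "vegetables",
    "vegetable" = "vegetables",
    "fruit" = "fruit",
    "fruits" = "fruit",
    "meat" = "meat",
    "lean meat" = "meat",
    "lean meats and alternatives" = "meat",
    "meat and alternatives" = "meat",
    "dairy" = "dairy",
    "dairy and alternatives" = "dairy",
    "fats_oils" = "fats_oils",
    "fats and oils" = "fats_oils",
    "unsaturated spreads and oils" = "fats_oils",
    "discretionary" = "discretionary",
    "energy-dense, nutrient-poor foods" = "discretionary",
    "energy dense nutrient poor" = "discretionary"
  )
}

#' Normalise food-group labels to canonical codes
#'
#' Accepts the canonical codes as well as common long-form labels
#' ("Grains and cereals", "Energy-dense, nutrient-poor foods", ...),
#' case-insensitively.
#'
#' @param x Character vector of group labels.
#' @return Character vector of canonical group codes.
#' @examples
#' normalize_group(c("Fruit", "Lean meat", "GRAINS"))
#' @export
normalize_group <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(group_aliases()[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf("unknown food group label(s): %s",
                  paste(shQuote(bad), collapse = ", ")),
          class = "snaq_parse_error")
  }
  out
}

#' Display names for food groups
#'
#' @param group Character vector of canonical group codes.
#' @return Character vector of human-readable names.
#' @export
group_label <- function(group) {
  labels <- c(
    grains = "Grains and cereals",
    vegetables = "Vegetables",
    fruit = "Fruit",
    meat = "Lean meat and alternatives",
    dairy = "Dairy and alternatives",
    fats_oils = "Unsaturated spreads and oils",
    discretionary = "Energy-dense, nutrient-poor foods"
  )
  unname(labels[group])
}
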