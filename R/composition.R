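# Reference tables: per-serving food-group composition, supplement products,
# pregnancy nutrient reference values (EAR/RDI) and AGTHE serving targets.

# Plausible energy content (kJ) of one standard AGTHE serving, per group.
# Point values are exact standard-serving energies; ranges reflect the spread
# across foods within the group.
energy_bands <- function() {
  tibble(
    group = snaq_food_groups(),
    lo = c(500, 100, 350, 500, 500, 250, 600),
    hi = c(500, 350, 350, 600, 600, 250, 600)
  )
}

#' Read a per-serving food-group composition table
#'
#' The composition table gives the average nutrient content of one standard
#' AGTHE serving of each of the seven food groups. The shipped default
#' ([snaq_composition()]) is a constructed stand-in for the (unpublished)
#' AUSNUT-2007-derived averages embedded in the original tool; replace it
#' with your own table to use different food composition data.
#'
#' Per-serving energy is checked against a plausibility band per group
#' (e.g. one standard grains serving is 500 kJ, vegetables 100-350 kJ). Out
#' of band values produce a warning, or an error when `strict = TRUE`.
#'
#' @param path Path to a CSV file with columns `group`, `energy_kj`,
#'   `iron_mg`, `calcium_mg`, `folate_dfe_ug`, `iodine_ug`, `zinc_mg` and
#'   exactly one row per food group.
#' @param strict Treat an out-of-band per-serving energy as an error rather
#'   than a warning.
#' @param energy_tolerance Relative tolerance applied to the energy band
#'   limits before flagging.
#' @return A tibble with one row per food group (class `snaq_composition`).
#' @examples
#' comp <- snaq_composition()
#' comp
#' @export
read_composition <- function(path, strict = FALSE, energy_tolerance = 0.25) {
  needed <- c("group", profile_columns())
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("composition file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "snaq_schema_error")
  }
  tab$group <- normalize_group(tab$group)
  groups <- snaq_food_groups()
  dup <- unique(tab$group[duplicated(tab$group)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate composition row(s) for group(s): %s",
                  paste(dup, collapse = ", ")),
          class = "snaq_schema_error")
  }
  absent <- setdiff(groups, tab$group)
  if (length(absent) > 0) {
    abort(sprintf("composition table is missing group(s): %s",
                  paste(absent, collapse = ", ")),
          class = "snaq_schema_error")
  }
  vals <- as.matrix(tab[profile_columns()])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("composition amounts must be finite and >= 0",
          class = "snaq_validation_error")
  }
  tab <- dplyr::arrange(tab[c("group", profile_columns())],
                        match(.data$group, groups))
  check_energy_bands(tab, strict = strict, tolerance = energy_tolerance)
  class(tab) <- c("snaq_composition", class(tab))
  tab
}

check_energy_bands <- function(tab, strict, tolerance) {
  bands <- energy_bands()
  merged <- dplyr::left_join(tab, bands, by = "group")
  bad <- merged$energy_kj < merged$lo * (1 - tolerance) |
    merged$energy_kj > merged$hi * (1 + tolerance)
  if (any(bad)) {
    msg <- sprintf(
      "per-serving energy outside plausible band for: %s",
      paste(sprintf("%s (%g kJ, band %g-%g)", merged$group[bad],
                    merged$energy_kj[bad], merged$lo[bad], merged$hi[bad]),
            collapse = "; "))
    if (strict) abort(msg, class = "snaq_validation_error") else warn(msg)
  }
  invisible(tab)
}

#' @rdname read_composition
#' @export
snaq_composition <- function() {
  read_composition(system.file("extdata", "composition_synthetic.csv",
                               package = "snaqr", mustWork = TRUE))
}

#' Read a supplement product table
#'
#' Each row is one product with per-dose nutrient amounts. A `folic_acid_ug`
#' column, if present, is converted to dietary folate equivalents (DFE) and
#' added to `folate_dfe_ug`: synthetic folic acid from supplements counts
#' 1.7 µg DFE per µg under the standard nutrient-reference convention.
#' Missing nutrient columns default to 0 (including energy: supplements are
#' treated as energy-free).
#'
#' @param path Path to a CSV file with a `product_id` column and any of the
#'   per-dose nutrient columns (`iron_mg`, `calcium_mg`, `folate_dfe_ug`,
#'   `folic_acid_ug`, `iodine_ug`, `zinc_mg`, `energy_kj`).
#' @param dfe_factor µg DFE per µg of synthetic folic acid.
#' @return A tibble with one row per product and the full set of per-dose
#'   nutrient columns.
#' @examples
#' snaq_supplements()
#' @export
read_supplements <- function(path, dfe_factor = 1.7) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(tab) == 0) {
    out <- tibble(product_id = character())
    for (col in profile_columns()) out[[col]] <- numeric()
    return(out)
  }
  if (!"product_id" %in% names(tab)) {
    abort("supplement file must have a product_id column",
          class = "snaq_schema_error")
  }
  if (anyDuplicated(tab$product_id)) {
    abort("duplicate product_id in supplement file",
          class = "snaq_schema_error")
  }
  for (col in c(profile_columns(), "folic_acid_ug")) {
    if (!col %in% names(tab)) tab[[col]] <- 0
    tab[[col]][is.na(tab[[col]])] <- 0
  }
  vals <- as.matrix(tab[c(profile_columns(), "folic_acid_ug")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("supplement per-dose amounts must be finite and >= 0",
          class = "snaq_validation_error")
  }
  tab$folate_dfe_ug <- tab$folate_dfe_ug + dfe_factor * tab$folic_acid_ug
  tab[c("product_id", profile_columns())]
}

#' @rdname read_supplements
#' @export
snaq_supplements <- function(dfe_factor = 1.7) {
  read_supplements(system.file("extdata", "supplements_synthetic.csv",
                               package = "snaqr", mustWork = TRUE),
                   dfe_factor = dfe_factor)
}

#' Pregnancy nutrient reference values (EAR and RDI)
#'
#' Defaults are the Australian pregnancy reference values for the five key
#' micronutrients: EAR iron 22 mg, calcium 840 mg, folate 520 µg DFE, iodine
#' 160 µg, zinc 9 mg; RDI iron 27 mg, calcium 1000 mg, folate 600 µg DFE,
#' iodine 220 µg, zinc 11 mg. Energy has no EAR/RDI in this framework and is
#' never classified.
#'
#' @param path Optional path to a JSON file of the form
#'   `{"iron": {"ear": 22, "rdi": 27}, ...}` keyed by nutrient code. When
#'   omitted, the defaults above are returned.
#' @return A tibble with columns `nutrient`, `ear`, `rdi`, `unit`.
#' @examples
#' snaq_nrv()
#' @export
snaq_nrv <- function(path = NULL) {
  defaults <- tibble(
    nutrient = c("iron", "calcium", "folate_dfe", "iodine", "zinc"),
    ear = c(22, 840, 520, 160, 9),
    rdi = c(27, 1000, 600, 220, 11)
  )
  if (!is.null(path)) {
    raw <- jsonlite::read_json(path)
    defaults <- purrr::imap_dfr(raw, function(v, k) {
      tibble(nutrient = k, ear = as.numeric(v$ear), rdi = as.numeric(v$rdi))
    })
    bad <- setdiff(defaults$nutrient, snaq_nutrients()$nutrient)
    if (length(bad) > 0 || "energy" %in% defaults$nutrient) {
      abort(sprintf("unknown or unsupported nutrient in NRV file: %s",
                    paste(c(bad, intersect("energy", defaults$nutrient)),
                          collapse = ", ")),
            class = "snaq_schema_error")
    }
  }
  if (any(!is.finite(defaults$ear)) || any(!is.finite(defaults$rdi)) ||
      any(defaults$ear <= 0) || any(defaults$ear >= defaults$rdi)) {
    abort("NRV table must satisfy 0 < ear < rdi for every nutrient",
          class = "snaq_validation_error")
  }
  nn <- snaq_nutrients()
  defaults$unit <- nn$unit[match(defaults$nutrient, nn$nutrient)]
  defaults
}

#' AGTHE pregnancy food-group serving targets
#'
#' Defaults are the pregnancy recommendations: grains >= 8.5, vegetables
#' >= 5, fruit >= 2, meat and alternatives >= 3.5, dairy >= 2.5 servings/day,
#' and 0-2.5 servings/day ranges for unsaturated spreads/oils and for
#' energy-dense, nutrient-poor (discretionary) foods.
#'
#' @param path Optional path to a JSON file keyed by group code, each entry
#'   either `{"min": x}` (threshold target) or `{"lo": a, "hi": b}` (range
#'   target). When omitted, the defaults above are returned.
#' @return A tibble with columns `group`, `min_servings`, `max_servings`
#'   (`NA` when unbounded above) and `target_label`.
#' @examples
#' agthe_targets()
#' @export
agthe_targets <- function(path = NULL) {
  out <- tibble(
    group = snaq_food_groups(),
    min_servings = c(8.5, 5, 2, 3.5, 2.5, 0, 0),
    max_servings = c(NA, NA, NA, NA, NA, 2.5, 2.5)
  )
  if (!is.null(path)) {
    raw <- jsonlite::read_json(path)
    for (k in names(raw)) {
      g <- normalize_group(k)
      v <- raw[[k]]
      if (!is.null(v$min)) {
        out$min_servings[out$group == g] <- as.numeric(v$min)
        out$max_servings[out$group == g] <- NA_real_
      } else {
        out$min_servings[out$group == g] <- as.numeric(v$lo)
        out$max_servings[out$group == g] <- as.numeric(v$hi)
      }
    }
  }
  bad <- out$min_servings < 0 |
    (!is.na(out$max_servings) & out$max_servings < out$min_servings)
  if (any(bad)) {
    abort(sprintf("invalid target for group(s): %s",
                  paste(out$group[bad], collapse = ", ")),
          class = "snaq_validation_error")
  }
  out$target_label <- ifelse(
    is.na(out$max_servings),
    paste0("≥", format(out$min_servings, trim = TRUE)),
    paste0(format(out$min_servings, trim = TRUE), "-",
           format(out$max_servings, trim = TRUE)))
  out
}
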