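# Core estimation: mean daily servings (+ supplement doses) -> nutrient
# profiles; adequacy classification against EAR/RDI; AGTHE target attainment;
# Table-1-style cohort summaries.

condition_levels <- function() c("food_and_supplements", "food_only")

#' Estimate daily nutrient profiles from food-group servings
#'
#' For each participant and nutrient, the estimate is the serving-weighted
#' sum of the per-serving group composition, plus (when
#' `include_supplements = TRUE`) the dose-weighted sum over supplement
#' products. Supplements contribute no energy, so the energy estimate is
#' identical under both conditions.
#'
#' @param servings Mean daily servings tibble ([mean_daily_servings()]).
#' @param supplement_doses Mean daily doses tibble
#'   ([mean_daily_supplement_doses()]); may be `NULL` or empty.
#' @param composition Per-serving composition table ([snaq_composition()]).
#' @param supplements Supplement product table ([snaq_supplements()]).
#' @param include_supplements Include supplement nutrients in the profile.
#' @return A wide tibble: `participant_id`, `condition`
#'   (`"food_and_supplements"` or `"food_only"`), then one column per
#'   nutrient (`energy_kj`, `iron_mg`, `calcium_mg`, `folate_dfe_ug`,
#'   `iodine_ug`, `zinc_mg`).
#' @examples
#' serv <- tibble::tibble(participant_id = "a", group = "dairy",
#'                        servings = 1, n_days = 3)
#' estimate_profiles(mean_daily_servings_complete(serv))
#' @export
estimate_profiles <- function(servings, supplement_doses = NULL,
                              composition = snaq_composition(),
                              supplements = snaq_supplements(),
                              include_supplements = FALSE) {
  cols <- profile_columns()
  ids <- unique(servings$participant_id)
  comp <- composition[match(snaq_food_groups(), composition$group), ]
  cmat <- as.matrix(comp[cols])              # 7 groups x 6 nutrients
  wide <- tidyr::pivot_wider(servings[c("participant_id", "group", "servings")],
                             names_from = "group", values_from = "servings",
                             values_fill = 0)
  for (g in snaq_food_groups()) if (!g %in% names(wide)) wide[[g]] <- 0
  smat <- as.matrix(wide[snaq_food_groups()])  # n x 7
  prof <- smat %*% cmat
  out <- tibble(participant_id = wide$participant_id)
  for (j in seq_along(cols)) out[[cols[j]]] <- unname(prof[, j])

  if (include_supplements && !is.null(supplement_doses) &&
      nrow(supplement_doses) > 0) {
    unknown <- setdiff(supplement_doses$product_id, supplements$product_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown supplement product_id: %s",
                    paste(unknown, collapse = ", ")),
            class = "snaq_validation_error")
    }
    pmat <- as.matrix(supplements[cols])
    add <- supplement_doses
    add_prof <- add$doses_per_day *
      pmat[match(add$product_id, supplements$product_id), , drop = FALSE]
    by_pid <- rowsum(add_prof, add$participant_id)
    idx <- match(rownames(by_pid), out$participant_id)
    for (j in seq_along(cols)) {
      out[[cols[j]]][idx] <- out[[cols[j]]][idx] + unname(by_pid[, j])
    }
  }
  out <- dplyr::mutate(
    out,
    condition = if (include_supplements) "food_and_supplements" else "food_only",
    .after = "participant_id")
  out[match(ids, out$participant_id), ]
}

#' Complete a servings table to all seven groups
#'
#' Utility used when a servings tibble was built by hand and does not list
#' every group: missing groups are filled with 0 servings.
#'
#' @param servings Tibble with columns `participant_id`, `group`,
#'   `servings` (and optionally `n_days`).
#' @return The completed tibble, one row per participant and group.
#' @export
mean_daily_servings_complete <- function(servings) {
  grid <- tidyr::expand_grid(
    participant_id = unique(servings$participant_id),
    group = snaq_food_groups())
  out <- dplyr::left_join(grid, servings, by = c("participant_id", "group"))
  out$servings[is.na(out$servings)] <- 0
  out
}

#' Intake as a percentage of the pregnancy EAR
#'
#' For example, 100 µg of dietary folate equivalents is 19% of the 520 µg
#' pregnancy folate EAR.
#'
#' @param amount Intake amount(s), in the nutrient's units per day.
#' @param nutrient Nutrient code (one of `"iron"`, `"calcium"`,
#'   `"folate_dfe"`, `"iodine"`, `"zinc"`; energy has no EAR).
#' @param nrv Nutrient reference table ([snaq_nrv()]).
#' @param digits Digits to round the percentage to; default 0 (nearest
#'   integer percent). Use `NULL` for no rounding.
#' @return Numeric percentage(s).
#' @examples
#' percent_of_ear(100, "folate_dfe")
#' @export
percent_of_ear <- function(amount, nutrient, nrv = snaq_nrv(), digits = 0) {
  if (any(nutrient == "energy")) {
    abort("energy has no EAR; percent_of_ear is undefined for it",
          class = "snaq_unsupported_nutrient")
  }
  ear <- nrv$ear[match(nutrient, nrv$nutrient)]
  if (anyNA(ear)) {
    abort(sprintf("no EAR for nutrient(s): %s",
                  paste(unique(nutrient[is.na(ear)]), collapse = ", ")),
          class = "snaq_unsupported_nutrient")
  }
  stopifnot(all(amount >= 0))
  pct <- 100 * amount / ear
  if (is.null(digits)) pct else round(pct, digits)
}

#' Ordered adequacy classes
#'
#' @return The ordered factor levels used for adequacy classification:
#'   `below_ear < ear_to_below_rdi < at_or_above_rdi`.
#' @export
adequacy_levels <- function() {
  c("below_ear", "ear_to_below_rdi", "at_or_above_rdi")
}

classify_intake <- function(intake, ear, rdi) {
  cls <- ifelse(intake < ear, "below_ear",
                ifelse(intake < rdi, "ear_to_below_rdi", "at_or_above_rdi"))
  factor(cls, levels = adequacy_levels(), ordered = TRUE)
}

#' Classify micronutrient adequacy against EAR and RDI
#'
#' Each micronutrient intake is placed in one of three ordered classes:
#' below the EAR (`intake < ear`), at or above the EAR but below the RDI
#' (`ear <= intake < rdi`), or at or above the RDI (`intake >= rdi`).
#' Intakes are classified unrounded. Energy is skipped (no EAR/RDI).
#'
#' @param profiles Wide profile tibble ([estimate_profiles()]).
#' @param nrv Nutrient reference table ([snaq_nrv()]).
#' @return A long tibble: `participant_id`, `condition`, `nutrient`,
#'   `intake`, `adequacy` (ordered factor).
#' @examples
#' prof <- tibble::tibble(participant_id = "a", condition = "food_only",
#'                        energy_kj = 8000, iron_mg = 9.5, calcium_mg = 800,
#'                        folate_dfe_ug = 320, iodine_ug = 99, zinc_mg = 10.6)
#' classify_adequacy(prof)
#' @export
classify_adequacy <- function(profiles, nrv = snaq_nrv()) {
  long <- tidyr::pivot_longer(profiles, cols = dplyr::any_of(profile_columns()),
                              names_to = "column", values_to = "intake")
  long$nutrient <- nutrient_for_column(long$column)
  long <- long[long$nutrient != "energy", ]
  long <- dplyr::left_join(long, nrv[c("nutrient", "ear", "rdi")],
                           by = "nutrient")
  long$adequacy <- classify_intake(long$intake, long$ear, long$rdi)
  keep <- intersect(c("participant_id", "condition"), names(long))
  long[c(keep, "nutrient", "intake", "adequacy")]
}

#' Does a mean daily serving count meet its AGTHE target?
#'
#' Threshold targets are met when `servings >= min_servings`; range targets
#' (spreads/oils, discretionary foods) when
#' `min_servings <= servings <= max_servings`, inclusive at both ends.
#'
#' @param servings Numeric vector of mean servings/day.
#' @param group Food-group code(s), recycled against `servings`.
#' @param targets Target table ([agthe_targets()]).
#' @return Logical vector.
#' @examples
#' meets_target(c(2, 3.5), c("fruit", "discretionary"))
#' @export
meets_target <- function(servings, group, targets = agthe_targets()) {
  stopifnot(all(servings >= 0))
  i <- match(group, targets$group)
  if (anyNA(i)) {
    abort(sprintf("unknown group(s): %s",
                  paste(unique(group[is.na(i)]), collapse = ", ")),
          class = "snaq_validation_error")
  }
  lo <- targets$min_servings[i]
  hi <- targets$max_servings[i]
  servings >= lo & (is.na(hi) | servings <= hi)
}

#' Summarise cohort food-group intake against AGTHE targets
#'
#' Produces per-group cohort statistics in the layout of a food-group intake
#' table: mean and sample SD (n-1 denominator; `NA` for a single
#' participant), median and interquartile range by linear interpolation
#' between order statistics (quantile type 7), and the number and percentage
#' of participants meeting the group's target.
#'
#' @param servings Mean daily servings tibble covering the cohort
#'   ([mean_daily_servings()]).
#' @param targets Target table ([agthe_targets()]).
#' @return A tibble of class `snaq_cohort_summary`, one row per food group:
#'   `group`, `n`, `mean`, `sd`, `median`, `p25`, `p75`, `target_label`,
#'   `n_meeting`, `pct_meeting`.
#' @export
summarize_cohort <- function(servings, targets = agthe_targets()) {
  if (nrow(servings) == 0) {
    abort("cannot summarise an empty cohort", class = "snaq_validation_error")
  }
  full <- mean_daily_servings_complete(
    servings[c("participant_id", "group", "servings")])
  out <- dplyr::summarise(
    dplyr::group_by(full, .data$group),
    n = dplyr::n(),
    mean = mean(.data$servings),
    sd = if (dplyr::n() > 1) sd(.data$servings) else NA_real_,
    median = median(.data$servings),
    p25 = unname(quantile(.data$servings, 0.25, type = 7)),
    p75 = unname(quantile(.data$servings, 0.75, type = 7)),
    n_meeting = sum(meets_target(.data$servings,
                                 .data$group[1], targets = targets)),
    .groups = "drop")
  out$pct_meeting <- 100 * out$n_meeting / out$n
  out <- dplyr::left_join(out, targets[c("group", "target_label")],
                          by = "group")
  out <- out[match(snaq_food_groups(), out$group),
             c("group", "n", "mean", "sd", "median", "p25", "p75",
               "target_label", "n_meeting", "pct_meeting")]
  class(out) <- c("snaq_cohort_summary", class(out))
  out
}

#' @rdname summarize_cohort
#' @param object A `snaq_cohort_summary`.
#' @param ... Unused.
#' @method autoplot snaq_cohort_summary
#' @export
autoplot.snaq_cohort_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(group_label(df$group), levels = rev(group_label(snaq_food_groups())))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(x = .data$median, xmin = .data$p25,
                                          xmax = .data$p75)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$median,
                                    label = paste0(round(.data$pct_meeting),
                                                   "% meet ", .data$target_label)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "Servings/day, median (IQR)", y = NULL,
                  title = "Cohort food-group intake vs AGTHE pregnancy targets") +
    ggplot2::theme_minimal()
}
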