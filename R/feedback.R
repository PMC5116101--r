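# Per-participant feedback: food-group intake vs AGTHE targets and
# micronutrient adequacy, rendered as text for counselling-style summaries.

#' Build a per-participant feedback summary
#'
#' Combines the participant's mean daily food-group servings (vs AGTHE
#' targets, with the serving gap to the target) and their nutrient profile
#' (adequacy class and percent of the pregnancy EAR). The gap is the
#' shortfall to the minimum target when unmet below, the excess over the
#' range ceiling when unmet above, and 0 when met.
#'
#' @param participant_id Participant to summarise.
#' @param servings Mean daily servings tibble covering the participant.
#' @param profiles Wide profile tibble covering the participant
#'   ([estimate_profiles()]); if both conditions are present the
#'   supplement-inclusive one is summarised.
#' @param targets Target table ([agthe_targets()]).
#' @param nrv Nutrient reference table ([snaq_nrv()]).
#' @return A list of class `snaq_feedback`: `participant_id`, `condition`,
#'   `food_groups` (tibble: group, servings, target_label, met, gap) and
#'   `nutrients` (tibble: nutrient, intake, unit, ear, rdi, adequacy,
#'   pct_ear).
#' @examples
#' serv <- mean_daily_servings_complete(
#'   tibble::tibble(participant_id = "a", group = "fruit", servings = 2))
#' prof <- estimate_profiles(serv)
#' build_feedback("a", serv, prof)
#' @export
build_feedback <- function(participant_id, servings, profiles,
                           targets = agthe_targets(), nrv = snaq_nrv()) {
  serv <- servings[servings$participant_id == participant_id, ]
  prof <- profiles[profiles$participant_id == participant_id, ]
  if (nrow(serv) == 0 || nrow(prof) == 0) {
    abort(sprintf("no data for participant %s", participant_id),
          class = "snaq_validation_error")
  }
  if (nrow(prof) > 1) {
    prof <- prof[order(prof$condition != "food_and_supplements"), ][1, ]
  }
  serv <- mean_daily_servings_complete(
    serv[c("participant_id", "group", "servings")])
  fg <- dplyr::left_join(serv, targets, by = "group")
  fg$met <- meets_target(fg$servings, fg$group, targets = targets)
  fg$gap <- ifelse(fg$met, 0,
                   ifelse(fg$servings < fg$min_servings,
                          fg$min_servings - fg$servings,
                          fg$servings - fg$max_servings))
  fg <- fg[match(snaq_food_groups(), fg$group),
           c("group", "servings", "target_label", "met", "gap")]

  adequacy <- classify_adequacy(prof, nrv = nrv)
  nn <- snaq_nutrients()
  nutrients <- dplyr::left_join(adequacy, nrv[c("nutrient", "ear", "rdi")],
                                by = "nutrient")
  nutrients$unit <- nn$unit[match(nutrients$nutrient, nn$nutrient)]
  nutrients$pct_ear <- percent_of_ear(nutrients$intake, nutrients$nutrient,
                                      nrv = nrv)
  energy <- prof$energy_kj[1]
  structure(list(
    participant_id = participant_id,
    condition = prof$condition[1],
    energy_kj = energy,
    food_groups = fg,
    nutrients = nutrients[c("nutrient", "intake", "unit", "ear", "rdi",
                            "adequacy", "pct_ear")]
  ), class = "snaq_feedback")
}

#' @rdname build_feedback
#' @param x A `snaq_feedback` object.
#' @param ... Unused.
#' @return `format()` returns a character vector of report lines.
#' @export
format.snaq_feedback <- function(x, ...) {
  adequacy_text <- c(below_ear = "below the EAR",
                     ear_to_below_rdi = "meets the EAR, below the RDI",
                     at_or_above_rdi = "meets the RDI")
  lines <- c(
    sprintf("Dietary feedback for participant %s (%s)",
            x$participant_id, gsub("_", " ", x$condition)),
    sprintf("Estimated energy intake: %.0f kJ/day", x$energy_kj),
    "",
    "Food groups (mean servings/day vs AGTHE pregnancy target):")
  fg <- x$food_groups
  for (i in seq_len(nrow(fg))) {
    status <- if (fg$met[i]) "met" else sprintf("not met (gap %.1f servings)",
                                                fg$gap[i])
    lines <- c(lines, sprintf("  - %s: %.1f vs %s — %s",
                              group_label(fg$group[i]), fg$servings[i],
                              fg$target_label[i], status))
  }
  lines <- c(lines, "", "Key nutrients for pregnancy:")
  nt <- x$nutrients
  for (i in seq_len(nrow(nt))) {
    lines <- c(lines, sprintf(
      "  - %s: %.2f %s/day — %.0f%% of EAR; %s",
      nt$nutrient[i], nt$intake[i], nt$unit[i], nt$pct_ear[i],
      adequacy_text[[as.character(nt$adequacy[i])]]))
  }
  lines
}

#' @rdname build_feedback
#' @export
print.snaq_feedback <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
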