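# Whole-cohort analysis report: the glue the CLI and scripts call.

#' Run the full cohort analysis
#'
#' End-to-end pipeline: validate/exclude records, average to mean daily
#' servings and supplement doses, estimate profiles under the requested
#' supplement condition, classify adequacy and summarise the cohort against
#' AGTHE targets.
#'
#' @param records Records tibble ([read_records()]).
#' @param supplement_uses Optional supplement-use tibble.
#' @param composition Composition table.
#' @param supplements Supplement product table.
#' @param include_supplements Supplement condition for the profiles.
#' @param nrv Nutrient reference table.
#' @param targets AGTHE target table.
#' @param min_days Exclusion threshold ([valid_records()]).
#' @return A list of class `snaq_report`: `excluded`, `servings`,
#'   `profiles`, `adequacy`, `cohort_summary`, and `adequacy_summary`
#'   (per-nutrient n and % per adequacy class).
#' @export
snaq_analyze <- function(records, supplement_uses = NULL,
                         composition = snaq_composition(),
                         supplements = snaq_supplements(),
                         include_supplements = TRUE,
                         nrv = snaq_nrv(), targets = agthe_targets(),
                         min_days = 2) {
  split <- valid_records(records, min_days = min_days)
  if (nrow(split$kept) == 0) {
    abort("no participants left after exclusion",
          class = "snaq_validation_error")
  }
  serv <- mean_daily_servings(split$kept)
  doses <- NULL
  if (!is.null(supplement_uses) && nrow(supplement_uses) > 0) {
    kept_uses <- supplement_uses[
      supplement_uses$participant_id %in% unique(split$kept$participant_id), ]
    if (nrow(kept_uses) > 0) {
      doses <- mean_daily_supplement_doses(kept_uses, split$kept, supplements)
    }
  }
  profiles <- estimate_profiles(serv, doses, composition = composition,
                                supplements = supplements,
                                include_supplements = include_supplements)
  adequacy <- classify_adequacy(profiles, nrv = nrv)
  adequacy_summary <- dplyr::summarise(
    dplyr::group_by(adequacy, .data$nutrient, .data$adequacy,
                    .drop = FALSE),
    n = dplyr::n(), .groups = "drop_last")
  adequacy_summary <- dplyr::mutate(adequacy_summary,
                                    pct = 100 * .data$n / sum(.data$n))
  adequacy_summary <- dplyr::ungroup(adequacy_summary)
  structure(list(
    excluded = split$excluded,
    servings = serv,
    profiles = profiles,
    adequacy = adequacy,
    adequacy_summary = adequacy_summary,
    cohort_summary = summarize_cohort(serv, targets = targets)
  ), class = "snaq_report")
}

#' Write an analysis report as JSON
#'
#' Numbers are written unrounded; rounding belongs to text rendering only.
#'
#' @param report A `snaq_report` ([snaq_analyze()]) or `snaq_agreement`
#'   ([validity_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "snaq_report")) {
    payload <- list(
      schema = "snaqr/report/v1",
      excluded = report$excluded,
      servings = report$servings,
      profiles = report$profiles,
      adequacy = dplyr::mutate(report$adequacy,
                               adequacy = as.character(.data$adequacy)),
      adequacy_summary = dplyr::mutate(
        report$adequacy_summary, adequacy = as.character(.data$adequacy)),
      cohort_summary = as_tibble(report$cohort_summary)
    )
  } else if (inherits(report, "snaq_agreement")) {
    tab <- tidy(report)
    payload <- list(schema = "snaqr/agreement/v1", agreement = tab)
  } else {
    abort("unsupported report object", class = "snaq_validation_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
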