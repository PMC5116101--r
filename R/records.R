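# Multi-day dietary records: reading, validation, exclusion, and averaging
# to per-participant mean daily food-group servings and supplement doses.

#' Read multi-day food-group serving records
#'
#' Records are long format: one row per participant, day and food group,
#' giving the number of standard AGTHE servings consumed. Mixed dishes are
#' assumed already decomposed into food-group servings at data entry; day
#' indices are opaque labels with no calendar semantics.
#'
#' @param path Path to a CSV file with header
#'   `participant_id,day,occasion,group,servings` (`occasion` optional), or
#'   a JSON array of objects with the same field names.
#' @return A tibble with columns `participant_id`, `day`, `occasion`,
#'   `group` (canonical code) and `servings`, in file order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("participant_id,day,occasion,group,servings",
#'              "p1,1,breakfast,Fruit,1.5",
#'              "p1,2,lunch,Grains and cereals,2"), path)
#' read_records(path)
#' @export
read_records <- function(path) {
  tab <- read_table_file(path)
  needed <- c("participant_id", "day", "group", "servings")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("records file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "snaq_schema_error")
  }
  if (!"occasion" %in% names(tab)) tab$occasion <- NA_character_
  key <- tolower(trimws(as.character(tab$group)))
  mapped <- unname(group_aliases()[key])
  if (anyNA(mapped)) {
    bad <- which(is.na(mapped))[1]
    abort(sprintf("row %d: unknown food group label %s", bad,
                  shQuote(tab$group[bad])),
          class = "snaq_parse_error")
  }
  out <- tibble(
    participant_id = as.character(tab$participant_id),
    day = as.integer(tab$day),
    occasion = as.character(tab$occasion),
    group = mapped,
    servings = as.numeric(tab$servings)
  )
  validate_record_values(out)
  out
}

read_table_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_guess()))
  }
}

validate_record_values <- function(records) {
  if (any(is.na(records$day)) || any(records$day < 1)) {
    abort("day must be an integer >= 1", class = "snaq_validation_error")
  }
  if (any(!is.finite(records$servings)) || any(records$servings < 0)) {
    bad <- which(!is.finite(records$servings) | records$servings < 0)
    abort(sprintf("servings must be finite and >= 0 (row %d)", bad[1]),
          class = "snaq_validation_error")
  }
  invisible(records)
}

#' Read supplement-use records
#'
#' @param path Path to a CSV file with header
#'   `participant_id,day,product_id,doses`, or a JSON array of objects with
#'   the same field names.
#' @param supplements Optional supplement product table
#'   ([read_supplements()]); when supplied, every `product_id` must resolve
#'   against it.
#' @return A tibble with columns `participant_id`, `day`, `product_id`,
#'   `doses`.
#' @export
read_supplement_uses <- function(path, supplements = NULL) {
  tab <- read_table_file(path)
  needed <- c("participant_id", "day", "product_id", "doses")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("supplement-use file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "snaq_schema_error")
  }
  out <- tibble(
    participant_id = as.character(tab$participant_id),
    day = as.integer(tab$day),
    product_id = as.character(tab$product_id),
    doses = as.numeric(tab$doses)
  )
  if (any(!is.finite(out$doses)) || any(out$doses < 0)) {
    abort("doses must be finite and >= 0", class = "snaq_validation_error")
  }
  if (!is.null(supplements)) {
    unknown <- setdiff(out$product_id, supplements$product_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown supplement product_id: %s",
                    paste(unknown, collapse = ", ")),
            class = "snaq_validation_error")
    }
  }
  out
}

#' Number of distinct days recorded per participant
#'
#' @param records A records tibble ([read_records()]).
#' @return A tibble with columns `participant_id`, `n_days`.
#' @export
days_recorded <- function(records) {
  dplyr::summarise(dplyr::group_by(records, .data$participant_id),
                   n_days = dplyr::n_distinct(.data$day), .groups = "drop")
}

#' Split records into analysable and excluded participants
#'
#' Participants who recorded fewer than `min_days` distinct days are
#' excluded from analysis; the study convention keeps 2-day records and
#' drops single-day records.
#'
#' @param records A records tibble ([read_records()]).
#' @param min_days Minimum number of distinct recorded days to keep a
#'   participant (default 2).
#' @return A list with elements `kept` (records tibble restricted to kept
#'   participants) and `excluded` (tibble `participant_id`, `n_days`,
#'   `reason`).
#' @examples
#' recs <- tibble::tibble(participant_id = c("a", "a", "b"),
#'                        day = c(1L, 2L, 1L), occasion = NA_character_,
#'                        group = "fruit", servings = 1)
#' valid_records(recs)$excluded
#' @export
valid_records <- function(records, min_days = 2) {
  stopifnot(min_days >= 1)
  if (nrow(records) == 0) {
    return(list(kept = records,
                excluded = tibble(participant_id = character(),
                                  n_days = integer(), reason = character())))
  }
  nd <- days_recorded(records)
  drop <- nd[nd$n_days < min_days, ]
  excluded <- tibble(
    participant_id = drop$participant_id,
    n_days = drop$n_days,
    reason = sprintf("recorded %d day(s); fewer than the %d required",
                     drop$n_days, min_days))
  kept <- records[!records$participant_id %in% drop$participant_id, ]
  list(kept = kept, excluded = excluded)
}

#' Mean daily food-group servings per participant
#'
#' For each participant and food group, total servings over all items are
#' divided by the number of distinct days the participant recorded: a group
#' not eaten on a given day contributes zero to that day, and the
#' denominator is days actually recorded (a 2-day record divides by 2).
#'
#' @param records A records tibble ([read_records()]).
#' @return A tibble with one row per participant and food group (all seven
#'   groups present, zero-filled): `participant_id`, `group`, `servings`
#'   (mean/day), `n_days`.
#' @examples
#' recs <- tibble::tibble(participant_id = "a", day = 1:3,
#'                        occasion = NA_character_, group = "vegetables",
#'                        servings = c(2, 3, 4))
#' mean_daily_servings(recs)
#' @export
mean_daily_servings <- function(records) {
  validate_record_values(records)
  nd <- days_recorded(records)
  totals <- dplyr::summarise(
    dplyr::group_by(records, .data$participant_id, .data$group),
    total = sum(.data$servings), .groups = "drop")
  grid <- tidyr::expand_grid(participant_id = nd$participant_id,
                             group = snaq_food_groups())
  out <- dplyr::left_join(grid, totals, by = c("participant_id", "group"))
  out <- dplyr::left_join(out, nd, by = "participant_id")
  out$servings <- ifelse(is.na(out$total), 0, out$total) / out$n_days
  out[c("participant_id", "group", "servings", "n_days")]
}

#' Mean daily supplement doses per participant
#'
#' Per product, total doses over the record are divided by the number of
#' distinct days the participant recorded (so one dose on 1 of 3 days is
#' 1/3 dose per day). Participants with no supplement use are omitted.
#'
#' @param uses A supplement-use tibble ([read_supplement_uses()]).
#' @param records The matching records tibble, used for the per-participant
#'   day counts.
#' @param supplements Optional product table for `product_id` resolution.
#' @return A tibble with columns `participant_id`, `product_id`,
#'   `doses_per_day`.
#' @export
mean_daily_supplement_doses <- function(uses, records, supplements = NULL) {
  if (!is.null(supplements)) {
    unknown <- setdiff(uses$product_id, supplements$product_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown supplement product_id: %s",
                    paste(unknown, collapse = ", ")),
            class = "snaq_validation_error")
    }
  }
  nd <- days_recorded(records)
  orphan <- setdiff(unique(uses$participant_id), nd$participant_id)
  if (length(orphan) > 0) {
    abort(sprintf("supplement use for participant(s) with no food record: %s",
                  paste(orphan, collapse = ", ")),
          class = "snaq_validation_error")
  }
  totals <- dplyr::summarise(
    dplyr::group_by(uses, .data$participant_id, .data$product_id),
    total = sum(.data$doses), .groups = "drop")
  out <- dplyr::left_join(totals, nd, by = "participant_id")
  out$doses_per_day <- out$total / out$n_days
  out[c("participant_id", "product_id", "doses_per_day")]
}
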