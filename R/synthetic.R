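# Seeded synthetic cohorts: multi-day food-group records, supplement use,
# and a paired noisy "reference method" nutrient profile, with the
# statistical structure of a small pregnancy cohort.

#' Fit a lognormal distribution from median and quartiles
#'
#' Inverts the lognormal quantile function: `mu = log(median)` and
#' `sigma = (log(p75) - log(p25)) / (2 * qnorm(0.75))`. The quartiles of
#' the fitted distribution reproduce the inputs exactly.
#'
#' @param median,p25,p75 Positive reals with `p25 < median < p75`.
#' @return Named numeric vector `c(mu, sigma)` (log scale).
#' @examples
#' fit_lognormal_from_quartiles(3.5, 2.4, 3.9)
#' @export
fit_lognormal_from_quartiles <- function(median, p25, p75) {
  if (!(p25 > 0 && p25 < median && median < p75)) {
    abort("need 0 < p25 < median < p75", class = "snaq_validation_error")
  }
  c(mu = log(median), sigma = (log(p75) - log(p25)) / (2 * qnorm(0.75)))
}

#' Default per-group daily serving distributions
#'
#' Median and interquartile range of daily servings per food group for the
#' emulated cohort of 25 pregnant women (all-participants column of the
#' study-style intake table): grains 4.7 (3.6-6.5), vegetables 2.2
#' (1.2-3.5), fruit 1.7 (0.9-2.5), meat 1.9 (1.4-2.9), dairy 1.8 (1.3-2.7),
#' spreads/oils 2.0 (0.5-3.0), discretionary 3.5 (2.4-3.9).
#'
#' @return A tibble: `group`, `median`, `p25`, `p75`, `zero_prob` (point
#'   mass at zero servings, default 0).
#' @export
default_serving_distributions <- function() {
  tibble(
    group = snaq_food_groups(),
    median = c(4.7, 2.2, 1.7, 1.9, 1.8, 2.0, 3.5),
    p25    = c(3.6, 1.2, 0.9, 1.4, 1.3, 0.5, 2.4),
    p75    = c(6.5, 3.5, 2.5, 2.9, 2.7, 3.0, 3.9),
    zero_prob = 0
  )
}

#' Default reference-method bias factors
#'
#' Multiplicative per-nutrient factors applied to the food-only truth to
#' form the reference method's expected value, chosen to reproduce the
#' direction of inter-method disagreement seen in practice (reference
#' energy lower than the brief method, iron and folate higher).
#'
#' @return Named numeric vector keyed by nutrient code.
#' @export
default_reference_bias <- function() {
  c(energy = 0.92, iron = 1.24, calcium = 0.91, folate_dfe = 1.28,
    iodine = 1.05, zinc = 1.00)
}

#' Configuration for a synthetic cohort
#'
#' @param n_participants Cohort size (default 25, the emulated study size).
#' @param n_days Recorded days per participant (default 3).
#' @param serving_distributions Tibble as
#'   [default_serving_distributions()]: per-group daily-serving lognormal
#'   parameterized by median/p25/p75, plus an optional point mass at zero.
#' @param supplement_use_prob Probability that a participant is a
#'   supplement user; users take the supplement daily (default 0.75).
#' @param supplement_product Single-row supplement product table
#'   ([snaq_supplements()]).
#' @param reference_noise_sigma SD (log scale) of the multiplicative
#'   lognormal error applied independently per nutrient to form the
#'   reference method's food-only estimate (default 0.2).
#' @param reference_bias Named per-nutrient multiplicative bias
#'   ([default_reference_bias()]); use 1 for an unbiased reference.
#' @param composition Composition table used for the true profiles.
#' @param seed Integer seed; the whole simulation is reproducible given it.
#' @return A list of class `snaq_config`.
#' @export
synthetic_config <- function(n_participants = 25,
                             n_days = 3,
                             serving_distributions = default_serving_distributions(),
                             supplement_use_prob = 0.75,
                             supplement_product = snaq_supplements(),
                             reference_noise_sigma = 0.2,
                             reference_bias = default_reference_bias(),
                             composition = snaq_composition(),
                             seed = 1L) {
  stopifnot(n_participants >= 1, n_days >= 1, reference_noise_sigma >= 0,
            supplement_use_prob >= 0, supplement_use_prob <= 1,
            nrow(supplement_product) >= 1)
  sd_tab <- serving_distributions
  bad <- !(sd_tab$p25 < sd_tab$median & sd_tab$median < sd_tab$p75) |
    sd_tab$p25 <= 0
  if (any(bad)) {
    abort(sprintf("invalid quartile parameters for group(s): %s",
                  paste(sd_tab$group[bad], collapse = ", ")),
          class = "snaq_validation_error")
  }
  if (is.null(names(reference_bias)) && length(reference_bias) == 1) {
    reference_bias <- setNames(rep(reference_bias, 6),
                               snaq_nutrients()$nutrient)
  }
  missing_bias <- setdiff(snaq_nutrients()$nutrient, names(reference_bias))
  if (length(missing_bias) > 0) {
    abort(sprintf("reference_bias missing nutrient(s): %s",
                  paste(missing_bias, collapse = ", ")),
          class = "snaq_validation_error")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    serving_distributions = sd_tab,
    supplement_use_prob = supplement_use_prob,
    supplement_product = supplement_product[1, ],
    reference_noise_sigma = reference_noise_sigma,
    reference_bias = reference_bias,
    composition = composition,
    seed = as.integer(seed)
  ), class = "snaq_config")
}

#' Simulate a paired-methods synthetic cohort
#'
#' Per participant, daily servings are drawn independently per group and
#' day from the lognormal fitted to the configured quartiles (with an
#' optional point mass at zero). A participant is a supplement user with
#' probability `supplement_use_prob`; users take one dose of the configured
#' product on every recorded day. The reference method's food-only profile
#' is the participant's true food-only profile (from the mean daily
#' servings and the configured composition) multiplied per nutrient by the
#' configured bias and by lognormal noise `exp(N(0, sigma))`; the
#' with-supplements condition adds the (exactly known) supplement
#' contribution to both methods. Everything is reproducible given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list: `records` (long records tibble), `supplement_uses`,
#'   `reference_profiles` (wide profile tibble, both conditions), `config`.
#' @examples
#' sim <- simulate_cohort(synthetic_config(n_participants = 4, seed = 7))
#' head(sim$records)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "snaq_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("p%02d", seq_len(n))
  sd_tab <- config$serving_distributions
  fits <- purrr::pmap(sd_tab[c("median", "p25", "p75")],
                      function(median, p25, p75)
                        fit_lognormal_from_quartiles(median, p25, p75))

  rows <- vector("list", nrow(sd_tab))
  grid <- tidyr::expand_grid(participant_id = ids,
                             day = seq_len(config$n_days))
  for (g in seq_len(nrow(sd_tab))) {
    m <- nrow(grid)
    draws <- stats::rlnorm(m, meanlog = fits[[g]]["mu"],
                           sdlog = fits[[g]]["sigma"])
    zp <- sd_tab$zero_prob[g]
    if (zp > 0) draws[runif(m) < zp] <- 0
    rows[[g]] <- tibble(
      participant_id = grid$participant_id,
      day = as.integer(grid$day),
      occasion = "daily total",
      group = sd_tab$group[g],
      servings = draws)
  }
  records <- dplyr::arrange(dplyr::bind_rows(rows),
                            .data$participant_id, .data$day,
                            match(.data$group, snaq_food_groups()))

  user <- runif(n) < config$supplement_use_prob
  uses <- tidyr::expand_grid(participant_id = ids[user],
                             day = seq_len(config$n_days))
  supplement_uses <- tibble(
    participant_id = uses$participant_id,
    day = as.integer(uses$day),
    product_id = config$supplement_product$product_id[1],
    doses = if (nrow(uses) > 0) 1 else numeric())

  # true (brief-method) profiles from the generated records
  serv <- mean_daily_servings(records)
  doses <- if (nrow(supplement_uses) > 0) {
    mean_daily_supplement_doses(supplement_uses, records)
  } else NULL
  food <- estimate_profiles(serv, composition = config$composition,
                            include_supplements = FALSE)
  both <- estimate_profiles(serv, doses, composition = config$composition,
                            supplements = config$supplement_product,
                            include_supplements = TRUE)

  cols <- profile_columns()
  bias <- config$reference_bias[nutrient_for_column(cols)]
  noise <- matrix(stats::rnorm(n * length(cols), 0,
                               config$reference_noise_sigma),
                  nrow = n)
  ref_food <- food
  for (j in seq_along(cols)) {
    ref_food[[cols[j]]] <- food[[cols[j]]] * bias[j] * exp(noise[, j])
  }
  supp_add <- as.matrix(both[cols]) - as.matrix(food[cols])
  ref_both <- ref_food
  ref_both$condition <- "food_and_supplements"
  for (j in seq_along(cols)) {
    ref_both[[cols[j]]] <- ref_food[[cols[j]]] + supp_add[, j]
  }
  reference_profiles <- dplyr::bind_rows(ref_both, ref_food)

  list(records = records, supplement_uses = supplement_uses,
       reference_profiles = reference_profiles, config = config)
}

#' Brief-method profiles for a simulated cohort
#'
#' Convenience wrapper running the record-averaging and estimation pipeline
#' on a [simulate_cohort()] result, returning both supplement conditions
#' stacked.
#'
#' @param sim A [simulate_cohort()] result.
#' @param min_days Exclusion threshold passed to [valid_records()].
#' @return A wide profile tibble with both conditions.
#' @export
snaq_profiles <- function(sim, min_days = 2) {
  kept <- valid_records(sim$records, min_days = min_days)$kept
  serv <- mean_daily_servings(kept)
  doses <- if (nrow(sim$supplement_uses) > 0) {
    mean_daily_supplement_doses(sim$supplement_uses, kept)
  } else NULL
  dplyr::bind_rows(
    estimate_profiles(serv, doses, composition = sim$config$composition,
                      supplements = sim$config$supplement_product,
                      include_supplements = TRUE),
    estimate_profiles(serv, composition = sim$config$composition,
                      include_supplements = FALSE))
}

#' Agreement recovery across simulated replicates
#'
#' Runs `simulate_cohort` then `validity_table` for each replicate (and
#' each noise level when `sigmas` is supplied) and summarises the
#' distribution of rho and kappa per nutrient and condition. Replicate
#' seeds are derived deterministically from the config seed.
#'
#' @param config A [synthetic_config()].
#' @param replicates Number of replicates per noise level.
#' @param sigmas Optional numeric vector of `reference_noise_sigma` values
#'   to sweep; default uses the config's single value.
#' @param nrv Nutrient reference table for classification.
#' @return A tibble: `sigma`, `condition`, `nutrient`, `replicates`,
#'   `mean_rho`, `sd_rho`, `mean_kappa`, `sd_kappa`, `prop_degenerate`.
#' @export
recovery_experiment <- function(config, replicates, sigmas = NULL,
                                nrv = snaq_nrv()) {
  stopifnot(replicates >= 1)
  if (is.null(sigmas)) sigmas <- config$reference_noise_sigma
  out <- list()
  for (si in seq_along(sigmas)) {
    per_rep <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$reference_noise_sigma <- sigmas[si]
      cfg$seed <- (config$seed + 7919L * si + r) %% .Machine$integer.max
      sim <- simulate_cohort(cfg)
      vt <- validity_table(snaq_profiles(sim), sim$reference_profiles,
                           nrv = nrv)
      tab <- tidy(vt)
      tab$replicate <- r
      per_rep[[r]] <- tab
    }
    all_reps <- dplyr::bind_rows(per_rep)
    summ <- dplyr::summarise(
      dplyr::group_by(all_reps, .data$condition, .data$nutrient),
      replicates = dplyr::n(),
      mean_rho = mean(.data$rho, na.rm = TRUE),
      sd_rho = sd(.data$rho, na.rm = TRUE),
      mean_kappa = mean(.data$kappa, na.rm = TRUE),
      sd_kappa = sd(.data$kappa, na.rm = TRUE),
      prop_degenerate = mean(.data$degenerate),
      .groups = "drop")
    summ$sigma <- sigmas[si]
    out[[si]] <- summ
  }
  res <- dplyr::bind_rows(out)
  res[c("sigma", "condition", "nutrient", "replicates", "mean_rho",
        "sd_rho", "mean_kappa", "sd_kappa", "prop_degenerate")]
}
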