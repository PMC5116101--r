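# Independent oracles and small fixture builders used across the suite.

# midranks computed by counting, not via rank()
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman rho as Pearson on hand-counted midranks, via the
# product-moment form (independent of the package's sum-of-deviations path)
oracle_spearman <- function(x, y) {
  r <- oracle_midrank(x)
  s <- oracle_midrank(y)
  n <- length(x)
  num <- mean(r * s) - mean(r) * mean(s)
  den <- sqrt((mean(r^2) - mean(r)^2) * (mean(s^2) - mean(s)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# kappa straight from a crosstab of counts
oracle_kappa_from_tab <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

oracle_kappa <- function(a, b, levels = sort(unique(c(a, b)))) {
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  oracle_kappa_from_tab(tab)
}

profile_cols_for_test <- function() snaq_nutrients()$column

# long-format record rows for one participant
make_records <- function(participant_id, days, groups, servings) {
  tibble::tibble(participant_id = participant_id, day = as.integer(days),
                 occasion = NA_character_, group = groups,
                 servings = servings)
}

# a wide profile row with explicit nutrient values (others zero)
make_profile <- function(participant_id, condition = "food_only", ...) {
  vals <- list(...)
  out <- tibble::tibble(participant_id = participant_id,
                        condition = condition, energy_kj = 0, iron_mg = 0,
                        calcium_mg = 0, folate_dfe_ug = 0, iodine_ug = 0,
                        zinc_mg = 0)
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

noise_free_config <- function(seed, n_participants = 25) {
  synthetic_config(
    n_participants = n_participants, seed = seed,
    reference_noise_sigma = 0,
    reference_bias = stats::setNames(rep(1, 6), snaq_nutrients()$nutrient))
}
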