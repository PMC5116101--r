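# Nutrient estimation, adequacy classification, target attainment and
# cohort summaries.

test_that("profiles are serving-weighted sums of the composition fixture", {
  zero <- mean_daily_servings_complete(
    tibble::tibble(participant_id = "a", group = "fruit", servings = 0))
  p0 <- estimate_profiles(zero)
  expect_true(all(as.matrix(p0[profile_cols_for_test()]) == 0))

  one_dairy <- mean_daily_servings_complete(
    tibble::tibble(participant_id = "a", group = "dairy", servings = 1))
  p1 <- estimate_profiles(one_dairy)
  comp <- snaq_composition()
  expect_equal(p1$calcium_mg, comp$calcium_mg[comp$group == "dairy"])
  expect_equal(p1$energy_kj, comp$energy_kj[comp$group == "dairy"])
})

test_that("a hand-summed two-group-plus-supplement profile matches", {
  serv <- mean_daily_servings_complete(
    tibble::tibble(participant_id = "a", group = c("grains", "dairy"),
                   servings = c(2, 1)))
  doses <- tibble::tibble(participant_id = "a",
                          product_id = "prenatal_multi", doses_per_day = 1)
  prof <- estimate_profiles(serv, doses, include_supplements = TRUE)
  # fixture: grains (500 kJ, 0.8 Fe, 20 Ca, 30 DFE, 5 I, 0.7 Zn);
  # dairy (550, 0.05, 280, 10, 30, 0.6);
  # supplement (0 kJ, 60 Fe, 125 Ca, 800*1.7 DFE, 220 I, 11 Zn)
  expect_equal(prof$energy_kj, 2 * 500 + 550)
  expect_equal(prof$iron_mg, 2 * 0.8 + 0.05 + 60)
  expect_equal(prof$calcium_mg, 2 * 20 + 280 + 125)
  expect_equal(prof$folate_dfe_ug, 2 * 30 + 10 + 1360)
  expect_equal(prof$iodine_ug, 2 * 5 + 30 + 220)
  expect_equal(prof$zinc_mg, 2 * 0.7 + 0.6 + 11)
  expect_equal(prof$condition, "food_and_supplements")

  bad <- tibble::tibble(participant_id = "a", product_id = "unknown",
                        doses_per_day = 1)
  expect_error(estimate_profiles(serv, bad, include_supplements = TRUE),
               class = "snaq_validation_error")
})

test_that("supplements never decrease a nutrient and leave energy alone", {
  set.seed(21)
  serv <- mean_daily_servings_complete(
    tidyr::expand_grid(participant_id = paste0("p", 1:6),
                       group = snaq_food_groups()) |>
      dplyr::mutate(servings = runif(42, 0, 4)))
  doses <- tibble::tibble(participant_id = paste0("p", 1:3),
                          product_id = "prenatal_multi",
                          doses_per_day = c(1, 0.5, 1 / 3))
  with_s <- estimate_profiles(serv, doses, include_supplements = TRUE)
  without <- estimate_profiles(serv, doses, include_supplements = FALSE)
  for (col in profile_cols_for_test()) {
    expect_true(all(with_s[[col]] >= without[[col]]))
  }
  expect_equal(with_s$energy_kj, without$energy_kj)
})

test_that("percent of EAR reproduces the folate worked example", {
  expect_equal(percent_of_ear(100, "folate_dfe"), 19)
  expect_equal(percent_of_ear(0, "iron"), 0)
  expect_equal(percent_of_ear(520, "folate_dfe"), 100)
  expect_equal(percent_of_ear(100, "folate_dfe", digits = NULL),
               100 * 100 / 520)
  expect_error(percent_of_ear(100, "energy"),
               class = "snaq_unsupported_nutrient")
})

test_that("adequacy classification honours the <EAR / >=EAR / >=RDI bounds", {
  prof <- make_profile("a", iron_mg = 9.5, zinc_mg = 11, calcium_mg = 840)
  cls <- classify_adequacy(prof)
  get <- function(n) as.character(cls$adequacy[cls$nutrient == n])
  expect_equal(get("iron"), "below_ear")
  expect_equal(get("zinc"), "at_or_above_rdi")      # exactly the RDI
  expect_equal(get("calcium"), "ear_to_below_rdi")  # exactly the EAR
  expect_false("energy" %in% cls$nutrient)

  # exactly the iron EAR
  cls2 <- classify_adequacy(make_profile("a", iron_mg = 22))
  expect_equal(as.character(cls2$adequacy[cls2$nutrient == "iron"]),
               "ear_to_below_rdi")
})

test_that("classification is monotone and partitions intakes", {
  nrv <- snaq_nrv()
  set.seed(31)
  for (nut in nrv$nutrient) {
    ear <- nrv$ear[nrv$nutrient == nut]
    rdi <- nrv$rdi[nrv$nutrient == nut]
    x <- sort(c(runif(40, 0, 2 * rdi), ear, rdi))
    cls <- snaqr:::classify_intake(x, ear, rdi)
    expect_false(anyNA(cls))
    expect_true(all(diff(as.integer(cls)) >= 0))
    expect_equal(as.integer(cls[x < ear]),
                 rep(1L, sum(x < ear)))
    expect_equal(as.integer(cls[x >= rdi]),
                 rep(3L, sum(x >= rdi)))
  }
})

test_that("target attainment is inclusive at the boundaries", {
  expect_true(meets_target(2, "fruit"))
  expect_false(meets_target(1.99, "fruit"))
  expect_false(meets_target(3.5, "discretionary"))  # exceeds 0-2.5 range
  expect_true(meets_target(2.5, "discretionary"))
  expect_true(meets_target(8.5, "grains"))
  expect_error(meets_target(1, "sweets"), class = "snaq_validation_error")
})

test_that("cohort summary uses n-1 SD and linear-interpolation quartiles", {
  serv <- tibble::tibble(
    participant_id = paste0("p", 1:4),
    group = "fruit", servings = c(1, 2, 3, 4))
  sm <- summarize_cohort(mean_daily_servings_complete(serv))
  fruit <- sm[sm$group == "fruit", ]
  expect_equal(fruit$median, 2.5)
  expect_equal(fruit$p25, 1.75)
  expect_equal(fruit$p75, 3.25)
  expect_equal(fruit$sd, sd(c(1, 2, 3, 4)))
  expect_equal(fruit$n_meeting, 3)   # 2, 3 and 4 meet the >=2 target
  expect_equal(fruit$pct_meeting, 75)

  single <- summarize_cohort(mean_daily_servings_complete(
    tibble::tibble(participant_id = "a", group = "fruit", servings = 2)))
  expect_true(is.na(single$sd[single$group == "fruit"]))
  expect_equal(single$pct_meeting[single$group == "fruit"], 100)

  expect_error(summarize_cohort(serv[0, ]), class = "snaq_validation_error")
})

test_that("adequacy class percentages sum to 100 per nutrient", {
  sim <- simulate_cohort(synthetic_config(seed = 9, n_participants = 12))
  report <- snaq_analyze(sim$records, sim$supplement_uses)
  sums <- dplyr::summarise(
    dplyr::group_by(report$adequacy_summary, nutrient),
    total = sum(pct))
  expect_equal(sums$total, rep(100, nrow(sums)))
})
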