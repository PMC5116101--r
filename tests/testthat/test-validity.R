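# Spearman rho, Cohen kappa, energy binning, interpretation bands and the
# agreement table.

test_that("spearman handles perfect monotone and tied data", {
  x <- c(2, 5, 9, 11, 30)
  up <- spearman_rho(x, x^3 + 1)
  expect_equal(up$rho, 1)
  expect_equal(up$p, 0)   # |rho| = 1: below any representable p
  down <- spearman_rho(x, rev(x))
  expect_equal(down$rho, -1)

  tied <- spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4))
  expect_equal(tied$rho, oracle_spearman(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               tolerance = 1e-12)
  # and against the established implementation
  expect_equal(tied$rho,
               unname(stats::cor(c(1, 2, 2, 4), c(3, 1, 4, 4),
                                 method = "spearman")))

  const <- spearman_rho(c(1, 1, 1), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
  expect_error(spearman_rho(1:3, 1:4), class = "snaq_validation_error")
})

test_that("spearman t-approximation p matches cor.test on untied data", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- spearman_rho(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("exact permutation p enumerates the null", {
  # n = 3, identity: only identity and reversal reach |rho| = 1
  res <- spearman_rho(1:3, c(10, 20, 30), method = "exact")
  expect_equal(res$rho, 1)
  expect_equal(res$p, 2 / 6)
  expect_error(spearman_rho(1:9, 1:9, method = "exact"),
               class = "snaq_validation_error")
})

test_that("spearman is symmetric and invariant to increasing transforms", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    a <- spearman_rho(x, y)
    expect_equal(a$rho, spearman_rho(y, x)$rho, tolerance = 1e-12)
    expect_equal(a$rho, spearman_rho(exp(x), y)$rho, tolerance = 1e-12)
    expect_equal(a$rho, spearman_rho(x, 3 * y + 2)$rho, tolerance = 1e-12)
  }
})

test_that("kappa matches the direct crosstab formula on a toy table", {
  # crosstab ((20, 5), (10, 15)): p_o = .7, p_e = .5, kappa = .4
  a <- rep(c("lo", "lo", "hi", "hi"), c(20, 5, 10, 15))
  b <- rep(c("lo", "hi", "lo", "hi"), c(20, 5, 10, 15))
  res <- cohen_kappa(a, b, levels = c("lo", "hi"))
  expect_equal(res$kappa, 0.4, tolerance = 1e-12)
  expect_equal(res$p_o, 0.7)
  expect_equal(res$p_e, 0.5)
  expect_equal(unname(res$crosstab),
               matrix(c(20, 10, 5, 15), 2))
  expect_equal(res$kappa, oracle_kappa_from_tab(res$crosstab),
               tolerance = 1e-12)
})

test_that("kappa basics: identity, symmetry, degeneracy, bounds", {
  a <- c("x", "x", "y", "z", "y")
  expect_equal(cohen_kappa(a, a)$kappa, 1)

  b <- c("x", "y", "y", "z", "x")
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa,
               tolerance = 1e-12)

  con <- cohen_kappa(rep("x", 5), rep("x", 5), levels = c("x", "y"))
  expect_true(con$degenerate)
  expect_true(is.na(con$kappa))
  # one-sided constancy is also degenerate
  expect_true(cohen_kappa(rep("x", 5), c("x", "y", "x", "y", "x"))$degenerate)

  expect_error(cohen_kappa(a, b[-1]), class = "snaq_validation_error")

  set.seed(61)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    u <- sample(letters[1:3], n, replace = TRUE)
    v <- sample(letters[1:3], n, replace = TRUE)
    res <- cohen_kappa(u, v)
    if (!res$degenerate) expect_lte(res$kappa, 1)
  }
})

test_that("linear weights reward near-diagonal agreement", {
  a <- rep(c("low", "mid", "high"), each = 4)
  b <- c(rep("mid", 4), rep("low", 4), rep("high", 4))
  un <- cohen_kappa(a, b)
  lw <- cohen_kappa(a, b, weights = "linear")
  expect_gt(lw$kappa, un$kappa)
})

test_that("energy bins are half-open 1000 kJ categories anchored at zero", {
  expect_equal(bin_energy(0), 0L)
  expect_equal(bin_energy(999.999), 0L)
  expect_equal(bin_energy(1000), 1L)
  # the two methods' cohort medians land in different bins
  expect_equal(bin_energy(c(8418.33, 7738.89)), c(8L, 7L))
  expect_equal(bin_energy(1500, width = 500), 3L)
})

test_that("kappa interpretation bands follow the conventional ladder", {
  expect_equal(interpret_kappa(0.488), "moderate")
  expect_equal(interpret_kappa(0.803), "substantial")  # rounds to .80
  expect_equal(interpret_kappa(0.60), "moderate")
  expect_equal(interpret_kappa(0.61), "substantial")
  expect_equal(interpret_kappa(-0.068), "poor")
  expect_equal(interpret_kappa(c(0.1, 0.3, 0.95)),
               c("slight", "fair", "almost perfect"))
})

test_that("self-agreement gives rho 1 and kappa 1 or degenerate", {
  sim <- simulate_cohort(synthetic_config(seed = 12))
  prof <- snaq_profiles(sim)
  vt <- tidy(validity_table(prof, prof))
  expect_equal(vt$rho, rep(1, nrow(vt)))
  expect_true(all(vt$degenerate | abs(vt$kappa - 1) < 1e-12))
})

test_that("an all-below-EAR nutrient is degenerate, as for food-only iron", {
  set.seed(71)
  n <- 25
  a <- make_profile(sprintf("p%02d", 1:n),
                    iron_mg = runif(n, 7.7, 10.85),
                    calcium_mg = runif(n, 600, 1200),
                    folate_dfe_ug = runif(n, 200, 700),
                    iodine_ug = runif(n, 80, 250),
                    zinc_mg = runif(n, 8, 13),
                    energy_kj = runif(n, 6000, 10000))
  b <- a
  b$iron_mg <- runif(n, 8.5, 13.7)  # reference also everywhere below 22
  vt <- tidy(validity_table(a, b))
  iron <- vt[vt$nutrient == "iron", ]
  expect_true(iron$degenerate)
  expect_true(is.na(iron$kappa))
  expect_false(is.na(iron$rho))
})

test_that("validity table checks participants and reports margins", {
  sim <- simulate_cohort(synthetic_config(seed = 13, n_participants = 10))
  prof <- snaq_profiles(sim)
  refp <- sim$reference_profiles

  vt <- validity_table(prof, refp)
  expect_s3_class(vt, "snaq_agreement")
  expect_equal(nrow(vt), 12)  # 6 nutrients x 2 conditions
  for (i in seq_len(nrow(vt))) {
    expect_equal(sum(vt$crosstab[[i]]), vt$n[i])
    m <- vt$margins[[i]]
    expect_equal(sum(m$n[m$method == "a"]), vt$n[i])
    expect_equal(sum(m$pct[m$method == "b"]), 100)
  }

  mismatched <- refp[refp$participant_id != "p01", ]
  expect_error(validity_table(prof, mismatched),
               class = "snaq_validation_error")

  gl <- glance(vt)
  expect_equal(gl$n_rows, 12)
  md <- format_validity_markdown(vt)
  expect_true(any(grepl("^\\| Condition", md)))
})
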