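# Inter-method agreement between the brief analysis and a reference
# nutrient analysis: Spearman rank correlation (midranks, t-approximation
# p-value, exact permutation option), unweighted Cohen kappa with the null
# asymptotic z-test, 1000-kJ energy binning, and the table-shaped report.

# midranks: average rank for ties
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with midranks
#'
#' Ties receive midranks in each vector; rho is the Pearson correlation of
#' the two rank vectors, computed from the explicit sum formula. The
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (the convention of mainstream statistics software); `|rho| = 1` yields a
#' p-value of 0, i.e. below the machine floor. `method = "exact"` instead
#' enumerates all permutations of one argument (only for `n <= 8`) and
#' returns the exact two-sided permutation p-value
#' `P(|rho_perm| >= |rho_obs|)`.
#'
#' A constant vector has no rank variance: rho is undefined and the result
#' is flagged `degenerate`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite.
#' @param method `"t"` (default) or `"exact"`.
#' @return A list: `rho`, `p`, `n`, `degenerate`, `method`.
#' @examples
#' spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4))
#' @export
spearman_rho <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "snaq_validation_error")
  }
  n <- length(x)
  if (n < 3) abort("need n >= 3", class = "snaq_validation_error")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("values must be finite", class = "snaq_validation_error")
  }
  rx <- midrank(x)
  ry <- midrank(y)
  rho <- rank_pearson(rx, ry)
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE,
                method = method))
  }
  if (method == "exact") {
    if (n > 8) abort("exact permutation p only supported for n <= 8",
                     class = "snaq_validation_error")
    perms <- permutations(n)
    stat <- apply(perms, 1, function(idx) rank_pearson(rx, ry[idx]))
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
  } else {
    if (1 - rho^2 <= 0) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE, method = method)
}

# Pearson correlation from explicit sums; NA if either vector is constant
rank_pearson <- function(rx, ry) {
  n <- length(rx)
  dx <- rx - sum(rx) / n
  dy <- ry - sum(ry) / n
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sxx * syy)
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  res <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    res[rows, 1] <- i
    res[rows, -1] <- sub + (sub >= i)
  }
  res
}

#' Cohen kappa for agreement between two classifications
#'
#' Unweighted by default: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` and chance agreement `p_e` from the two marginal
#' distributions. The two-sided p-value comes from the null asymptotic
#' z-test `z = kappa / SE0` with
#' `SE0 = sqrt((p_e + p_e^2 - sum_i pr_i * pc_i * (pr_i + pc_i)) /
#' (n * (1 - p_e)^2))` (`pr`, `pc` the row/column margins) — the standard
#' large-sample null standard error. If either classification is constant
#' (a single distinct label) no statistic is computed and the result is
#' flagged `degenerate`, reported as "Constants (no statistics computed)".
#'
#' `weights = "linear"` applies linear disagreement weights
#' `w_ij = 1 - |i - j| / (k - 1)` to both `p_o` and `p_e` (no p-value is
#' computed for the weighted statistic).
#'
#' @param a,b Equal-length vectors of class labels (factors share their
#'   level sets; otherwise the sorted union of observed labels is used).
#' @param levels Optional explicit label set defining the crosstab axes.
#' @param weights `"none"` (default) or `"linear"`.
#' @return A list: `kappa`, `p`, `z`, `n`, `p_o`, `p_e`, `degenerate`,
#'   `crosstab` (k x k count matrix, rows = `a`, cols = `b`).
#' @examples
#' cohen_kappa(c("x", "x", "y"), c("x", "y", "y"))
#' @export
cohen_kappa <- function(a, b, levels = NULL, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) {
    abort("a and b must have equal length", class = "snaq_validation_error")
  }
  n <- length(a)
  if (n < 2) abort("need n >= 2", class = "snaq_validation_error")
  if (is.null(levels)) {
    if (is.factor(a) && is.factor(b) && identical(levels(a), levels(b))) {
      levels <- levels(a)
    } else {
      levels <- sort(unique(c(as.character(a), as.character(b))))
    }
  }
  fa <- factor(as.character(a), levels = levels)
  fb <- factor(as.character(b), levels = levels)
  if (anyNA(fa) || anyNA(fb)) {
    abort("labels outside the supplied level set", class = "snaq_validation_error")
  }
  tab <- table(fa, fb)
  dimnames(tab) <- list(a = levels, b = levels)
  if (length(unique(as.character(a))) < 2 ||
      length(unique(as.character(b))) < 2) {
    return(list(kappa = NA_real_, p = NA_real_, z = NA_real_, n = n,
                p_o = NA_real_, p_e = NA_real_, degenerate = TRUE,
                crosstab = unclass(tab)))
  }
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  k <- length(levels)
  if (weights == "linear") {
    w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    p_o <- sum(w * tab) / n
    p_e <- sum(w * outer(pr, pc))
    kap <- (p_o - p_e) / (1 - p_e)
    return(list(kappa = kap, p = NA_real_, z = NA_real_, n = n, p_o = p_o,
                p_e = p_e, degenerate = FALSE, crosstab = unclass(tab)))
  }
  p_o <- sum(diag(tab)) / n
  p_e <- sum(pr * pc)
  kap <- (p_o - p_e) / (1 - p_e)
  se0 <- sqrt((p_e + p_e^2 - sum(pr * pc * (pr + pc))) / (n * (1 - p_e)^2))
  z <- kap / se0
  p <- 2 * pnorm(-abs(z))
  list(kappa = kap, p = p, z = z, n = n, p_o = p_o, p_e = p_e,
       degenerate = FALSE, crosstab = unclass(tab))
}

#' Bin daily energy intakes into fixed-width categories
#'
#' Energy agreement is assessed on categories of 1000 kJ: bins are
#' half-open intervals `[k*width, (k+1)*width)` anchored at 0, so the bin
#' index is `floor(value / width)`.
#'
#' @param values Numeric vector of kJ/day, `>= 0`.
#' @param width Bin width in kJ (default 1000).
#' @return Integer vector of bin indices.
#' @examples
#' bin_energy(c(0, 999.9, 1000, 7738.89, 8418.33))
#' @export
bin_energy <- function(values, width = 1000) {
  stopifnot(width > 0, all(values >= 0))
  as.integer(floor(values / width))
}

#' Interpret a kappa value on the Landis-Koch ladder
#'
#' Bands (applied to kappa rounded to 2 decimals, the precision at which
#' the bands are conventionally stated): below 0 poor, 0-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00
#' almost perfect. Endpoints are inclusive, so 0.60 is moderate and 0.803
#' (rounding to 0.80) is substantial.
#'
#' @param kappa Numeric vector in `[-1, 1]` (NA allowed).
#' @return Character vector of band labels.
#' @examples
#' interpret_kappa(c(0.488, 0.803, 0.6, -0.068))
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(all(is.na(kappa) | (kappa >= -1 & kappa <= 1)))
  kr <- round(kappa, 2)
  dplyr::case_when(
    is.na(kr) ~ NA_character_,
    kr < 0 ~ "poor",
    kr <= 0.20 ~ "slight",
    kr <= 0.40 ~ "fair",
    kr <= 0.60 ~ "moderate",
    kr <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Relative-validity table between two methods
#'
#' For each nutrient and supplement condition present in both profile
#' tables: Spearman rho (with p) on the raw intakes, and Cohen kappa (with
#' p) on the adequacy classes — except energy, where kappa is computed on
#' 1000-kJ intake bins since energy has no EAR/RDI. When either method's
#' classification is constant the kappa cell is degenerate
#' ("Constants (no statistics computed)").
#'
#' @param profiles_a Wide profile tibble for the brief method
#'   ([estimate_profiles()]), one row per participant and condition.
#' @param profiles_b Same-shaped tibble for the reference method, covering
#'   the same participants.
#' @param nrv Nutrient reference table ([snaq_nrv()]).
#' @param energy_bin_kj Width of the energy agreement bins.
#' @return A tibble of class `snaq_agreement`, one row per condition and
#'   nutrient: `condition`, `nutrient`, `n`, `rho`, `rho_p`, `kappa`,
#'   `kappa_p`, `degenerate`, `agreement` (band label), `crosstab`
#'   (list-column of count matrices) and `margins` (list-column: per-class
#'   n and % for each method).
#' @export
validity_table <- function(profiles_a, profiles_b, nrv = snaq_nrv(),
                           energy_bin_kj = 1000) {
  conditions <- intersect(intersect(unique(profiles_a$condition),
                                    unique(profiles_b$condition)),
                          condition_levels())
  if (length(conditions) == 0) {
    abort("no common supplement condition between the two profile tables",
          class = "snaq_validation_error")
  }
  rows <- list()
  for (cond in conditions) {
    a <- profiles_a[profiles_a$condition == cond, ]
    b <- profiles_b[profiles_b$condition == cond, ]
    if (!setequal(a$participant_id, b$participant_id) ||
        anyDuplicated(a$participant_id) || anyDuplicated(b$participant_id)) {
      abort("participant sets differ between the two methods",
            class = "snaq_validation_error")
    }
    b <- b[match(a$participant_id, b$participant_id), ]
    for (col in profile_columns()) {
      nut <- nutrient_for_column(col)
      x <- a[[col]]
      y <- b[[col]]
      sp <- spearman_rho(x, y)
      if (nut == "energy") {
        ca <- as.character(bin_energy(x, width = energy_bin_kj))
        cb <- as.character(bin_energy(y, width = energy_bin_kj))
        lev <- as.character(sort(unique(as.integer(c(ca, cb)))))
      } else {
        ear <- nrv$ear[nrv$nutrient == nut]
        rdi <- nrv$rdi[nrv$nutrient == nut]
        ca <- classify_intake(x, ear, rdi)
        cb <- classify_intake(y, ear, rdi)
        lev <- adequacy_levels()
      }
      kp <- cohen_kappa(ca, cb, levels = lev)
      margins <- tibble(
        class = rep(lev, 2),
        method = rep(c("a", "b"), each = length(lev)),
        n = c(as.integer(rowSums(kp$crosstab)),
              as.integer(colSums(kp$crosstab))))
      margins$pct <- 100 * margins$n / length(x)
      rows[[length(rows) + 1]] <- tibble(
        condition = cond, nutrient = nut, n = length(x),
        rho = sp$rho, rho_p = sp$p,
        kappa = kp$kappa, kappa_p = kp$p,
        degenerate = sp$degenerate || kp$degenerate,
        agreement = interpret_kappa(kp$kappa),
        crosstab = list(kp$crosstab), margins = list(margins))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("snaq_agreement", class(out))
  out
}

#' @rdname validity_table
#' @param x A `snaq_agreement` table.
#' @param ... Unused.
#' @method tidy snaq_agreement
#' @export
tidy.snaq_agreement <- function(x, ...) {
  out <- as_tibble(x)
  out$crosstab <- NULL
  out$margins <- NULL
  out
}

#' @rdname validity_table
#' @method glance snaq_agreement
#' @export
glance.snaq_agreement <- function(x, ...) {
  tab <- tidy(x)
  tibble(
    n_rows = nrow(tab),
    n_degenerate = sum(tab$degenerate),
    rho_min = min(tab$rho, na.rm = TRUE),
    rho_max = max(tab$rho, na.rm = TRUE),
    kappa_min = suppressWarnings(min(tab$kappa, na.rm = TRUE)),
    kappa_max = suppressWarnings(max(tab$kappa, na.rm = TRUE))
  )
}

#' @rdname validity_table
#' @param object A `snaq_agreement` table.
#' @method autoplot snaq_agreement
#' @export
autoplot.snaq_agreement <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df[c("condition", "nutrient", "rho", "kappa")],
                              cols = c("rho", "kappa"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$nutrient,
                                     shape = .data$statistic)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$condition) +
    ggplot2::xlim(-1, 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "Agreement statistic", y = NULL,
                  title = "Inter-method agreement by nutrient") +
    ggplot2::theme_minimal()
}

#' Render a validity table as markdown
#'
#' @param x A `snaq_agreement` table.
#' @param digits Digits for rho/kappa.
#' @return Character vector of markdown lines.
#' @export
format_validity_markdown <- function(x, digits = 3) {
  tab <- tidy(x)
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                  format = "f"))
  fmt_p <- function(p) ifelse(is.na(p), "",
                              ifelse(p < 0.001, "<.001",
                                     sub("^0", "", formatC(p, digits = 3,
                                                           format = "f"))))
  lines <- c("| Condition | Nutrient | n | rho (P) | kappa (P) | Agreement |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tab))) {
    kcell <- if (tab$degenerate[i] && is.na(tab$kappa[i])) {
      "Constants (no statistics computed)"
    } else {
      sprintf("%s (%s)", fmt(tab$kappa[i]), fmt_p(tab$kappa_p[i]))
    }
    lines <- c(lines, sprintf(
      "| %s | %s | %d | %s (%s) | %s | %s |",
      tab$condition[i], tab$nutrient[i], tab$n[i],
      fmt(tab$rho[i]), fmt_p(tab$rho_p[i]), kcell,
      ifelse(is.na(tab$agreement[i]), "", tab$agreement[i])))
  }
  lines
}
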