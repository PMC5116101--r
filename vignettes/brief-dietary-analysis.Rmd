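---
title: "Brief food-group dietary analysis and its relative validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brief food-group dietary analysis and its relative validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snaqr)
```

## The problem

Full nutrient analysis of a prospective dietary record — coding every food
and drink item against a food composition database — is accurate but slow,
and impractical when a dietitian wants to give feedback within days.
A brief alternative is to score the record only in *food-group servings*:
the analyst assigns each item a number of standard servings of one of the
seven Australian Guide to Healthy Eating (AGTHE) groups (grains, vegetables,
fruit, lean meat and alternatives, dairy, unsaturated spreads/oils, and
energy-dense nutrient-poor "discretionary" foods), and nutrient intake is
then estimated from the *average* nutrient composition of one standard
serving of each group, plus any micronutrient supplements taken.

snaqr implements that brief method for pregnancy, where the nutrients of
greatest concern are iron, calcium, folate (as dietary folate equivalents,
DFE), iodine and zinc, together with total energy. It also implements the
relative-validity analysis used to evaluate such a method against a full
item-level reference analysis: Spearman rank correlation on the raw
intakes and Cohen kappa on adequacy (or energy-bin) classifications.

## The model

For participant $i$, let $s_{ig}$ be the mean daily servings of group $g$
(total servings over the record divided by the number of distinct days
recorded) and $c_{gk}$ the composition table's amount of nutrient $k$ per
standard serving of $g$. With mean daily supplement doses $d_{ip}$ of
products with per-dose content $u_{pk}$, the estimated daily intake is

$$\hat{y}_{ik} = \sum_{g} s_{ig}\, c_{gk} \;+\; \mathbb{1}[\text{supplements included}] \sum_{p} d_{ip}\, u_{pk}.$$

Supplements are treated as energy-free, so the energy estimate is identical
with and without supplements. Synthetic folic acid in supplements is
converted to DFE at 1.7 µg DFE per µg before entering the sum (the standard
nutrient-reference convention for fortificant folic acid; the factor is an
argument of `read_supplements()`).

Each micronutrient intake is classified against the pregnancy reference
values (defaults: EAR 22/840/520/160/9 and RDI 27/1000/600/220/11 for
iron/calcium/folate/iodine/zinc) into three ordered classes taken literally
from the reporting convention: `below_ear` ($y < \mathrm{EAR}$),
`ear_to_below_rdi` ($\mathrm{EAR} \le y < \mathrm{RDI}$) and
`at_or_above_rdi` ($y \ge \mathrm{RDI}$). Intakes are classified unrounded.
Food-group intake is compared with the AGTHE pregnancy targets
(grains ≥ 8.5, vegetables ≥ 5, fruit ≥ 2, meat ≥ 3.5, dairy ≥ 2.5
servings/day; spreads/oils and discretionary foods within 0–2.5), range
targets inclusive at both ends.

## Agreement statistics

`spearman_rho()` assigns midranks to ties and computes the Pearson
correlation of the rank vectors from the explicit sum formula. The
two-sided p-value uses $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees
of freedom, matching mainstream statistical software at cohort sizes around
25; $|\rho| = 1$ is reported as $p = 0$ (below the machine floor). An exact
permutation p-value is available for $n \le 8$; it exists mainly as an
independent oracle for the approximation and for very small studies.

`cohen_kappa()` is unweighted by default:
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the two margins. The
p-value is the null asymptotic z-test
$z = \kappa / \widehat{SE}_0$,
$\widehat{SE}_0 = \sqrt{\left(p_e + p_e^2 - \sum_i p_{i\cdot} p_{\cdot i}(p_{i\cdot} + p_{\cdot i})\right) / \left(n (1-p_e)^2\right)}$,
the convention of the software typically used for such analyses. Exact
continuity-correction behaviour of specific SPSS builds is not replicated;
last-digit differences in p-values are possible. A linear-weights option
exists but is off by default, since the method under evaluation is
conventionally reported with the unweighted statistic.

If either method classifies every participant identically (as happens for
food-only iron in a pregnancy cohort, where nobody reaches the 22 mg EAR),
kappa is undefined: the result is flagged degenerate and rendered as
"Constants (no statistics computed)", never as a numeric 0 or 1.

Energy has no EAR/RDI, so energy agreement uses half-open 1000 kJ bins
anchored at 0 (`bin_energy()`, bin $= \lfloor y/1000 \rfloor$); the width
is configurable, the origin deliberately fixed at 0 since only the width is
conventionally stated.

Kappa values are interpreted on the Landis–Koch ladder (poor / slight /
fair / moderate / substantial / almost perfect) applied to kappa rounded to
two decimals — the precision at which the band edges are stated. This makes
the bands genuinely inclusive at .60 and .80 and classifies 0.803 as
substantial, consistent with how such values are reported in practice.

## The synthetic cohort generator

The unpublished participant records cannot ship with the package, so
`simulate_cohort()` generates cohorts with the same statistical skeleton:

* **Serving distributions.** Daily servings per group are drawn i.i.d.
  per participant, group and day from a lognormal parameterized by median
  and quartiles (`fit_lognormal_from_quartiles()`: $\mu = \ln m$,
  $\sigma = (\ln p_{75} - \ln p_{25}) / (2 z_{0.75})$). Defaults are the
  observed cohort medians/IQRs (e.g. discretionary 3.5 (2.4–3.9)
  servings/day). Two caveats are intentional properties of this
  parameterization. First, three quartiles over-determine a two-parameter
  distribution unless they are log-symmetric ($p_{25} p_{75} = m^2$): the
  fit preserves the median and the quartile *ratio* exactly, and only
  approximates asymmetric quartile pairs. Second, the quartiles describe
  the *daily* draw; the distribution of 3-day participant means is
  slightly right-shifted (by roughly $e^{\sigma^2/6}$ on the median).
  An optional point mass at zero servings per group emulates
  never-consumers (e.g. fruit in a subgroup whose 25th percentile is 0).
* **Supplements.** Each participant is a supplement user with probability
  0.75 (a typical prenatal-supplement prevalence in Australian pregnancy
  cohorts; the emulated study does not report its prevalence); users take
  one dose of an Elevit-like prenatal product daily. The shipped product
  table is synthetic and clearly labelled as such.
* **Reference method.** The reference profile is the participant's true
  food-only profile multiplied, per nutrient, by a fixed bias factor and
  by independent lognormal noise $e^{N(0, \sigma)}$ ($\sigma = 0.2$ by
  default). Default biases (energy 0.92, iron 1.24, calcium 0.91, folate
  1.28, iodine 1.05, zinc 1.00) give the reference method the direction of
  disagreement seen in practice: lower energy, higher iron and folate.
  The supplement contribution, which both methods observe exactly, is
  added identically to both sides. Multiplicative noise on nutrients (not
  on servings) is the simplest error model that produces rank-preserving,
  magnitude-shifted disagreement; $\sigma$ and the biases are free
  parameters of the simulation, not estimates of any real method's error.

At $\sigma = 0$ with unit bias the pipeline must recover agreement exactly
($\rho = 1$, $\kappa = 1$ or degenerate) — the test suite asserts this over
50 replicates — and mean $\rho$ must fall strictly as $\sigma$ grows
(checked over 50 replicates at $\sigma \in \{0.05, 0.2, 0.5\}$ with
25-participant cohorts, the emulated study size). These problem sizes keep
the whole suite comfortably fast while leaving the Monte-Carlo conclusions
unambiguous at the tested noise separations.

What passing these tests shows — and does not show. The simulator emulates
serving distributions, supplement prevalence and a tunable inter-method
error. It does not emulate item-level coding differences, under-reporting,
day-of-week effects, or correlated portion-estimation error between the two
methods (in the motivating study one dietitian analysed the records with
both methods, so their errors are unlikely to be independent). Perfect
behaviour on synthetic cohorts therefore validates the *computation*, not
the field accuracy of the brief method itself.

## The composition fixture

The per-serving composition table embedded in the original tool (averaged
from AUSNUT 2007) was never published. The package ships
`composition_synthetic.csv`: per-serving energies at the AGTHE
standard-serving values (grains 500 kJ, vegetables 225, fruit 350, meat
550, dairy 550, spreads/oils 250, discretionary 600) and micronutrient
densities chosen so that the observed median servings imply food-only
nutrient totals of realistic magnitude (≈ 8 MJ energy, ≈ 10 mg iron,
≈ 870 mg calcium, ≈ 350 µg DFE, ≈ 110 µg iodine, ≈ 11 mg zinc per day).
It is a documented stand-in, validated on load against per-group energy
bands (warning by default, error with `strict = TRUE`, tolerance
configurable), and replaceable via `read_composition()`. How the original
tool averaged individual foods into group means (weighted or not, which
foods) is unknown; the fixture makes no claim to match it.

## Degenerate inputs and numerical choices

* Quantiles in cohort summaries use linear interpolation between order
  statistics (R's default type 7), the common default of mainstream
  statistics packages; SDs use the $n-1$ denominator and a
  single-participant SD is `NA`, never 0.
* Exclusion: participants with fewer than 2 distinct recorded days are
  excluded (configurable `min_days`); the averaging denominator is the
  number of days actually recorded.
* All stored and JSON-emitted numbers are unrounded; rounding (servings to
  1 decimal, nutrients to 2, percentages to integers) happens only in text
  rendering.
* Every stochastic function takes or derives from an explicit integer
  seed; a fixed seed reproduces cohorts exactly.

## A worked run

```{r example}
sim <- simulate_cohort(synthetic_config(seed = 42))
brief <- snaq_profiles(sim)
vt <- validity_table(brief, sim$reference_profiles)
tidy(vt)

summarize_cohort(mean_daily_servings(sim$records))

percent_of_ear(100, "folate_dfe")  # a 5 g serving of a folate-rich spread
```
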