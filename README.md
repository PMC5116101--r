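# snaqr

Brief food-group dietary analysis for pregnancy, with the statistics needed
to evaluate it against a full reference analysis.

Dietitians who analyse prospective dietary records (for example image-based
food records) item-by-item against a food composition database get accurate
nutrient estimates slowly. A brief alternative scores the record only in
standard food-group servings of the Australian Guide to Healthy Eating
(AGTHE) and estimates nutrients from the average composition of one
standard serving per group, plus micronutrient supplements. snaqr
implements that method end-to-end for the nutrients that matter most in
pregnancy — energy, iron, calcium, folate (dietary folate equivalents),
iodine and zinc — and the relative-validity analysis used to compare it
with a reference method.

For participant *i*, nutrient *k*, group servings *s* and per-serving
composition *c*:

    ŷ_ik = Σ_g s_ig · c_gk  (+ Σ_p d_ip · u_pk when supplements are included)

Micronutrient intakes are classified against pregnancy reference values
(EAR/RDI) into `below_ear` / `ear_to_below_rdi` / `at_or_above_rdi`;
food-group intake is compared with AGTHE pregnancy targets (grains ≥ 8.5,
vegetables ≥ 5, fruit ≥ 2, meat ≥ 3.5, dairy ≥ 2.5 servings/day, 0–2.5
ranges for spreads/oils and discretionary foods). Method agreement uses
Spearman ρ (midranks, t-approximation p-value) on raw intakes and
unweighted Cohen κ (null asymptotic z-test) on adequacy classes — on
1000 kJ bins for energy, which has no EAR. Constant classifications yield
"Constants (no statistics computed)" rather than a number.

Because the motivating study's participant records are not published, the
package includes a seeded synthetic-cohort generator
(`simulate_cohort()`): lognormal daily servings parameterized by the
observed median/IQR per group, configurable supplement-use prevalence, and
a paired "reference method" profile with per-nutrient multiplicative bias
and lognormal noise. The shipped per-serving composition table is a
documented synthetic stand-in (the original AUSNUT-2007-derived averages
are unpublished) and is replaceable via `read_composition()`.

## Worked example

```r
library(snaqr)

sim   <- simulate_cohort(synthetic_config(seed = 42))   # 25 women, 3 days
brief <- snaq_profiles(sim)                             # the brief method
vt    <- validity_table(brief, sim$reference_profiles)  # vs the reference
tidy(vt)
#> # A tibble: 12 × 9
#>    condition            nutrient       n   rho      rho_p   kappa  kappa_p degenerate agreement
#>  1 food_and_supplements energy        25 0.615 1.08e-3    0.0523  4.23e-1 FALSE      slight
#>  2 food_and_supplements iron          25 0.808 1.01e-6    1       5.73e-7 FALSE      almost perfect
#>  3 food_and_supplements calcium       25 0.756 1.23e-5    0.339   7.24e-3 FALSE      fair
#>  4 food_and_supplements folate_dfe    25 0.761 1.01e-5    0.615   4.10e-5 FALSE      substantial
#>  ...
#>  8 food_only            iron          25 0.628 7.67e-4   NA      NA       TRUE       <NA>
```

Row 8 is the study's signature degenerate case: with supplements excluded,
every simulated intake sits below the 22 mg pregnancy iron EAR on both
methods, so both classifications are constant and no kappa exists. The ρ
column still quantifies rank agreement on the raw intakes.

Per-participant feedback in counselling form:

```r
serv <- mean_daily_servings(sim$records)
build_feedback("p01", serv, brief)
#> Dietary feedback for participant p01 (food and supplements)
#> Estimated energy intake: 8786 kJ/day
#>
#> Food groups (mean servings/day vs AGTHE pregnancy target):
#>   - Grains and cereals: 5.9 vs ≥8.5 — not met (gap 2.6 servings)
#>   - Fruit: 2.1 vs ≥2.0 — met
#>   ...
#> Key nutrients for pregnancy:
#>   - iron: 11.93 mg/day — 54% of EAR; below the EAR
#>   - calcium: 1018.56 mg/day — 121% of EAR; meets the RDI
#>   ...
```

A single number worth remembering: one 5 g serving of a folate-rich yeast
spread provides 100 µg DFE, and

```r
percent_of_ear(100, "folate_dfe")
#> [1] 19
```

i.e. 19% of the 520 µg pregnancy folate EAR from one food item.

A thin command-line wrapper ships at `inst/cli/snaq`
(`snaq analyze|validate|simulate|defaults|feedback`); run it with
`Rscript $(Rscript -e 'cat(system.file("cli","snaq",package="snaqr"))') defaults`.

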