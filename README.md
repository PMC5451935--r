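# isostage

Residential segregation and late-stage cancer diagnosis: an R package for
building county **Isolation Indices** from census-tract composition,
attaching them to cancer-registry cohorts as *place-centered* or
*person-centered* exposures, fitting a **three-level random-intercept
logistic model** (persons ⊂ counties ⊂ states), and screening county-level
residuals for spatial autocorrelation with a permutation **Moran's I**
test.

It is written for epidemiologists and health-services researchers who
study geographic disparities in cancer outcomes. Registry files carrying
county of residence are access-restricted, so the package ships a
hierarchical cohort simulator with known truth; every stage of the
pipeline is validated end-to-end on synthetic data.

## The models

**Isolation Index.** For county *j* with tracts *i* = 1…N, group count
x<sub>i</sub>, tract total t<sub>i</sub>, and county group total
X = Σ x<sub>i</sub>:

    I_j = Σ_i (x_i / X) (x_i / t_i)   ∈ [0, 1]

— the probability that a group member's random within-county contact is a
co-member. `I_j` is missing (not zero) when the group is absent from the
county; counties with `I_j ≥ 0.90` are flagged hyper-segregated.

**Outcome model.** With late-stage indicator y and covariates x (race,
age, and the isolation exposures of the chosen mode):

    logit P(y_ijk = 1) = x'β + u_jk + v_k,
    u_jk ~ N(0, σ²_county),  v_k ~ N(0, σ²_state)

fitted by nested adaptive Gauss–Hermite quadrature (7 nodes per level by
default). Coefficients are reported as odds ratios with Wald CIs; the
person-level latent variance is the standard-logistic constant π²/3 ≈
3.2899, reported alongside the estimated county and state variances.

**Diagnostics.** Per county: observed late-stage proportion minus mean
predicted probability (random intercepts included), outlier flags at
mean ± 2 SD, and a two-sided permutation Moran's I on the differences
under queen-contiguity or k-nearest-neighbour weights.

## Worked example

```r
library(isostage)

# Isolation indices from tract composition
tr <- data.frame(tract_id = c("t1", "t2", "t3"), county_id = "c001",
                 state_id = "s01", White = c(380, 30, 40),
                 Black = c(10, 360, 50), total = c(400, 400, 100))
isolation_table(tr, c("White", "Black"))
#>   county_id state_id     White     Black
#> 1      c001      s01 0.8427778 0.8315476
```

Whites and Blacks each concentrate in their own tracts, so both indices
are far above the raw county shares (0.53 and 0.47): a member of either
group mostly meets co-members. Neither reaches the 0.90 hyper-segregation
threshold.

```r
# End-to-end parameter recovery on a synthetic cohort with known truth
cfg <- sim_config(n_states = 4, counties_per_state = 5,
                  tracts_per_county = 4, persons_per_county = 250,
                  county_concentration = 50, segregation_alpha = 2,
                  tract_pop_mean = 800, seed = 7)
rec <- recovery_experiment(cfg)
rec$estimates[, c("term", "true_or", "or", "lower", "upper")]
#>                     term true_or    or lower upper
#> 1            (Intercept)   0.429 0.417 0.352 0.493
#> 2    race_ethnicityAsian   0.974 0.526 0.349 0.793
#> 3    race_ethnicityBlack   1.450 1.321 1.068 1.633
#> 4 race_ethnicityHispanic   1.253 1.181 0.941 1.483
#> 5    race_ethnicityOther   0.880 0.842 0.506 1.403
#> 6           age_group<50   1.342 1.400 1.156 1.696
#> 7         age_group50-64   1.063 1.003 0.840 1.198
#> 8         age_group65-74   0.894 0.987 0.810 1.203
rec$var_components
#>   component   true estimate
#> 1    county 0.0103   0.0078
#> 2     state 0.0037   0.0048
```

At this deliberately small size (4,745 retained cases) each 95% interval
covers its true odds ratio except the sparse Asian cell; at the default
50,000-case configuration the recovery is tight — the test suite asserts
it over 50 replicates.

The full dual-model analysis (place-centered Model 1 vs person-centered
Model 2, shared cohort construction, per-county diagnostics and Moran
report) runs from a single config:

```r
run <- run_pipeline(list(tracts = "tracts.csv", persons = "persons.csv",
                         centroids = "centroids.csv", outdir = "out"))
```

or from a shell via `inst/cli/isostage.R` (`simulate`, `run`, `recover`
subcommands).

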