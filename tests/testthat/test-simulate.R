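test_that("config validation catches degenerate settings", {
  expect_error(sim_config(baseline_mix = c(White = 0.5, Black = 0.4,
                                           Hispanic = 0.05, Asian = 0.04)),
               "sum to 1")
  expect_error(sim_config(segregation_alpha = 0), "positive")
  expect_error(sim_config(var_county = -1), "non-negative")
  expect_error(sim_config(tracts_per_county = 0), "positive integers")
  expect_error(sim_config(age_probs = c("<50" = 0.5, "50-64" = 0.4,
                                        "65-74" = 0.2, "75+" = 0.1)),
               "age_probs")
})

test_that("the generator is deterministic given a seed", {
  cfg <- small_sim_config(seed = 99, persons = 40)
  g1 <- generate_geography(cfg)
  g2 <- generate_geography(cfg)
  expect_identical(g1, g2)
  c1 <- generate_cohort(g1, cfg)
  c2 <- generate_cohort(g2, cfg)
  expect_identical(c1, c2)
  o1 <- generate_outcomes(c1, cfg)
  o2 <- generate_outcomes(c2, cfg)
  expect_identical(o1, o2)
  # a different seed changes the data
  cfg2 <- small_sim_config(seed = 100, persons = 40)
  expect_false(identical(generate_geography(cfg2), g1))
})

test_that("a huge concentration reproduces the even-distribution identity", {
  cfg <- sim_config(n_states = 2, counties_per_state = 5,
                    tracts_per_county = 8, segregation_alpha = 1e6,
                    tract_pop_mean = 5000, seed = 5)
  geo <- generate_geography(cfg)
  iso <- isolation_table(geo$tracts, cfg$group_labels)
  for (j in seq_len(nrow(iso))) {
    cty <- geo$counties[geo$counties$county_id == iso$county_id[j], ]
    for (g in cfg$group_labels) {
      if (!is.na(iso[[g]][j]) && cty[[g]] > 0.01)
        expect_equal(iso[[g]][j], cty[[g]], tolerance = 0.02)
    }
  }
})

test_that("more tract concentration (smaller alpha) raises isolation", {
  mean_white_iso <- function(alpha, seed) {
    cfg <- sim_config(n_states = 2, counties_per_state = 8,
                      tracts_per_county = 8, segregation_alpha = alpha,
                      tract_pop_mean = 2000, seed = seed)
    geo <- generate_geography(cfg)
    iso <- isolation_table(geo$tracts, cfg$group_labels)
    mean(iso$White, na.rm = TRUE)
  }
  for (s in 1:5)
    expect_gt(mean_white_iso(0.05, 1000 + s),
              mean_white_iso(1e6, 1000 + s))
})

test_that("exclusion flags fire at their configured rates", {
  cfg <- sim_config(n_states = 2, counties_per_state = 5,
                    tracts_per_county = 2, persons_per_county = 10000,
                    tract_pop_mean = 500, seed = 17)
  geo <- generate_geography(cfg)
  coh <- generate_cohort(geo, cfg)
  out <- apply_exclusions(coh)
  n <- nrow(coh)
  expect_equal(n, 100000L)
  p_keep <- prod(1 - cfg$exclusion_fracs)  # = 0.9458...
  expect_equal(out$n_retained / n, p_keep,
               tolerance = 4 * sqrt(p_keep * (1 - p_keep) / n) / p_keep)
  expect_true(all(out$tally > 0))  # every exclusion reason exercised
})

test_that("race and age frequencies match their target distributions", {
  cfg <- sim_config(n_states = 2, counties_per_state = 10,
                    tracts_per_county = 4, persons_per_county = 10000,
                    tract_pop_mean = 2000, seed = 23)
  geo <- generate_geography(cfg)
  coh <- generate_cohort(geo, cfg)
  n <- nrow(coh)
  expect_equal(n, 200000L)
  # aggregate expectation: person-weighted county mixes times (1 - p_other)
  mix <- as.matrix(geo$counties[cfg$group_labels])
  expected <- colMeans(mix) * (1 - cfg$p_other)
  freq <- table(factor(coh$race_ethnicity,
                       levels = c(cfg$group_labels, "Other"))) / n
  for (g in cfg$group_labels)
    expect_equal(unname(freq[[g]]), unname(expected[g]),
                 tolerance = 3 * sqrt(expected[g] / n) / expected[g])
  expect_equal(unname(freq[["Other"]]), cfg$p_other,
               tolerance = 3 * sqrt(cfg$p_other / n) / cfg$p_other)
  for (a in names(cfg$age_probs)) {
    fa <- mean(coh$age_group == a)
    expect_lt(abs(fa - cfg$age_probs[[a]]),
              3 * sqrt(cfg$age_probs[[a]] / n))
  }
  # every race and age level appears
  expect_setequal(unique(coh$race_ethnicity),
                  c(cfg$group_labels, "Other"))
  expect_setequal(unique(coh$age_group), names(cfg$age_probs))
})

test_that("zero requested persons yields an empty, well-typed cohort", {
  cfg <- small_sim_config(seed = 3, persons = 0)
  coh <- generate_cohort(generate_geography(cfg), cfg)
  expect_equal(nrow(coh), 0L)
  expect_true(all(c("person_id", "late_stage", "is_primary") %in%
                    names(coh)))
})

test_that("a null model with intercept logit(0.308) hits that prevalence", {
  beta0 <- c("(Intercept)" = qlogis(0.308),
             race_ethnicityBlack = 0, race_ethnicityHispanic = 0,
             race_ethnicityAsian = 0, race_ethnicityOther = 0,
             "age_group<50" = 0, "age_group50-64" = 0,
             "age_group65-74" = 0)
  cfg <- sim_config(n_states = 2, counties_per_state = 5,
                    tracts_per_county = 2, persons_per_county = 10000,
                    tract_pop_mean = 500, county_concentration = 50,
                    true_beta = beta0, var_county = 0, var_state = 0,
                    seed = 29)
  geo <- generate_geography(cfg)
  coh <- generate_outcomes(generate_cohort(geo, cfg), cfg)
  expect_equal(mean(coh$late_stage), 0.308, tolerance = 0.005 / 0.308)
})

test_that("state variance widens the spread of state-level prevalence", {
  spread <- function(vs, seed) {
    cfg <- sim_config(n_states = 12, counties_per_state = 4,
                      tracts_per_county = 2, persons_per_county = 400,
                      tract_pop_mean = 500, county_concentration = 50,
                      var_county = 0, var_state = vs, seed = seed)
    geo <- generate_geography(cfg)
    coh <- generate_outcomes(generate_cohort(geo, cfg), cfg)
    stats::var(tapply(coh$late_stage, coh$state_id, mean))
  }
  wins <- sum(vapply(1:10, function(s)
    spread(0.2, 4000 + s) > spread(0.0, 4000 + s), logical(1)))
  expect_gte(wins, 8)
})

test_that("a missing truth coefficient is a configuration error", {
  cfg <- small_sim_config(seed = 51, persons = 50)
  cfg$true_beta <- cfg$true_beta[-2]
  geo <- generate_geography(cfg)
  coh <- generate_cohort(geo, cfg)
  expect_error(generate_outcomes(coh, cfg), "true_beta")
})
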