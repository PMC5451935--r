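#' Configuration for the hierarchical cohort simulator
#'
#' Describes a synthetic study population: states containing counties
#' containing census tracts, tract racial/ethnic composition drawn from a
#' Dirichlet-multinomial with a single segregation dial, persons sampled
#' from their county's realized mix, and a binary late-stage outcome
#' generated from a logistic model with county and state random
#' intercepts. Defaults give 10 states x 20 counties x 250 persons
#' (50,000 cases) with fixed-effect odds ratios and variance components of
#' the magnitude seen in large registry analyses (e.g. a Black-vs-White OR
#' of 1.45, county variance 0.0103, state variance 0.0037).
#'
#' @param n_states,counties_per_state,tracts_per_county geography sizes.
#' @param group_labels racial/ethnic groups with tract counts.
#' @param baseline_mix named probability vector over `group_labels`
#'   (national composition; sums to 1).
#' @param county_concentration Dirichlet concentration of county mixes
#'   around `baseline_mix` (smaller = more between-county heterogeneity).
#' @param segregation_alpha Dirichlet concentration of tract mixes around
#'   the county mix; small values concentrate groups into their own tracts
#'   (high segregation), large values make every tract mirror the county.
#' @param tract_pop_mean Poisson mean of tract population totals.
#' @param persons_per_county cases sampled per county (scalar, or a
#'   length-2 range sampled uniformly).
#' @param p_other probability a case belongs to the residual "Other"
#'   race/ethnicity category (no group index of its own).
#' @param age_probs named probability vector over the four age groups.
#' @param exclusion_fracs named fractions of records given, independently,
#'   the non-primary, unknown-stage and autopsy/death-certificate flags.
#' @param true_beta named log-odds vector keyed by design column names of
#'   the truth model (intercept, race and age dummies, and optionally any
#'   attached exposure column).
#' @param var_county,var_state random-intercept variances.
#' @param seed master integer seed; stage-specific streams are derived
#'   from it so, e.g., adding persons never perturbs the geography.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_states = 10L, counties_per_state = 20L,
                       tracts_per_county = 10L,
                       group_labels = c("White", "Black", "Hispanic",
                                        "Asian"),
                       baseline_mix = c(White = 0.773, Black = 0.101,
                                        Hispanic = 0.081, Asian = 0.033) /
                         0.988,
                       county_concentration = 5,
                       segregation_alpha = 0.5,
                       tract_pop_mean = 4000,
                       persons_per_county = 250L,
                       p_other = 0.013,
                       age_probs = c("<50" = 0.226, "50-64" = 0.366,
                                     "65-74" = 0.219, "75+" = 0.189),
                       exclusion_fracs = c(non_primary = 0.02,
                                           unknown_stage = 0.025,
                                           autopsy_dc = 0.01),
                       true_beta = c("(Intercept)" = qlogis(0.30),
                                     race_ethnicityBlack = log(1.45),
                                     race_ethnicityHispanic = log(1.253),
                                     race_ethnicityAsian = log(0.974),
                                     race_ethnicityOther = log(0.88),
                                     "age_group<50" = log(1.342),
                                     "age_group50-64" = log(1.063),
                                     "age_group65-74" = log(0.894)),
                       var_county = 0.0103, var_state = 0.0037,
                       seed = 1L) {
  cfg <- list(n_states = as.integer(n_states),
              counties_per_state = as.integer(counties_per_state),
              tracts_per_county = as.integer(tracts_per_county),
              group_labels = group_labels,
              baseline_mix = baseline_mix,
              county_concentration = county_concentration,
              segregation_alpha = segregation_alpha,
              tract_pop_mean = tract_pop_mean,
              persons_per_county = persons_per_county,
              p_other = p_other, age_probs = age_probs,
              exclusion_fracs = exclusion_fracs,
              true_beta = true_beta,
              var_county = var_county, var_state = var_state,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_states < 1L || counties_per_state < 1L || tracts_per_county < 1L)
      stop("geography sizes must be positive integers", call. = FALSE)
    if (length(baseline_mix) != length(group_labels))
      stop("baseline_mix must have one entry per group", call. = FALSE)
    if (abs(sum(baseline_mix) - 1) > 1e-9)
      stop("baseline_mix must sum to 1", call. = FALSE)
    if (abs(sum(age_probs) - 1) > 1e-9)
      stop("age_probs must sum to 1", call. = FALSE)
    if (segregation_alpha <= 0)
      stop("segregation_alpha must be positive", call. = FALSE)
    if (var_county < 0 || var_state < 0)
      stop("variances must be non-negative", call. = FALSE)
    if (p_other < 0 || p_other >= 1)
      stop("p_other must lie in [0, 1)", call. = FALSE)
    if (!length(persons_per_county) %in% 1:2 || any(persons_per_county < 0))
      stop("persons_per_county must be a scalar or a range", call. = FALSE)
  })
  cfg
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  tot <- rowSums(g)
  bad <- tot == 0  # extreme underflow with tiny shapes
  if (any(bad)) {
    for (r in which(bad)) g[r, sample.int(k, 1L, prob = alpha)] <- 1
    tot <- rowSums(g)
  }
  g / tot
}

#' Generate synthetic geography: tract compositions and county centroids
#'
#' County mixes are Dirichlet-perturbed from the national baseline; tract
#' group proportions are Dirichlet draws centred on the county mix with
#' total concentration `segregation_alpha` (small = segregated tracts);
#' tract counts are multinomial given Poisson tract totals. Centroids lie
#' on a jittered grid. Deterministic given the config seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `tracts` (tract composition table), `centroids`
#'   (`county_id`, `x`, `y`), and `counties` (`county_id`, `state_id`,
#'   per-group county mix actually realized from tract counts).
#' @export
generate_geography <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, 1L))
  nS <- config$n_states; nCps <- config$counties_per_state
  nT <- config$tracts_per_county
  nC <- nS * nCps
  G <- length(config$group_labels)
  state_id <- rep(sprintf("S%02d", seq_len(nS)), each = nCps)
  county_id <- sprintf("%s_C%03d", state_id, seq_len(nC))
  county_mix <- rdirichlet(nC, config$county_concentration *
                             config$baseline_mix)
  rows <- vector("list", nC)
  for (j in seq_len(nC)) {
    shares <- rdirichlet(nT, config$segregation_alpha * county_mix[j, ])
    totals <- rpois(nT, config$tract_pop_mean)
    counts <- matrix(0L, nT, G)
    for (i in seq_len(nT))
      if (totals[i] > 0)
        counts[i, ] <- as.integer(rmultinom(1L, totals[i], shares[i, ]))
    d <- data.frame(tract_id = sprintf("%s_T%02d", county_id[j], seq_len(nT)),
                    county_id = county_id[j], state_id = state_id[j],
                    stringsAsFactors = FALSE)
    for (g in seq_len(G)) d[[config$group_labels[g]]] <- counts[, g]
    d$total <- as.integer(totals)
    rows[[j]] <- d
  }
  tracts <- do.call(rbind, rows)
  rownames(tracts) <- NULL
  side <- ceiling(sqrt(nC))
  centroids <- data.frame(
    county_id = county_id,
    x = ((seq_len(nC) - 1L) %% side) + runif(nC, -0.3, 0.3),
    y = ((seq_len(nC) - 1L) %/% side) + runif(nC, -0.3, 0.3),
    stringsAsFactors = FALSE)
  agg <- rowsum(tracts[config$group_labels], tracts$county_id)
  agg <- agg[match(county_id, rownames(agg)), , drop = FALSE]
  tot <- rowSums(agg)
  mix <- as.matrix(agg) / ifelse(tot > 0, tot, 1)
  counties <- data.frame(county_id = county_id, state_id = state_id,
                         stringsAsFactors = FALSE)
  for (g in config$group_labels) counties[[g]] <- mix[, g]
  list(tracts = tracts, centroids = centroids, counties = counties)
}

#' Generate a raw synthetic case cohort
#'
#' Persons are assigned to counties; race/ethnicity is drawn from the
#' county's realized tract composition (plus a small "Other" fraction with
#' no group index of its own), age from the configured distribution, and
#' the three exclusion-triggering flags independently at their configured
#' rates. Deterministic given the config seed.
#'
#' @param geography result of [generate_geography()].
#' @param config a [sim_config()] object.
#' @return person-level data frame with the raw case-record columns
#'   (`late_stage` is `NA` until [generate_outcomes()] fills it in).
#' @export
generate_cohort <- function(geography, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, 2L))
  cty <- geography$counties
  nC <- nrow(cty)
  npc <- config$persons_per_county
  n_per <- if (length(npc) == 2L)
    sample(seq(npc[1L], npc[2L]), nC, replace = TRUE) else rep(npc, nC)
  n <- sum(n_per)
  if (n == 0L) {
    out <- data.frame(person_id = character(0), county_id = character(0),
                      state_id = character(0), race_ethnicity = character(0),
                      age_group = character(0), late_stage = integer(0),
                      is_primary = integer(0), stage_known = integer(0),
                      dx_source_autopsy_or_dc = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  county_id <- rep(cty$county_id, n_per)
  state_id <- rep(cty$state_id, n_per)
  race_levels <- c(config$group_labels, "Other")
  mix <- as.matrix(cty[config$group_labels])
  race <- character(n)
  pos <- 0L
  for (j in seq_len(nC)) {
    pr <- c(mix[j, ] * (1 - config$p_other), config$p_other)
    race[pos + seq_len(n_per[j])] <-
      sample(race_levels, n_per[j], replace = TRUE, prob = pr)
    pos <- pos + n_per[j]
  }
  ef <- config$exclusion_fracs
  data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    county_id = county_id, state_id = state_id,
    race_ethnicity = race,
    age_group = sample(names(config$age_probs), n, replace = TRUE,
                       prob = config$age_probs),
    late_stage = NA_integer_,
    is_primary = rbinom(n, 1L, 1 - ef[["non_primary"]]),
    stage_known = rbinom(n, 1L, 1 - ef[["unknown_stage"]]),
    dx_source_autopsy_or_dc = rbinom(n, 1L, ef[["autopsy_dc"]]),
    stringsAsFactors = FALSE)
}

#' Generate late-stage outcomes from the three-level truth model
#'
#' Draws state intercepts \eqn{v_k \sim N(0, \sigma^2_{state})} and county
#' intercepts \eqn{u_{jk} \sim N(0, \sigma^2_{county})}, then
#' `late_stage ~ Bernoulli(plogis(X beta + u + v))` with `X` built by
#' [build_design()] from `spec` and `beta = config$true_beta` (whose names
#' must exactly match the design columns). Deterministic given the config
#' seed.
#'
#' @param cohort person-level data frame (exposures attached if the truth
#'   model uses them).
#' @param config a [sim_config()] object.
#' @param spec truth-model [model_spec()]; default race + age with no
#'   exposure terms.
#' @return `cohort` with the `late_stage` column filled in.
#' @export
generate_outcomes <- function(cohort, config, spec = model_spec()) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, 3L))
  cohort$late_stage <- 0L  # placeholder so the design builder keeps rows
  des <- build_design(cohort, spec)
  if (des$n_dropped > 0)
    stop("cohort has missing values in truth-model terms; cannot simulate ",
         "outcomes for all rows", call. = FALSE)
  miss <- setdiff(des$terms, names(config$true_beta))
  extra <- setdiff(names(config$true_beta), des$terms)
  if (length(miss) || length(extra))
    stop("true_beta terms do not match the design: missing [",
         paste(miss, collapse = ", "), "], unused [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  beta <- config$true_beta[des$terms]
  counties <- unique(as.character(des$county))
  states <- unique(as.character(des$state))
  u <- setNames(rnorm(length(counties), 0, sqrt(config$var_county)),
                counties)
  v <- setNames(rnorm(length(states), 0, sqrt(config$var_state)), states)
  eta <- drop(des$x %*% beta) + u[as.character(des$county)] +
    v[as.character(des$state)]
  cohort$late_stage <- rbinom(length(eta), 1L, plogis(unname(eta)))
  attr(cohort, "true_random") <- list(u = u, v = v)
  cohort
}

#' End-to-end parameter-recovery experiment
#'
#' Runs the full pipeline on one synthetic realization — geography,
#' isolation indices, cohort, exclusions, both exposure attachments,
#' outcomes from known truth, the three-level fit, and odds-ratio
#' summaries — and reports truth against estimates.
#'
#' @param config a [sim_config()] object; `config$seed` controls the
#'   realization.
#' @param spec truth/fit [model_spec()] (default race + age).
#' @param quad_points,tol passed to [fit_three_level_logit()].
#' @param level confidence level for the coverage columns.
#' @param compute_se set `FALSE` to skip standard errors (no coverage
#'   columns).
#' @return list with `estimates` (data frame: term, true log-odds and OR,
#'   estimate, SE, CI, `covered`), `var_components` (truth vs estimate),
#'   `fit`, `prevalence`, `n`, and the exclusion `tally`.
#' @export
recovery_experiment <- function(config = sim_config(), spec = model_spec(),
                                quad_points = 7, tol = 1e-8, level = 0.95,
                                compute_se = TRUE) {
  geo <- generate_geography(config)
  iso <- isolation_table(geo$tracts, config$group_labels)
  cohort <- generate_cohort(geo, config)
  excl <- apply_exclusions(cohort)
  cohort <- excl$retained
  cohort <- attach_place_centered(cohort, iso, config$group_labels)
  cohort <- attach_person_centered(cohort, iso)
  cohort <- generate_outcomes(cohort, config, spec)
  des <- build_design(cohort, spec)
  fit <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                               quad_points = quad_points, tol = tol,
                               compute_se = compute_se, compute_eb = FALSE)
  truth <- config$true_beta[des$terms]
  est <- data.frame(term = des$terms,
                    true_beta = unname(truth),
                    true_or = exp(unname(truth)),
                    estimate = unname(fit$beta),
                    or = exp(unname(fit$beta)),
                    stringsAsFactors = FALSE)
  if (compute_se) {
    z <- qnorm(1 - (1 - level) / 2)
    est$se <- unname(fit$se)
    est$lower <- exp(est$estimate - z * est$se)
    est$upper <- exp(est$estimate + z * est$se)
    est$covered <- est$lower <= est$true_or & est$true_or <= est$upper
  }
  list(estimates = est,
       var_components = data.frame(
         component = c("county", "state"),
         true = c(config$var_county, config$var_state),
         estimate = c(fit$var_county, fit$var_state)),
       fit = fit,
       prevalence = mean(des$y),
       n = fit$n,
       tally = excl$tally)
}
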