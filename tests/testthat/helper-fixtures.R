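# Fixtures are generated in code at test time; oracles are deliberately
# naive re-implementations kept independent of the package internals.

# Literal double-loop evaluation of the Isolation Index sum.
naive_isolation <- function(tracts, group) {
  x <- tracts[[group]]; t <- tracts$total
  keep <- t > 0
  x <- x[keep]; t <- t[keep]
  X <- 0
  for (i in seq_along(x)) X <- X + x[i]
  if (X == 0) return(NA_real_)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] / X) * (x[i] / t[i])
  s
}

# Textbook triple-loop Moran's I.
naive_moran <- function(z, w) {
  n <- length(z)
  zb <- mean(z)
  num <- 0; S0 <- 0; den <- 0
  for (i in seq_len(n)) {
    den <- den + (z[i] - zb)^2
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (z[i] - zb) * (z[j] - zb)
      S0 <- S0 + w[i, j]
    }
  }
  (n / S0) * num / den
}

# Random multi-county tract composition table.
random_tract_table <- function(n_counties, max_tracts = 8,
                               groups = c("g1", "g2"), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ct in seq_len(n_counties)) {
    nt <- sample.int(max_tracts, 1L)
    total <- rpois(nt, 400) + 1L
    sh <- matrix(rgamma(nt * (length(groups) + 1L), 1), nt)
    sh <- sh / rowSums(sh)
    d <- data.frame(tract_id = sprintf("c%03d_t%02d", ct, seq_len(nt)),
                    county_id = sprintf("c%03d", ct),
                    state_id = "s1", stringsAsFactors = FALSE)
    for (gi in seq_along(groups))
      d[[groups[gi]]] <- vapply(seq_len(nt), function(i)
        rbinom(1L, total[i], sh[i, gi]), integer(1))
    # keep counts consistent with totals
    d$total <- pmax(total, Reduce(`+`, d[groups]))
    rows[[ct]] <- d
  }
  do.call(rbind, rows)
}

# Small balanced synthetic fixture: high county_concentration keeps all
# race levels represented even at modest n.
small_sim_config <- function(seed = 42, persons = 150,
                             n_states = 4, counties = 5) {
  sim_config(n_states = n_states, counties_per_state = counties,
             tracts_per_county = 4, persons_per_county = persons,
             county_concentration = 50, segregation_alpha = 2,
             tract_pop_mean = 800, seed = seed)
}

small_design_fixture <- function(seed = 42, persons = 150, ...) {
  cfg <- small_sim_config(seed = seed, persons = persons, ...)
  geo <- generate_geography(cfg)
  coh <- apply_exclusions(generate_cohort(geo, cfg))$retained
  coh <- generate_outcomes(coh, cfg)
  list(config = cfg, geography = geo, cohort = coh,
       design = build_design(coh, model_spec()))
}

# Rook adjacency pair list for an nr x nc grid, counties numbered rowwise.
grid_adjacency <- function(nr, nc) {
  id <- function(r, c) sprintf("q%03d", (r - 1L) * nc + c)
  from <- character(0); to <- character(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1L)) }
    if (r < nr) { from <- c(from, id(r, c)); to <- c(to, id(r + 1L, c)) }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

fake_fit <- function(beta, se) {
  structure(list(beta = beta, se = se, terms = names(beta),
                 var_county = 0, var_state = 0,
                 var_person_latent = pi^2 / 3, converged = TRUE),
            class = "three_level_fit")
}
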