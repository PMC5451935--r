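test_that("with variances fixed at zero the fit matches the IRLS oracle", {
  fx <- small_design_fixture(seed = 42, persons = 120)
  des <- fx$design
  fit <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                               fix_var = c(county = 0, state = 0),
                               tol = 1e-12,
                               start = list(beta = rep(0, ncol(des$x))))
  oracle <- glm.fit(des$x, des$y, family = binomial())
  expect_lt(max(abs(fit$beta - oracle$coefficients) /
                  abs(oracle$coefficients)), 1e-4)
  expect_equal(fit$var_county, 0)
  expect_equal(fit$var_state, 0)
})

test_that("intercept-only model with 50/50 outcomes has intercept zero", {
  n_per <- 10L
  cl <- rep(sprintf("c%d", 1:4), each = n_per)
  st <- rep(c("s1", "s2"), each = 2 * n_per)
  y <- rep(rep(c(0, 1), each = n_per / 2), 4)
  x <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_three_level_logit(x, y, cl, st,
                               fix_var = c(county = 0, state = 0),
                               tol = 1e-12, start = list(beta = 0))
  expect_equal(unname(fit$beta), 0, tolerance = 1e-6)
})

test_that("estimates are insensitive to the number of quadrature nodes", {
  fx <- small_design_fixture(seed = 42, persons = 250, n_states = 4,
                             counties = 5)
  des <- fx$design
  f7 <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                              quad_points = 7, compute_se = FALSE,
                              compute_eb = FALSE)
  f15 <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                               quad_points = 15, compute_se = FALSE,
                               compute_eb = FALSE)
  expect_lt(max(abs(f7$beta - f15$beta)), 1e-3)
  expect_lt(abs(f7$var_county - f15$var_county), 1e-3)
  expect_lt(abs(f7$var_state - f15$var_state), 1e-3)
})

test_that("fit agrees with an independent nested-GLMM implementation", {
  skip_if_not_installed("lme4")
  fx <- small_design_fixture(seed = 42, persons = 250, n_states = 4,
                             counties = 5)
  des <- fx$design
  ours <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                                compute_se = FALSE, compute_eb = FALSE)
  d <- data.frame(y = des$y, des$x[, -1], county = des$county,
                  state = des$state, check.names = FALSE)
  form <- stats::reformulate(c(sprintf("`%s`", colnames(des$x)[-1]),
                               "(1|state)", "(1|state:county)"), "y")
  ref <- suppressMessages(lme4::glmer(form, data = d, family = binomial))
  # same column order by construction: intercept then the design columns
  expect_equal(unname(ours$beta), unname(lme4::fixef(ref)),
               tolerance = 2e-3, ignore_attr = TRUE)
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-3)
})

test_that("the optimizer trace is monotone in the log-likelihood", {
  fx <- small_design_fixture(seed = 33, persons = 100)
  des <- fx$design
  fit <- fit_three_level_logit(des$x, des$y, des$county, des$state,
                               compute_se = FALSE, compute_eb = FALSE)
  expect_true(all(diff(fit$trace) >= 0))
  expect_true(fit$converged)
})

test_that("odds-ratio summaries exponentiate with Wald limits", {
  f1 <- fake_fit(c(a = 0), c(a = 0.5))
  s1 <- summarize_odds_ratios(f1)
  expect_equal(s1$or, 1)
  expect_true(s1$lower < 1 && s1$upper > 1)

  f2 <- fake_fit(c(a = log(2)), c(a = 0))
  s2 <- summarize_odds_ratios(f2)
  expect_equal(s2$or, 2)
  expect_equal(s2$lower, 2)
  expect_equal(s2$upper, 2)

  f3 <- fake_fit(c(black = 0.3716), c(black = 0.0079))
  s3 <- summarize_odds_ratios(f3)
  expect_equal(round(s3$or, 2), 1.45)
  expect_equal(round(s3$lower, 3), 1.428)
  expect_equal(round(s3$upper, 3), 1.473)
  expect_lt(s3$p_value, 1e-10)

  expect_error(summarize_odds_ratios(f1, level = 1.2), "level")
  f_bad <- f1; f_bad$converged <- FALSE
  expect_error(summarize_odds_ratios(f_bad), "converge")
  expect_silent(summarize_odds_ratios(f_bad, allow_unconverged = TRUE))
})

test_that("variance components report the latent level-1 constant and ICCs", {
  f <- fake_fit(c(a = 0), c(a = 1))
  f$var_county <- 0.0103; f$var_state <- 0.0037
  vc <- variance_components(f)
  expect_equal(round(vc$var_person_latent, 4), 3.2899)
  denom <- 0.0103 + 0.0037 + pi^2 / 3
  expect_equal(vc$icc_county, 0.014 / denom)
  expect_equal(vc$icc_state, 0.0037 / denom)
  expect_equal(round(vc$icc_county, 5), 0.00424)

  f$var_county <- 0; f$var_state <- 0
  vc0 <- variance_components(f)
  expect_equal(vc0$icc_county, 0)
  expect_equal(vc0$icc_state, 0)
})

test_that("predictions invert the linear predictor and calibrate", {
  fx <- small_design_fixture(seed = 42, persons = 250, n_states = 4,
                             counties = 5)
  des <- fx$design
  fit <- fit_three_level_logit(des$x, des$y, des$county, des$state)
  # null-coefficient model predicts 0.5 everywhere
  f0 <- fit
  f0$beta[] <- 0
  p0 <- predict_probabilities(f0, des$x, des$county, des$state,
                              include_random = FALSE)
  expect_true(all(p0 == 0.5))
  # fixed-effects-only predictions are plogis(X beta)
  pf <- predict_probabilities(fit, des$x, des$county, des$state,
                              include_random = FALSE)
  expect_equal(pf, plogis(drop(des$x %*% fit$beta)))
  # calibration-in-the-large
  pr <- predict_probabilities(fit, des$x, des$county, des$state,
                              include_random = TRUE)
  expect_lt(abs(mean(pr) - mean(des$y)), 0.005)
  expect_true(all(pr > 0 & pr < 1))
  # unseen clusters get a zero random effect, with a note
  expect_message(
    pu <- predict_probabilities(fit, des$x[1:2, , drop = FALSE],
                                c("newcounty", "newcounty"),
                                c("newstate", "newstate")),
    "unseen")
  expect_equal(pu, plogis(drop(des$x[1:2, ] %*% fit$beta)),
               ignore_attr = TRUE)
  # mismatched design columns are a structural error
  xbad <- des$x[, rev(seq_len(ncol(des$x)))]
  expect_error(predict_probabilities(fit, xbad, des$county, des$state),
               "columns")
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  expect_error(fit_three_level_logit(x, rep(2, 10), rep("c1", 10),
                                     rep("s1", 10)),
               "binary")
  # complete separation aborts with a diagnostic
  xs <- cbind(`(Intercept)` = 1, z = c(rep(0, 20), rep(1, 20)))
  ysep <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_three_level_logit(xs, ysep,
                                     rep(c("c1", "c2"), each = 20),
                                     rep("s1", 40),
                                     fix_var = c(county = 0, state = 0)),
               "separation")
})
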