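#' Fit the three-level random-intercept logistic model
#'
#' Maximum-likelihood fit of a Bernoulli-logit model with Gaussian random
#' intercepts for counties nested within states,
#' \deqn{\mathrm{logit}\,P(y_{ijk}=1) = x_{ijk}'\beta + u_{jk} + v_k,}
#' with \eqn{u_{jk} \sim N(0, \sigma^2_{county})} and
#' \eqn{v_k \sim N(0, \sigma^2_{state})}. The random intercepts are
#' integrated out by nested adaptive Gauss-Hermite quadrature: the
#' likelihood factorises over states, each state integral is evaluated on
#' quadrature nodes centred at the posterior mode of the state intercept,
#' and at each node the county integrals are evaluated on nodes centred at
#' the county-level conditional posterior modes. With `quad_points = 1`
#' this reduces to a nested Laplace approximation. Variances are optimised
#' on the log-standard-deviation scale, which enforces non-negativity.
#'
#' Standard errors come from the inverse of the observed information,
#' obtained by central finite differences of the marginal log-likelihood at
#' the optimum. Empirical-Bayes intercepts are posterior modes given the
#' estimated parameters (state modes with the counties integrated out, then
#' county modes conditional on the state modes).
#'
#' @param x design matrix (including an intercept column), e.g. from
#'   [build_design()].
#' @param y binary outcome vector (0/1).
#' @param county,state cluster identifier vectors aligned with rows of `x`;
#'   counties must nest within states.
#' @param quad_points quadrature nodes per level (default 7; 1 = Laplace).
#' @param tol convergence tolerance: relative change in the log-likelihood
#'   between accepted optimizer iterations.
#' @param max_iter maximum optimizer iterations.
#' @param fix_var optional named numeric fixing a variance component
#'   instead of estimating it, e.g. `c(county = 0, state = 0)` collapses
#'   the model to single-level logistic regression.
#' @param start optional list with any of `beta` (fixed-effect start,
#'   default: single-level `glm` estimates), `sd_county`, `sd_state`
#'   (default 0.05 each).
#' @param compute_se,compute_eb set `FALSE` to skip the finite-difference
#'   information matrix or the empirical-Bayes modes (saves time in
#'   simulation loops that only need point estimates).
#' @return an object of class `"three_level_fit"`: `beta`, `se`, `vcov`
#'   (fixed effects), `var_county`, `var_state`, `var_person_latent`
#'   (\eqn{\pi^2/3}), `eb_county`, `eb_state` (named vectors of posterior
#'   modes), `loglik`, `converged`, `n_iter`, `trace` (log-likelihood at
#'   accepted improvements), `terms`, `n`, `quad_points`.
#' @export
fit_three_level_logit <- function(x, y, county, state,
                                  quad_points = 7, tol = 1e-8,
                                  max_iter = 200, fix_var = NULL,
                                  start = NULL, compute_se = TRUE,
                                  compute_eb = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(x) == n, length(county) == n, length(state) == n)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  p <- ncol(x)
  terms <- colnames(x) %||% paste0("x", seq_len(p))

  fix_u <- !is.null(fix_var) && "county" %in% names(fix_var)
  fix_v <- !is.null(fix_var) && "state" %in% names(fix_var)
  if (fix_u && fix_var[["county"]] < 0 || fix_v && fix_var[["state"]] < 0)
    stop("fixed variances must be non-negative", call. = FALSE)

  state_f <- factor(as.character(state))
  # counties numbered within state order so their blocks are contiguous
  ord <- order(as.integer(state_f), as.character(county))
  xs <- x[ord, , drop = FALSE]; ys <- y[ord]
  cs <- as.character(county)[ord]; ss <- as.integer(state_f)[ord]
  county_key <- paste(ss, cs, sep = "\r")
  county_f <- factor(county_key, levels = unique(county_key))
  ci <- as.integer(county_f)
  nC <- nlevels(county_f); nS <- nlevels(state_f)
  if (!fix_u && nC < 2) stop("need >= 2 counties to estimate var_county",
                             call. = FALSE)
  if (!fix_v && nS < 2) stop("need >= 2 states to estimate var_state",
                             call. = FALSE)
  county_ptr <- c(0L, cumsum(tabulate(ci, nC)))
  state_of_county <- ss[!duplicated(ci)]
  state_ptr <- c(0L, cumsum(tabulate(state_of_county, nS)))
  county_labels <- cs[!duplicated(ci)]

  gh <- gauss_hermite(quad_points)
  gh_logw <- log(gh$weights)

  beta0 <- start$beta
  if (is.null(beta0)) {
    g0 <- glm.fit(xs, ys, family = binomial())
    beta0 <- g0$coefficients
    if (anyNA(beta0) || any(abs(beta0) > 15))
      stop("apparent complete separation in the fixed effects; ",
           "the maximum-likelihood estimate is not finite", call. = FALSE)
  }
  if (length(beta0) != p) stop("start$beta has wrong length", call. = FALSE)
  ls_u0 <- log(start$sd_county %||% 0.05)
  ls_v0 <- log(start$sd_state %||% 0.05)
  theta0 <- c(beta0,
              if (!fix_u) ls_u0,
              if (!fix_v) ls_v0)

  vwarm <- numeric(nS); uwarm <- numeric(nC)
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$trace <- numeric(0); env$par <- NULL
  sd_floor <- 1e-8; ls_cap <- 5
  map_sigma <- function(theta) {
    k <- p
    sig_u <- if (fix_u) sqrt(fix_var[["county"]]) else
      { k <- k + 1L; exp(min(theta[k], ls_cap)) }
    if (!fix_u && sig_u < sd_floor) sig_u <- 0
    sig_v <- if (fix_v) sqrt(fix_var[["state"]]) else
      { k <- k + 1L; exp(min(theta[k], ls_cap)) }
    if (!fix_v && sig_v < sd_floor) sig_v <- 0
    list(sig_u = sig_u, sig_v = sig_v)
  }
  eval_fg <- function(theta, want_grad = TRUE) {
    beta <- theta[seq_len(p)]
    sg <- map_sigma(theta)
    eta0 <- drop(xs %*% beta)
    res <- agq_nll_grad(eta0, ys, county_ptr, state_ptr, sg$sig_u,
                        sg$sig_v, gh$nodes, gh_logw, vwarm, uwarm,
                        want_grad)
    grad <- NULL
    if (want_grad) {
      grad <- c(-drop(crossprod(xs, res$resid)),
                if (!fix_u) {
                  # flat beyond the clamps of the log-sd parameterization
                  if (sg$sig_u == 0 || theta[p + 1L] > ls_cap) 0
                  else -res$g_lsu
                },
                if (!fix_v) {
                  kv <- p + 1L + !fix_u
                  if (sg$sig_v == 0 || theta[kv] > ls_cap) 0
                  else -res$g_lsv
                })
    }
    list(value = res$nll, grad = grad)
  }
  objective <- function(theta) {
    fg <- eval_fg(theta)
    env$par <- theta; env$grad <- fg$grad
    if (is.finite(fg$value) && fg$value < env$best) {
      env$best <- fg$value
      env$trace <- c(env$trace, -fg$value)
    }
    fg$value
  }
  gradient <- function(theta) {
    if (!is.null(env$par) && identical(theta, env$par)) return(env$grad)
    eval_fg(theta)$grad
  }

  opt <- optim(theta0, objective, gradient, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  theta <- opt$par
  beta <- setNames(theta[seq_len(p)], terms)
  sg <- map_sigma(theta)
  sig_u <- sg$sig_u; sig_v <- sg$sig_v
  converged <- opt$convergence == 0L
  if (!converged)
    warning("three-level fit did not converge within max_iter; ",
            "estimates returned with converged = FALSE")

  se <- rep(NA_real_, p); vc <- matrix(NA_real_, p, p)
  if (compute_se) {
    # observed information by central differences of the analytic gradient;
    # variance parameters stuck at the zero floor have a flat (zero)
    # gradient and are excluded from the differenced block
    free <- c(rep(TRUE, p),
              if (!fix_u) sig_u > 0,
              if (!fix_v) sig_v > 0)
    idx <- which(free)
    gfun <- function(th) eval_fg(th)$grad[idx]
    q <- length(idx)
    H <- matrix(NA_real_, q, q)
    hstep <- 1e-5 * pmax(abs(theta[idx]), 1)
    for (ii in seq_len(q)) {
      e <- numeric(length(theta)); e[idx[ii]] <- hstep[ii]
      H[, ii] <- (gfun(theta + e) - gfun(theta - e)) / (2 * hstep[ii])
    }
    H <- (H + t(H)) / 2
    cov_all <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov_all) || any(diag(cov_all)[seq_len(p)] <= 0)) {
      warning("observed information is not positive definite; ",
              "standard errors unavailable")
    } else {
      vc <- cov_all[seq_len(p), seq_len(p), drop = FALSE]
      se <- sqrt(diag(vc))
    }
  }
  dimnames(vc) <- list(terms, terms)

  eb_county <- setNames(numeric(nC), county_labels)
  eb_state <- setNames(numeric(nS), levels(state_f))
  if (compute_eb && (sig_u > 0 || sig_v > 0)) {
    eta0 <- drop(xs %*% beta)
    modes <- agq_modes(eta0, ys, county_ptr, state_ptr, sig_u, sig_v,
                       gh$nodes, gh_logw)
    eb_county[] <- modes$u
    eb_state[] <- modes$v
  }

  structure(list(beta = beta, se = setNames(se, terms), vcov = vc,
                 var_county = sig_u^2, var_state = sig_v^2,
                 var_person_latent = pi^2 / 3,
                 eb_county = eb_county, eb_state = eb_state,
                 loglik = -opt$value, converged = converged,
                 n_iter = unname(opt$counts[1L]), trace = env$trace,
                 terms = terms, n = n, n_county = nC, n_state = nS,
                 quad_points = quad_points),
            class = "three_level_fit")
}

#' @export
print.three_level_fit <- function(x, ...) {
  cat("Three-level random-intercept logistic fit\n")
  cat(sprintf("  n = %d persons, %d counties, %d states; AGQ nodes = %d\n",
              x$n, x$n_county, x$n_state, x$quad_points))
  cat(sprintf("  logLik = %.3f (converged: %s)\n", x$loglik, x$converged))
  cat(sprintf("  var(county) = %.5f, var(state) = %.5f, latent level-1 = %.4f\n",
              x$var_county, x$var_state, x$var_person_latent))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' Odds-ratio summary table
#'
#' Exponentiates the fixed-effect estimates into odds ratios with Wald
#' confidence limits (symmetric on the log-odds scale) and two-sided Wald
#' p-values.
#'
#' @param fit a [fit_three_level_logit()] object.
#' @param level confidence level in (0, 1).
#' @param allow_unconverged set `TRUE` to summarise a non-converged fit.
#' @return data frame with columns `term`, `estimate`, `se`, `or`,
#'   `p_value`, `lower`, `upper`, ordered as in the design.
#' @export
summarize_odds_ratios <- function(fit, level = 0.95,
                                  allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "three_level_fit"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must be a single value in (0, 1)", call. = FALSE)
  if (!fit$converged && !allow_unconverged)
    stop("fit did not converge; pass allow_unconverged = TRUE to summarise",
         call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$beta; s <- fit$se
  data.frame(term = fit$terms,
             estimate = unname(b), se = unname(s),
             or = exp(unname(b)),
             p_value = 2 * pnorm(-abs(unname(b) / unname(s))),
             lower = exp(unname(b) - z * unname(s)),
             upper = exp(unname(b) + z * unname(s)),
             stringsAsFactors = FALSE)
}

#' Variance components and intraclass correlations
#'
#' The person-level (level-1) variance on the latent-response scale is the
#' standard-logistic variance \eqn{\pi^2/3}; it is a constant of the model,
#' never estimated. ICCs are latent-scale variance shares:
#' `icc_state` is the correlation of persons sharing only a state,
#' `icc_county` that of persons sharing a county (and hence its state).
#'
#' @param fit a [fit_three_level_logit()] object.
#' @return list with `var_person_latent`, `var_county`, `var_state`,
#'   `icc_county`, `icc_state`.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "three_level_fit"))
  vp <- pi^2 / 3
  denom <- fit$var_state + fit$var_county + vp
  list(var_person_latent = vp,
       var_county = fit$var_county,
       var_state = fit$var_state,
       icc_county = (fit$var_state + fit$var_county) / denom,
       icc_state = fit$var_state / denom)
}

#' Predicted late-stage probabilities
#'
#' Inverse-logit of the linear predictor, optionally including the
#' empirical-Bayes county and state intercepts. Clusters unseen at fit time
#' contribute a random effect of zero (counted in a message).
#'
#' @param fit a [fit_three_level_logit()] object.
#' @param x design matrix with the same columns as at fit time.
#' @param county,state cluster id vectors aligned with rows of `x`.
#' @param include_random add the empirical-Bayes intercepts (default TRUE).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_probabilities <- function(fit, x, county, state,
                                  include_random = TRUE) {
  stopifnot(inherits(fit, "three_level_fit"))
  x <- as.matrix(x)
  if (!identical(colnames(x), fit$terms))
    stop("design columns do not match the fitted model", call. = FALSE)
  eta <- drop(x %*% fit$beta)
  if (include_random) {
    u <- fit$eb_county[as.character(county)]
    v <- fit$eb_state[as.character(state)]
    n_new <- sum(is.na(u)) + sum(is.na(v))
    if (n_new > 0)
      message(n_new, " row(s) in clusters unseen at fit time; ",
              "their random effects set to 0")
    u[is.na(u)] <- 0; v[is.na(v)] <- 0
    eta <- eta + unname(u) + unname(v)
  }
  plogis(eta)
}

#' Write the odds-ratio and variance-component tables as CSV
#'
#' @param fit a [fit_three_level_logit()] object.
#' @param or_path,vc_path output file paths.
#' @param level confidence level passed to [summarize_odds_ratios()].
#' @return invisible list of the two tables.
#' @export
write_fit_tables <- function(fit, or_path, vc_path, level = 0.95) {
  or <- summarize_odds_ratios(fit, level = level, allow_unconverged = TRUE)
  vcs <- variance_components(fit)
  vc <- data.frame(component = c("person_latent", "county", "state"),
                   variance = c(vcs$var_person_latent, vcs$var_county,
                                vcs$var_state),
                   icc = c(NA, vcs$icc_county, vcs$icc_state))
  write.csv(or, or_path, row.names = FALSE, na = "")
  write.csv(vc, vc_path, row.names = FALSE, na = "")
  invisible(list(odds_ratios = or, variance_components = vc))
}
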