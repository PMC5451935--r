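#' @useDynLib isostage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats glm.fit binomial optim plogis qlogis qnorm pnorm rnorm
#'   rpois rmultinom rbinom rgamma runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gauss-Hermite nodes and weights
#'
#' Abscissae and weights for \eqn{\int e^{-x^2} f(x)\,dx \approx \sum_t w_t
#' f(a_t)} via the Golub-Welsch eigen-decomposition of the Jacobi matrix.
#' Used internally by the adaptive-quadrature likelihood.
#'
#' @param n number of nodes (positive integer); `n = 1` gives the single
#'   node 0 with weight \eqn{\sqrt{\pi}} (the Laplace limit).
#' @return list with numeric `nodes` and `weights`, both length `n`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = e$vectors[1L, ord]^2 * sqrt(pi))
}

# Central-difference Hessian of a scalar function; rel. step per coordinate.
num_hessian <- function(fn, par, rel_step = 1e-5) {
  p <- length(par)
  h <- rel_step * pmax(abs(par), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    fp <- fn(par + ei); fm <- fn(par - ei)
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic per-stage seed derivation (a Lehmer-style multiplier with
#' an additive offset, reduced modulo a 31-bit prime) so that pipeline
#' stages and replicate runs can draw from distinct, reproducible RNG
#' streams controlled by one master seed.
#'
#' @param seed master integer seed.
#' @param offset integer stream offset (stage or replicate number).
#' @return a positive integer seed below 2^31.
#' @export
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587) + 1L
}

assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
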