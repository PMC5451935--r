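#' County-level observed vs predicted aggregation
#'
#' Aggregates person-level outcomes and model predictions to the county
#' level: observed late-stage proportion, mean predicted probability, and
#' their difference (observed minus predicted, the sign convention used in
#' every output of this package). The case-weighted mean of the observed
#' proportions equals the overall sample prevalence.
#'
#' @param county_id county identifier per person.
#' @param y binary outcome per person.
#' @param p predicted probability per person, in (0, 1).
#' @return data frame with `county_id`, `n_cases`, `observed_prop`,
#'   `mean_predicted`, `difference`.
#' @export
aggregate_county <- function(county_id, y, p) {
  stopifnot(length(county_id) == length(y), length(y) == length(p))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("predictions must lie strictly in (0, 1)", call. = FALSE)
  f <- factor(as.character(county_id),
              levels = unique(as.character(county_id)))
  n <- as.integer(table(f))
  obs <- as.numeric(tapply(y, f, sum)) / n
  pred <- as.numeric(tapply(p, f, mean))
  data.frame(county_id = levels(f), n_cases = n, observed_prop = obs,
             mean_predicted = pred, difference = obs - pred,
             stringsAsFactors = FALSE)
}

#' Flag counties with outlying observed-minus-predicted differences
#'
#' Flags both tails: counties whose difference lies at least `k` standard
#' deviations (population SD, denominator n) from the mean difference.
#'
#' @param diagnostics data frame from [aggregate_county()].
#' @param k number of standard deviations (default 2).
#' @return `diagnostics` with a logical `outlier_flag` column.
#' @export
flag_outliers <- function(diagnostics, k = 2) {
  assert_columns(diagnostics, "difference", "diagnostics table")
  if (nrow(diagnostics) < 3L)
    stop("need at least 3 counties to flag outliers", call. = FALSE)
  d <- diagnostics$difference
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))
  if (s == 0) {
    message("zero variance in differences; no outliers flagged")
    diagnostics$outlier_flag <- FALSE
    return(diagnostics)
  }
  # inclusive at the boundary, with a small fp guard
  diagnostics$outlier_flag <- abs(d - m) >= k * s * (1 - 1e-12)
  diagnostics
}

#' Build a spatial weights matrix for counties
#'
#' Queen/rook-style contiguity from an explicit adjacency pair list, or
#' k-nearest-neighbour weights from county centroids (asymmetric allowed:
#' each county points to its k nearest). Optionally row-standardized so
#' each non-isolated row sums to 1.
#'
#' @param ids character vector of county ids (the matrix ordering).
#' @param adjacency data frame with columns `from`, `to` (undirected pairs;
#'   required for `scheme = "queen"`).
#' @param centroids data frame with columns `county_id`, `x`, `y`
#'   (required for `scheme = "knn"`).
#' @param scheme `"queen"` or `"knn"`.
#' @param k neighbours per county for the knn scheme (default 5).
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return an object of class `"spatial_weights"`: list with `ids`, `w`
#'   (dense matrix, zero diagonal, non-negative), `scheme`,
#'   `row_standardized`.
#' @export
build_weights <- function(ids, adjacency = NULL, centroids = NULL,
                          scheme = c("queen", "knn"), k = 5,
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 counties", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate county ids", call. = FALSE)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (scheme == "queen") {
    if (is.null(adjacency))
      stop("queen scheme requires an adjacency pair list", call. = FALSE)
    assert_columns(adjacency, c("from", "to"), "adjacency list")
    i <- match(as.character(adjacency$from), ids)
    j <- match(as.character(adjacency$to), ids)
    if (anyNA(i) || anyNA(j))
      stop("adjacency references unknown county ids", call. = FALSE)
    if (any(i == j)) stop("self-adjacency is not allowed", call. = FALSE)
    w[cbind(i, j)] <- 1; w[cbind(j, i)] <- 1
  } else {
    if (is.null(centroids))
      stop("knn scheme requires county centroids", call. = FALSE)
    assert_columns(centroids, c("county_id", "x", "y"), "centroid table")
    m <- match(ids, as.character(centroids$county_id))
    if (anyNA(m)) stop("centroid missing for county ids: ",
                       paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
    if (k >= n) stop("k must be smaller than the number of counties",
                     call. = FALSE)
    xy <- cbind(centroids$x[m], centroids$y[m])
    dm <- as.matrix(stats::dist(xy))
    diag(dm) <- Inf
    for (r in seq_len(n)) w[r, order(dm[r, ])[seq_len(k)]] <- 1
  }
  iso <- rowSums(w) == 0 & colSums(w) == 0
  if (any(iso))
    warning(sum(iso), " isolated county/ies retained with zero weight rows")
  if (row_standardize) {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(ids = ids, w = w, scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Global Moran's I with a permutation test
#'
#' The cross-product spatial autocorrelation statistic
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} (z_i - \bar z)(z_j - \bar
#' z)}{\sum_i (z_i - \bar z)^2}, \quad S_0 = \sum_{ij} w_{ij},}
#' ranging (approximately) over \eqn{[-1, 1]}: -1 indicates perfect
#' dispersion, values near the permutation expectation \eqn{-1/(n-1)}
#' spatial randomness, and values near +1 perfect clustering. Significance
#' is assessed by a two-sided permutation test: values are randomly
#' relabelled across counties and
#' \eqn{p = (1 + \#\{|I_{perm}| \ge |I_{obs}|\}) / (1 + n_{perm})}.
#'
#' @param values per-county values (e.g. observed-minus-predicted
#'   differences), finite, non-constant.
#' @param weights a [build_weights()] object, or a bare non-negative matrix
#'   with zero diagonal. Counties whose weight row and column are entirely
#'   zero are dropped from the statistic (counted in a message).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draws.
#' @return an object of class `"moran_result"`: list with `I`,
#'   `expected_I` (\eqn{-1/(n-1)}), `perm_p`, `n_perm`, `seed`, `n`,
#'   `scheme`, `row_standardized`.
#' @export
global_morans_i <- function(values, weights, n_perm = 999, seed = 1L) {
  if (inherits(weights, "spatial_weights")) {
    w <- weights$w
    scheme <- weights$scheme
    row_std <- weights$row_standardized
  } else {
    w <- as.matrix(weights)
    scheme <- "custom"; row_std <- NA
  }
  n <- length(values)
  stopifnot(nrow(w) == n, ncol(w) == n)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(w < 0) || any(diag(w) != 0))
    stop("weights must be non-negative with a zero diagonal", call. = FALSE)
  drop_i <- rowSums(w) == 0 & colSums(w) == 0
  if (any(drop_i)) {
    message(sum(drop_i), " count(y/ies) with all-zero weights dropped ",
            "from the Moran statistic")
    w <- w[!drop_i, !drop_i, drop = FALSE]
    values <- values[!drop_i]
    n <- length(values)
  }
  if (n < 3L) stop("need at least 3 weighted counties", call. = FALSE)
  S0 <- sum(w)
  if (S0 <= 0) stop("need at least one positive weight", call. = FALSE)
  moran_stat <- function(z) {
    zc <- z - mean(z)
    denom <- sum(zc^2)
    if (denom == 0) stop("values are constant; Moran's I is undefined",
                         call. = FALSE)
    (n / S0) * drop(crossprod(zc, w %*% zc)) / denom
  }
  I_obs <- moran_stat(values)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(moran_stat(values[sample.int(n)])) >= abs(I_obs))
      exceed <- exceed + 1L
  }
  structure(list(I = I_obs, expected_I = -1 / (n - 1),
                 perm_p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 n = n, scheme = scheme, row_standardized = row_std),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Global Moran's I (differences = observed - predicted)\n")
  cat(sprintf("  I = %.5f, E[I] = %.5f (n = %d, scheme = %s)\n",
              x$I, x$expected_I, x$n, x$scheme))
  cat(sprintf("  two-sided permutation p = %.4f (%d permutations, seed %d)\n",
              x$perm_p, x$n_perm, x$seed))
  invisible(x)
}

#' Write the county diagnostics CSV and the Moran report JSON
#'
#' @param diagnostics flagged diagnostics table from [flag_outliers()].
#' @param moran a [global_morans_i()] result (or `NULL` to skip).
#' @param diag_path,moran_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_diagnostics <- function(diagnostics, moran, diag_path, moran_path) {
  write.csv(diagnostics, diag_path, row.names = FALSE, na = "")
  if (!is.null(moran))
    jsonlite::write_json(unclass(moran), moran_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(c(diag_path, if (!is.null(moran)) moran_path))
}
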