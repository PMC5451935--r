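test_that("county aggregation reproduces hand arithmetic and conserves mass", {
  d <- aggregate_county(rep("cA", 4), c(1, 0, 0, 1), c(0.6, 0.2, 0.3, 0.5))
  expect_equal(d$observed_prop, 0.5)
  expect_equal(d$mean_predicted, 0.4)
  expect_equal(d$difference, 0.1)
  expect_equal(d$n_cases, 4L)

  set.seed(8)
  cty <- sample(sprintf("c%d", 1:6), 200, replace = TRUE)
  y <- rbinom(200, 1, 0.3)
  p <- runif(200, 0.05, 0.95)
  agg <- aggregate_county(cty, y, p)
  expect_equal(sum(agg$observed_prop * agg$n_cases) / sum(agg$n_cases),
               mean(y), tolerance = 1e-12)
  # single-county cohort: observed prop equals overall prevalence
  one <- aggregate_county(rep("cx", 50), y[1:50], p[1:50])
  expect_equal(one$observed_prop, mean(y[1:50]))
})

test_that("outlier flags use mean +/- k SD on both tails", {
  d <- data.frame(county_id = paste0("c", 1:5),
                  difference = c(0, 0, 0, 0, 0.5))
  out <- flag_outliers(d, k = 2)
  expect_equal(out$outlier_flag, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  flat <- data.frame(county_id = paste0("c", 1:4), difference = rep(0.1, 4))
  expect_message(res <- flag_outliers(flat), "zero variance")
  expect_false(any(res$outlier_flag))

  expect_false(any(flag_outliers(d, k = Inf)$outlier_flag))
  # both tails
  d2 <- data.frame(difference = c(-0.5, 0, 0, 0, 0, 0.5))
  out2 <- flag_outliers(d2, k = 1.5)
  expect_equal(out2$outlier_flag,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(flag_outliers(d[1:2, , drop = FALSE]), "at least 3")
})

test_that("queen weights from a pair list give the expected degrees", {
  adj <- grid_adjacency(2, 2)
  w <- build_weights(sprintf("q%03d", 1:4), adjacency = adj,
                     scheme = "queen", row_standardize = FALSE)
  expect_true(all(rowSums(w$w) == 2))  # rook grid: degree 2 everywhere
  expect_true(all(diag(w$w) == 0))
  expect_true(isSymmetric(w$w))

  wr <- build_weights(sprintf("q%03d", 1:4), adjacency = adj,
                      scheme = "queen", row_standardize = TRUE)
  expect_true(all(abs(rowSums(wr$w) - 1) < 1e-12))
  expect_equal(sort(unique(wr$w[1, wr$w[1, ] > 0])), 0.5)
})

test_that("knn weights link each point to its nearest neighbours", {
  cent <- data.frame(county_id = c("a", "b", "c"),
                     x = c(0, 1, 2), y = c(0, 0, 0))
  w <- build_weights(c("a", "b", "c"), centroids = cent, scheme = "knn",
                     k = 1, row_standardize = FALSE)
  expect_equal(w$w["a", "b"], 1)  # endpoints link to the middle
  expect_equal(w$w["c", "b"], 1)
  expect_equal(sum(w$w), 3)
  expect_error(build_weights(c("a", "b"), centroids = cent, scheme = "knn",
                             k = 5), "smaller")
})

test_that("checkerboard dispersion gives Moran's I of exactly -1", {
  adj <- grid_adjacency(2, 2)
  ids <- sprintf("q%03d", 1:4)
  w <- build_weights(ids, adjacency = adj, scheme = "queen",
                     row_standardize = FALSE)
  vals <- c(1, -1, -1, 1)  # rowwise grid: neighbours always differ
  m <- global_morans_i(vals, w, n_perm = 99, seed = 3)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected_I, -1 / 3)
})

test_that("two homogeneous blocks on a two-cluster graph cluster strongly", {
  ids <- sprintf("n%d", 1:8)
  within1 <- t(combn(ids[1:4], 2))
  within2 <- t(combn(ids[5:8], 2))
  adj <- data.frame(from = c(within1[, 1], within2[, 1]),
                    to = c(within1[, 2], within2[, 2]))
  w <- build_weights(ids, adjacency = adj, scheme = "queen",
                     row_standardize = TRUE)
  m <- global_morans_i(c(rep(5, 4), rep(-5, 4)) + rnorm(8, 0, 1e-3),
                       w, n_perm = 199, seed = 4)
  expect_gt(m$I, 0.9)
  expect_lt(m$perm_p, 0.05)
})

test_that("Moran's I matches the naive triple loop and ape on random fixtures", {
  skip_if_not_installed("ape")
  for (s in 1:10) {
    set.seed(700 + s)
    n <- sample(5:30, 1)
    w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.3), n, n)
    diag(w) <- 0
    ring <- cbind(1:n, c(2:n, 1))  # keep every row non-isolated
    w[ring] <- pmax(w[ring], 0.5)
    z <- rnorm(n)
    m <- global_morans_i(z, w, n_perm = 9, seed = 1)
    expect_equal(m$I, naive_moran(z, w), tolerance = 1e-12)
    # ape row-standardizes internally; hand it to our statistic the same way
    ws <- w / rowSums(w)
    expect_equal(global_morans_i(z, ws, n_perm = 9, seed = 1)$I,
                 ape::Moran.I(z, w)$observed, tolerance = 1e-10)
  }
})

test_that("Moran's I is invariant to relabelling and affine value changes", {
  set.seed(11)
  n <- 12
  w <- matrix(rbinom(n * n, 1, 0.4), n, n); diag(w) <- 0
  z <- rnorm(n)
  base <- global_morans_i(z, w, n_perm = 9, seed = 1)$I
  perm <- sample(n)
  expect_equal(global_morans_i(z[perm], w[perm, perm], n_perm = 9,
                               seed = 1)$I, base, tolerance = 1e-12)
  expect_equal(global_morans_i(3 - 2.5 * z, w, n_perm = 9, seed = 1)$I,
               base, tolerance = 1e-12)
})

test_that("degenerate Moran inputs are rejected; isolated counties dropped", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(global_morans_i(c(1, 2), w, n_perm = 9), "at least 3")
  w4 <- rbind(cbind(matrix(c(0, 1, 1, 0), 2), 0, 0), 0, 0)
  w4[3, 4] <- w4[4, 3] <- 1
  expect_error(global_morans_i(rep(1, 4), w4, n_perm = 9), "constant")
  w5 <- matrix(0, 4, 4); w5[1, 2] <- w5[2, 1] <- 1
  w5[2, 3] <- w5[3, 2] <- 1
  expect_message(m <- global_morans_i(c(1, -1, 2, 9), w5, n_perm = 9,
                                      seed = 1), "dropped")
  expect_equal(m$n, 3)
})
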