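test_that("whitening recovers identity covariance and hand-computable factors", {
  # data whose sample covariance is exactly the identity
  A <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * sqrt(3) / 2
  expect_equal(cov(A), diag(2), tolerance = 1e-12)
  w <- whiten(A)
  expect_equal(w$cholesky_factor, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(w$values, A, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(w$regularization_used, 0)

  # sample covariance diag(4, 1): L = diag(1/2, 1), column 1 halved
  c1 <- c(1, -1, 1, -1) * sqrt(3) / 2
  c2 <- c(1, 1, -1, -1) * sqrt(3) / 2
  B <- cbind(2 * c1, c2)
  expect_equal(cov(B), diag(c(4, 1)), tolerance = 1e-12, ignore_attr = TRUE)
  wb <- whiten(B)
  expect_equal(wb$cholesky_factor, diag(c(0.5, 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(wb$values[, 1], B[, 1] * 0.5, tolerance = 1e-10)
})

test_that("whitened columns have identity sample covariance on random data", {
  for (seed in 1:5) {
    x <- rand_instance(30, 4, seed = seed)
    w <- whiten(x)
    expect_identical(w$regularization_used, 0)
    expect_equal(cov(w$values), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # L is lower triangular with positive diagonal and L L' = Cov^{-1}
    expect_true(all(w$cholesky_factor[upper.tri(w$cholesky_factor)] == 0))
    expect_true(all(diag(w$cholesky_factor) > 0))
    expect_equal(tcrossprod(w$cholesky_factor), solve(cov(x$values)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("singular covariance errors in strict mode and names the column", {
  x <- matrix(rnorm(20), 10, 2)
  bad <- cbind(a = x[, 1], b = x[, 2], b_copy = x[, 2])
  expect_error(whiten(bad, regularization = 0), "singular covariance")
  expect_error(whiten(bad, regularization = 0), "b_copy|b")
  # default mode proceeds and reports the ridge it applied
  w <- whiten(bad)
  expect_gt(w$regularization_used, 0)
})

test_that("group means split whitened rows as expected", {
  # identical rows: both group means equal that row
  wh <- structure(list(values = matrix(1:3, 4, 3, byrow = TRUE),
                       cholesky_factor = diag(3), regularization_used = 0,
                       m = 3L, n = 4L), class = "whitened_matrix")
  gm <- group_means(allocation(c(1, 1, 0, 0)), wh)
  expect_equal(gm$group1, gm$group0)
  expect_equal(gm$group1, c(1, 2, 3), ignore_attr = TRUE)

  # n = 2: means are the two rows themselves
  x <- rand_instance(6, 2, seed = 1)
  wh <- whiten(x)
  gm <- group_means(allocation(c(1, 1, 0, 0, 0, 0)), wh)
  expect_equal(gm$group1, colMeans(wh$values[1:2, ]), ignore_attr = TRUE)
  expect_equal(gm$group0, colMeans(wh$values[3:6, ]), ignore_attr = TRUE)
  expect_error(group_means(allocation(rep(1, 6)), wh), "empty group")
})

test_that("Mahalanobis balance matches the quadratic-form oracle on all splits", {
  x <- rand_instance(6, 2, seed = 42)
  labs <- enumerate_allocations(6, c(3, 3))
  expect_identical(nrow(labs), 20L)
  wh <- whiten(x)
  for (i in seq_len(nrow(labs))) {
    w <- as.integer(labs[i, ] == 1L)
    expect_equal(mahalanobis_balance(allocation(w), x, whitened = wh),
                 oracle_mahalanobis(w, x$values), tolerance = 1e-10)
  }
})

test_that("duplicated row-pairs split across groups give zero balance", {
  base <- matrix(rnorm(8), 4, 2)
  x <- covariate_matrix(rbind(base, base))
  w <- allocation(c(1, 1, 1, 1, 0, 0, 0, 0))  # one copy of each pair per group
  expect_equal(mahalanobis_balance(w, x), 0, tolerance = 1e-10)
  expect_equal(hybrid_loss(w, x), 0, tolerance = 1e-10)
})

test_that("single-covariate balance is the standardized mean difference", {
  set.seed(3)
  v <- rnorm(10)
  x <- covariate_matrix(cbind(v = v))
  w <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 0)
  expect_equal(mahalanobis_balance(allocation(w), x),
               abs(mean(v[w == 1]) - mean(v[w == 0])) / sd(v),
               tolerance = 1e-10)
})

test_that("hybrid loss dominates Mahalanobis balance on every allocation", {
  x <- rand_instance(8, 3, seed = 11)
  wh <- whiten(x)
  labs <- enumerate_allocations(8, c(4, 4))
  for (i in seq_len(nrow(labs))) {
    a <- allocation(as.integer(labs[i, ] == 1L))
    H <- hybrid_loss(a, x, whitened = wh)
    M <- mahalanobis_balance(a, x, whitened = wh)
    expect_gte(H, M)
    expect_equal(H, oracle_hybrid(a$assignment, x$values), tolerance = 1e-10)
  }
})

test_that("balance losses are invariant under affine recoding and label swap", {
  for (seed in 1:5) {
    x <- rand_instance(12, 3, seed = seed)
    B <- matrix(rnorm(9), 3, 3) + diag(3) * 2   # invertible a.s.
    shift <- rnorm(3)
    y <- covariate_matrix(sweep(x$values %*% B, 2, shift, "+"))
    a <- allocation(rep(c(1, 0), 6))
    # M is invariant under any invertible affine recoding
    expect_equal(mahalanobis_balance(a, x), mahalanobis_balance(a, y),
                 tolerance = 1e-8)
    # H depends on the whitened coordinate system (L1/Linf are not
    # rotation-invariant), so its invariance group is the recodings that
    # leave the Cholesky frame fixed: lower-triangular B with positive
    # diagonal (column rescaling as a special case), plus shifts
    Bt <- matrix(0, 3, 3)
    Bt[lower.tri(Bt, diag = TRUE)] <- rnorm(6)
    diag(Bt) <- abs(diag(Bt)) + 0.5
    yt <- covariate_matrix(sweep(x$values %*% Bt, 2, shift, "+"))
    expect_equal(hybrid_loss(a, x), hybrid_loss(a, yt), tolerance = 1e-8)
    expect_equal(mahalanobis_balance(a, x), mahalanobis_balance(a, yt),
                 tolerance = 1e-8)
    # swapping group labels at n1 = n0 leaves both losses unchanged
    flip <- allocation(1L - a$assignment)
    expect_equal(mahalanobis_balance(a, x), mahalanobis_balance(flip, x),
                 tolerance = 1e-12)
    expect_equal(hybrid_loss(a, x), hybrid_loss(flip, x), tolerance = 1e-12)
  }
})

test_that("covariate matrix constructor validates its invariants", {
  expect_error(covariate_matrix(matrix(1:2, 1, 2)), "at least 2 units")
  expect_error(covariate_matrix(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
  expect_error(covariate_matrix(matrix(1:4, 2, 2), unit_ids = c("a", "a")),
               "unique")
  x <- covariate_matrix(data.frame(a = c(1, 2), b = c(3, 4)))
  expect_identical(x$d, 2L)
})

test_that("covariate CSV round-trip preserves ids and values", {
  x <- rand_instance(5, 3, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_covariates(x, path)
  y <- read_covariates(path)
  expect_identical(y$unit_ids, x$unit_ids)
  expect_equal(y$values, x$values, tolerance = 1e-12)
  # missing values refuse to load
  df <- read.csv(path)
  df[2, 2] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(read_covariates(path), "finite|missing")
})
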