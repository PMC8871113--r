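test_that("lambda mapping follows the equilibration formula", {
  expect_identical(lambda_from_star(0, 5, 15), 0)
  expect_equal(lambda_from_star(0.37, 8, 8), 0.37)   # k = d collapses the map
  expect_equal(lambda_from_star(0.1, 5, 15), 0.25)   # 0.1 / (0.1*(2/3) + 1/3)
  expect_equal(lambda_from_star(1, 3, 9), 1)
  expect_error(lambda_from_star(1.5, 3, 9), "lambda_star")
  expect_error(lambda_from_star(0.5, 0, 9), "k")
})

test_that("the size-keyed defaults reproduce the calibration schedule", {
  expect_equal(default_lambda_star(34), list(lambda_star = 0.1, time_limit = 5))
  expect_equal(default_lambda_star(176),
               list(lambda_star = 0.01, time_limit = 30))
  expect_equal(default_lambda_star(18182),
               list(lambda_star = 0.001, time_limit = 120))
  expect_equal(default_lambda_star(50)$lambda_star, 0.01)
  expect_equal(default_lambda_star(4000)$lambda_star, 0.01)
})

test_that("noise draws are reproducible standard normals", {
  set.seed(1); z1 <- draw_noise(50, 3)
  set.seed(1); z2 <- draw_noise(50, 3)
  expect_identical(z1$values, z2$values)
  set.seed(2)
  z <- draw_noise(1e4, 1)
  expect_lt(abs(mean(z$values)), 4 / sqrt(1e4))
  expect_true(var(drop(z$values)) > 0.94 && var(drop(z$values)) < 1.06)
  expect_error(draw_noise(1, 1), "n >= 2")
})

test_that("pure intentional allocation (lambda = 0) is deterministic", {
  x <- rand_instance(8, 3, seed = 21)   # n1 != n0 avoids the mirror tie
  fits <- lapply(1:4, function(s)
    haphazard(x, n1 = 3, lambda_star = 0, seed = s * 17))
  assigns <- vapply(fits, function(f) paste(f$allocation$assignment,
                                            collapse = ""), "")
  expect_identical(length(unique(assigns)), 1L)
  expect_identical(fits[[1]]$optimality, "proven_optimal")
})

test_that("pure random draws respect sizes and are uniform", {
  set.seed(5)
  for (i in 1:20) {
    a <- pure_random_sample(10, c(3, 7))
    expect_identical(sum(a$assignment), 3L)
  }
  # all 6 allocations of n = 4, n1 = 2 with near-equal frequency
  set.seed(6)
  keys <- replicate(6000, paste(pure_random_sample(4, c(2, 2))$assignment,
                                collapse = ""))
  freq <- table(keys)
  expect_identical(length(freq), 6L)
  expect_gt(suppressWarnings(chisq.test(freq)$p.value), 0.01)
  # inclusion probability n1 / n
  set.seed(7)
  inc <- rowMeans(replicate(4000, pure_random_sample(6, c(2, 4))$assignment))
  expect_true(all(abs(inc - 2 / 6) < 0.03))
  # multi-group sizes respected
  m <- pure_random_sample(9, c(2, 3, 4))
  expect_identical(m$group_sizes, c(2L, 3L, 4L))
})

test_that("rerandomization calibration matches quantile definitions", {
  x <- rand_instance(20, 3, seed = 31)
  set.seed(1)
  cfg_all <- calibrate_rerandomization(x, c(10, 10), p_a = 1, n_draws = 500)
  set.seed(1)
  cfg_med <- calibrate_rerandomization(x, c(10, 10), p_a = 0.5, n_draws = 500)
  wh <- whiten(x)
  set.seed(1)
  crit <- haphazard:::rerand_criterion_values(wh, c(10L, 10L), 500)
  expect_equal(cfg_all$threshold, max(crit), tolerance = 1e-12)
  expect_equal(cfg_med$threshold, median(crit), tolerance = 1e-12)
  # determinism under a fixed seed
  set.seed(2); t1 <- calibrate_rerandomization(x, c(10, 10))$threshold
  set.seed(2); t2 <- calibrate_rerandomization(x, c(10, 10))$threshold
  expect_identical(t1, t2)
})

test_that("rerandomization accepts immediately at an infinite threshold", {
  x <- rand_instance(12, 2, seed = 32)
  cfg <- calibrate_rerandomization(x, c(6, 6), p_a = 1, n_draws = 200)
  cfg$threshold <- Inf
  set.seed(3)
  draws <- replicate(50, attr(rerandomization_sample(x, cfg), "draws"))
  expect_true(all(draws == 1))
})

test_that("accepted rerandomized allocations are better balanced than average", {
  x <- rand_instance(30, 3, seed = 33)
  set.seed(4)
  cfg <- calibrate_rerandomization(x, c(10, 20), p_a = 0.05, n_draws = 2000)
  wh <- whiten(x)
  set.seed(5)
  acc <- replicate(40, mahalanobis_balance(
    rerandomization_sample(x, cfg, whitened = wh), x, whitened = wh))
  set.seed(6)
  unc <- replicate(400, mahalanobis_balance(
    pure_random_sample(30, c(10, 20)), x, whitened = wh))
  expect_lt(mean(acc), mean(unc))
  expect_true(all(acc <= cfg$threshold + 1e-12))
})

test_that("an impossible threshold errors after max_draws", {
  x <- rand_instance(12, 2, seed = 34)
  cfg <- calibrate_rerandomization(x, c(6, 6), p_a = 0.5, n_draws = 200,
                                   max_draws = 5)
  cfg$threshold <- -1
  expect_error(rerandomization_sample(x, cfg), "no acceptable allocation")
})

test_that("haphazard fits are reproducible and carry coherent metadata", {
  x <- rand_instance(30, 4, seed = 35)
  f1 <- haphazard(x, n1 = 10, seed = 9)
  f2 <- haphazard(x, n1 = 10, seed = 9)
  expect_identical(f1$allocation$assignment, f2$allocation$assignment)
  expect_identical(f1$config$lambda_star, 0.1)    # n < 50 default
  expect_identical(f1$config$k, 4L)
  expect_equal(f1$config$lambda, 0.1)             # k = d
  expect_equal(f1$balance$hybrid, hybrid_loss(f1$allocation, x),
               tolerance = 1e-12)
  # simulate() reruns the procedure with fresh noise
  ens <- simulate(f1, nsim = 5, seed = 10)
  expect_identical(ens$r, 5L)
  expect_identical(dim(ens$counts), c(30L, 2L))
  expect_true(all(rowSums(ens$counts) == 5L))
  expect_identical(nrow(ens$stats), 5L)
})

test_that("calibrated haphazard beats pure randomization on median balance", {
  x <- rand_instance(40, 5, seed = 36)
  wh <- whiten(x)
  fit <- haphazard(x, n1 = 20, seed = 12)
  ens <- simulate(fit, nsim = 30, seed = 13)
  hap_M <- vapply(ens$allocations, mahalanobis_balance, numeric(1),
                  x = x, whitened = wh)
  set.seed(14)
  pr_M <- replicate(300, mahalanobis_balance(
    pure_random_sample(40, c(20, 20)), x, whitened = wh))
  expect_lt(median(hap_M), median(pr_M))
})
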