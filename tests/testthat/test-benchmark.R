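test_that("a tiny comparison run is structurally complete and finite", {
  x <- rand_instance(6, 2, seed = 41)
  p <- seq(0.05, 0.30, length.out = 6)
  cmp <- run_comparison(x, p, n1 = 3, r = 2, calibration_draws = 200,
                        reference_draws = 30, seed = 1)
  expect_s3_class(cmp, "sampling_comparison")
  expect_identical(sort(names(cmp$results)),
                   sort(c("haphazard", "rerandomization", "pure_random")))
  for (res in cmp$results) {
    expect_identical(res$ensemble$r, 2L)
    expect_true(is.finite(res$kappa))
    expect_true(all(is.finite(res$balance)))
    expect_true(all(is.finite(res$standardized_differences)))
    expect_true(is.finite(res$error$rmse) && is.finite(res$error$sd))
  }
})

test_that("comparison reports are reproducible from the master seed", {
  x <- rand_instance(20, 3, seed = 42)
  set.seed(99); p <- simulate_prevalence(generate_population(20, seed = 42))
  c1 <- run_comparison(x, p, n1 = 8, r = 5, calibration_draws = 300,
                       reference_draws = 50, seed = 7)
  c2 <- run_comparison(x, p, n1 = 8, r = 5, calibration_draws = 300,
                       reference_draws = 50, seed = 7)
  for (m in c1$methods) {
    expect_identical(c1$results[[m]]$ensemble$counts,
                     c2$results[[m]]$ensemble$counts)
    expect_identical(c1$results[[m]]$error$rmse, c2$results[[m]]$error$rmse)
  }
  # dropping a method does not perturb the others' draws
  c3 <- run_comparison(x, p, n1 = 8, r = 5, reference_draws = 50,
                       methods = c("haphazard", "pure_random"), seed = 7)
  expect_identical(c1$results$haphazard$ensemble$counts,
                   c3$results$haphazard$ensemble$counts)
  expect_identical(c1$results$pure_random$ensemble$counts,
                   c3$results$pure_random$ensemble$counts)
})

test_that("methods order as expected on median balance", {
  pop <- generate_population(50, seed = 43)
  set.seed(44)
  p <- simulate_prevalence(pop)
  cmp <- run_comparison(pop, p, n1 = 15, r = 30, calibration_draws = 2000,
                        reference_draws = 100, seed = 8)
  med <- vapply(cmp$results, function(res) median(res$balance), numeric(1))
  expect_lt(med["haphazard"], med["rerandomization"])
  expect_lt(med["rerandomization"], med["pure_random"])
})

test_that("multi-group comparison with a vaccine scenario reports per-vaccine errors", {
  pop <- generate_population(45, seed = 45)
  set.seed(46)
  p <- simulate_prevalence(pop)
  sc <- vaccine_scenario()
  cmp <- run_comparison(pop, p, group_sizes = sc$group_sizes, scenario = sc,
                        r = 4, calibration_draws = 300, reference_draws = 50,
                        seed = 9, methods = c("haphazard", "pure_random"))
  for (res in cmp$results) {
    expect_identical(names(res$error),
                     c("coronavac", "astrazeneca", "moderna", "pfizer"))
    expect_true(all(vapply(res$error, function(e) is.finite(e$rmse), TRUE)))
    expect_identical(dim(res$standardized_differences), c(4L, 15L))
  }
  expect_equal(cmp$truth, (1 - sc$efficacies) * mean(p), tolerance = 1e-12)
})

test_that("rmse falls with sample size and hits zero at the census", {
  pop <- generate_population(24, seed = 47)
  set.seed(48)
  p <- simulate_prevalence(pop)
  tab <- rmse_vs_sample_size(pop, p, sizes = c(6, 12, 24), r = 20,
                             methods = c("haphazard", "pure_random"),
                             calibration_draws = 200, reference_draws = 50,
                             seed = 10)
  expect_identical(nrow(tab), 6L)
  census <- tab[tab$n1 == 24, ]
  expect_true(all(census$rmse == 0))
  for (m in unique(tab$method)) {
    sub <- tab[tab$method == m, ]
    expect_lte(sub$rmse[sub$n1 == 12], sub$rmse[sub$n1 == 6] * 1.3)
  }
  # a single size reproduces the plain comparison numbers
  tab25 <- rmse_vs_sample_size(pop, p, sizes = 6, r = 20,
                               methods = c("haphazard", "pure_random"),
                               calibration_draws = 200, reference_draws = 50,
                               seed = 10)
  cmp <- run_comparison(pop, p, n1 = 6, r = 20,
                        methods = c("haphazard", "pure_random"),
                        calibration_draws = 200, reference_draws = 50,
                        seed = 10)
  expect_equal(tab25$rmse[tab25$method == "haphazard"],
               cmp$results$haphazard$error$rmse, tolerance = 1e-12)
})

test_that("the trade-off curve has the expected shape and structure", {
  pop <- generate_population(20, seed = 49)
  tc <- tradeoff_curve(pop, n1 = 8, lambda_star_grid = c(0.01, 0.5),
                       r = 15, seed = 11)
  expect_s3_class(tc, "tradeoff_curve")
  expect_identical(nrow(tc), 2L)
  expect_lte(tc$balance[1], tc$balance[2] + 1e-9)
  expect_gte(tc$kappa[1], tc$kappa[2] - 1e-9)
  # single-point grid gives a single row
  tc1 <- tradeoff_curve(pop, n1 = 8, lambda_star_grid = 0.1, r = 5,
                        seed = 12)
  expect_identical(nrow(tc1), 1L)
})
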