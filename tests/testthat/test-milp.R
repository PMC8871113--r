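test_that("two-group model has the printed variable accounting", {
  x <- rand_instance(6, 2, seed = 1)
  z <- draw_noise(6, 2)
  p <- milp_two_group(x, z, 0.3, n1 = 3)
  expect_identical(p$variables$binary, 6L)
  expect_identical(p$variables$abs, 2L * (2L + 2L))
  expect_identical(p$variables$max, 2L)
  expect_identical(p$variables$total, 16L)
})

test_that("lambda endpoints zero out the other block's weights", {
  x <- rand_instance(6, 2, seed = 2)
  z <- draw_noise(6, 3)
  p0 <- milp_two_group(x, z, 0, n1 = 3)
  expect_true(all(p0$l1w[p0$block == 1L] == 0))
  expect_identical(p0$linfw[2L], 0)
  expect_true(all(p0$l1w[p0$block == 0L] > 0))
  p1 <- milp_two_group(x, z, 1, n1 = 3)
  expect_true(all(p1$l1w[p1$block == 0L] == 0))
  expect_identical(p1$linfw[1L], 0)
  expect_error(milp_two_group(x, z, 1.2, n1 = 3), "lambda")
  expect_error(milp_two_group(x, z, 0.5, n1 = 7), "group sizes")
})

test_that("multi-group model matches the four-vaccine Serrana dimensions", {
  x <- rand_instance(45, 3, seed = 3)
  z <- draw_noise(45, 3)
  p <- milp_multi_group(x, z, 0.1, group_sizes = c(12, 11, 11, 11))
  expect_identical(p$variables$binary, 4L * 45L)
  expect_identical(p$variables$abs, 2L * 4L * (3L + 3L))
  expect_identical(p$variables$max, 8L)
  expect_error(milp_multi_group(x, z, 0.1, group_sizes = c(12, 11, 11)),
               "sum")
})

test_that("solver matches the enumeration oracle across lambda values", {
  set.seed(100)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    n1 <- sample(2:(n - 2), 1)
    x <- rand_instance(n, 2)
    z <- rand_instance(n, 2)
    for (lam in c(0, 0.3, 1)) {
      s <- solve_milp(milp_two_group(x, z, lam, n1 = n1))
      b <- brute_force_optimum(x, z, lam, group_sizes = c(n1, n - n1))
      expect_identical(s$optimality, "proven_optimal")
      expect_equal(s$objective_value, b$objective_value, tolerance = 1e-6)
      # linearization exactness: objective equals the recomputed loss
      recomp <- (1 - lam) * hybrid_loss(s$allocation, x) +
        if (lam > 0) lam * hybrid_loss(s$allocation, z) else 0
      expect_equal(s$objective_value, recomp, tolerance = 1e-6)
      expect_identical(sum(s$allocation$assignment), n1)
    }
  }
})

test_that("multi-group solver matches the oracle and g = 2 matches two-group", {
  set.seed(200)
  x <- rand_instance(9, 2)
  z <- rand_instance(9, 2)
  s <- solve_milp(milp_multi_group(x, z, 0.3, group_sizes = c(3, 3, 3)))
  b <- brute_force_optimum(x, z, 0.3, group_sizes = c(3, 3, 3))
  expect_identical(s$optimality, "proven_optimal")
  expect_equal(s$objective_value, b$objective_value, tolerance = 1e-6)
  expect_identical(as.integer(rowSums(s$allocation$assignment)),
                   c(3L, 3L, 3L))

  x8 <- rand_instance(8, 2)
  z8 <- rand_instance(8, 2)
  s2 <- solve_milp(milp_multi_group(x8, z8, 0.2, group_sizes = c(3, 5)))
  stg <- solve_milp(milp_two_group(x8, z8, 0.2, n1 = 3))
  expect_equal(s2$objective_value, stg$objective_value, tolerance = 1e-6)
})

test_that("a perfectly splittable instance reaches objective zero", {
  base <- matrix(rnorm(10), 5, 2)
  x <- covariate_matrix(rbind(base, base))
  s <- solve_milp(milp_two_group(x, NULL, 0, n1 = 5), seed = 4)
  expect_equal(s$objective_value, 0, tolerance = 1e-9)
})

test_that("enumeration counts follow the multinomial coefficients", {
  expect_identical(nrow(enumerate_allocations(6, c(3, 3))), 20L)
  expect_identical(nrow(enumerate_allocations(6, c(2, 2, 2))), 90L)
  labs <- enumerate_allocations(6, c(2, 2, 2))
  expect_identical(nrow(unique(labs)), 90L)
  expect_true(all(apply(labs, 1, function(l) all(table(l) == 2))))
  expect_error(enumerate_allocations(60, c(30, 30)), "too large")
})

test_that("a tiny time limit still yields a feasible incumbent", {
  x <- rand_instance(120, 8, seed = 5)
  z <- draw_noise(120, 8)
  p <- milp_two_group(x, z, 0.01, n1 = 30, time_limit = 0.01)
  s <- solve_milp(p, seed = 6)
  expect_identical(s$optimality, "time_limit_incumbent")
  expect_identical(sum(s$allocation$assignment), 30L)
  expect_true(is.finite(s$objective_value))
})

test_that("solver runs are reproducible under a seed", {
  x <- rand_instance(40, 4, seed = 7)
  z <- draw_noise(40, 4)
  p <- milp_two_group(x, z, 0.05, n1 = 10)
  s1 <- solve_milp(p, seed = 11)
  s2 <- solve_milp(p, seed = 11)
  expect_identical(s1$allocation$assignment, s2$allocation$assignment)
  expect_identical(s1$objective_value, s2$objective_value)
})

test_that("LP export writes a complete audit model", {
  x <- rand_instance(6, 2, seed = 8)
  z <- draw_noise(6, 2)
  p <- milp_two_group(x, z, 0.3, n1 = 3)
  path <- tempfile(fileext = ".lp")
  write_lp(p, path)
  lines <- readLines(path)
  expect_true(any(grepl("^Minimize", lines)))
  expect_true(any(grepl("card:", lines)))
  expect_identical(sum(grepl("absdef_", lines)), 4L)   # one per whitened column
  expect_true(any(grepl("Binaries", lines)))
  pm <- milp_multi_group(x, z, 0.3, group_sizes = c(2, 2, 2))
  write_lp(pm, path)
  lines <- readLines(path)
  expect_identical(sum(grepl("^ col_", lines)), 6L)
  expect_identical(sum(grepl("^ row_", lines)), 3L)
})
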