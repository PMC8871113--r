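#' Compare allocation methods on one population
#'
#' Runs the full repeated-allocation experiment on a population of
#' candidate units: for each method (haphazard, rerandomization, pure
#' randomization), `r` independent allocations are drawn, and the report
#' collects the per-unit assignment counts, Fleiss' kappa, the
#' distributions of standardized between-group mean differences (scaled by
#' [reference_scale()]), the per-repetition prevalence estimates, and their
#' RMSE and SD about the municipality-level truth.  For a multi-group
#' design with a [vaccine_scenario()], per-vaccine infection-rate estimates
#' take the place of prevalence estimates.
#'
#' With a `seed`, every stochastic sub-task (each method, the reference
#' scale, the rerandomization calibration) runs on its own seed derived
#' from the master seed by a fixed per-task offset, so adding or removing
#' a method never perturbs another's draws and the full report is
#' reproducible.
#'
#' @param x Covariate matrix of candidate units.
#' @param p Length-`n` vector of sector prevalences (the response).
#' @param n1 Two-group design: number of sampled sectors (default 25).
#' @param group_sizes Multi-group design: group sizes (overrides `n1`).
#' @param scenario Optional [vaccine_scenario()] for multi-group designs.
#' @param methods Which methods to run.
#' @param r Repetitions per method (default 300).
#' @param lambda_star,k,time_limit Haphazard settings (defaults keyed on
#'   `n`; see [haphazard()]).
#' @param p_a Rerandomization acceptance probability (default 0.01).
#' @param calibration_draws Monte-Carlo draws for the rerandomization
#'   threshold (default `1e4`).
#' @param reference_draws Pure random draws for the reference scale
#'   (default 300).
#' @param seed Optional master seed.
#' @param n_restarts Local-search restarts passed to the solver.
#' @return An object of class `"sampling_comparison"`.
#' @export
run_comparison <- function(x, p, n1 = 25, group_sizes = NULL,
                           scenario = NULL,
                           methods = c("haphazard", "rerandomization",
                                       "pure_random"),
                           r = 300, lambda_star = NULL, k = NULL,
                           time_limit = NULL, p_a = 0.01,
                           calibration_draws = 1e4, reference_draws = 300,
                           seed = NULL, n_restarts = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  x <- as_covariate_matrix(x)
  if (length(p) != x$n) stop("'p' must have one entry per unit")
  if (r < 2) stop("need r >= 2 repetitions")
  two <- is.null(group_sizes)
  sizes <- if (two) c(n1, x$n - n1) else as.integer(group_sizes)
  if (!is.null(scenario) && two)
    stop("a vaccine scenario needs a multi-group design")
  offsets <- c(haphazard = 101000L, rerandomization = 202000L,
               pure_random = 303000L, reference = 404000L,
               calibration = 505000L)
  task_seed <- function(task)
    if (is.null(seed)) NULL else (seed + offsets[[task]]) %% .Machine$integer.max
  wh <- whiten(x)

  ts <- task_seed("reference")
  if (!is.null(ts)) set.seed(ts)
  scale <- reference_scale(x, sizes, n_draws = reference_draws)

  theta <- municipality_prevalence(p)
  truth <- if (is.null(scenario)) theta
           else (1 - scenario$efficacies) * theta

  draw_method <- function(method) {
    ts <- task_seed(method)
    if (!is.null(ts)) set.seed(ts)
    allocs <- vector("list", r)
    draws <- rep(NA_real_, r)
    if (method == "haphazard") {
      for (a in seq_len(r)) {
        fit <- haphazard(x, n1 = if (two) sizes[1L],
                         group_sizes = if (!two) sizes,
                         lambda_star = lambda_star, k = k,
                         time_limit = time_limit, n_restarts = n_restarts)
        allocs[[a]] <- fit$allocation
      }
    } else if (method == "rerandomization") {
      cs <- task_seed("calibration")
      if (!is.null(cs)) set.seed(cs)
      cfg <- calibrate_rerandomization(x, sizes, p_a = p_a,
                                       n_draws = calibration_draws)
      ts <- task_seed(method)
      if (!is.null(ts)) set.seed(ts)
      for (a in seq_len(r)) {
        al <- rerandomization_sample(x, cfg, whitened = wh)
        draws[a] <- attr(al, "draws")
        allocs[[a]] <- al
      }
    } else {
      for (a in seq_len(r)) allocs[[a]] <- pure_random_sample(x$n, sizes)
    }
    ens <- allocation_ensemble(allocs)
    balance <- vapply(allocs, function(al) {
      if (two) mahalanobis_balance(al, x, whitened = wh)
      else centroid_mahalanobis_sq(al, x, whitened = wh)
    }, numeric(1L))
    if (two) {
      sdiff <- standardized_differences(allocs, x, scale)
      est <- vapply(allocs, sample_estimator, numeric(1L), p = p)
      err <- rmse_sd(est, theta)
    } else {
      sdiff <- t(vapply(allocs, max_pairwise_std_diff, numeric(x$d),
                        x = x, scale = scale))
      if (!is.null(scenario)) {
        IR <- vaccine_infection_rates(p, scenario)
        est <- t(vapply(allocs, function(al) {
          vapply(seq_len(al$g), function(q)
            mean(IR[q, al$labels == q]), numeric(1L))
        }, numeric(length(scenario$efficacies))))
        colnames(est) <- names(scenario$efficacies)
        err <- lapply(seq_along(truth), function(v)
          rmse_sd(est[, v], truth[v]))
        names(err) <- names(scenario$efficacies)
      } else {
        est <- NULL
        err <- NULL
      }
    }
    list(method = method, ensemble = ens, kappa = fleiss_kappa(ens),
         balance = balance, standardized_differences = sdiff,
         estimates = est, error = err, rerand_draws = draws)
  }

  results <- lapply(methods, draw_method)
  names(results) <- methods
  structure(list(results = results, methods = methods, r = r,
                 sizes = sizes, two_group = two, theta = theta,
                 truth = truth, scenario = scenario,
                 reference_scale = scale, seed = seed),
            class = "sampling_comparison")
}

#' @export
print.sampling_comparison <- function(x, ...) {
  cat("Allocation method comparison:", x$r, "repetitions, group sizes (",
      paste(x$sizes, collapse = ", "), ")\n")
  if (x$two_group) {
    cat(sprintf("True prevalence theta = %.4f\n\n", x$theta))
    tab <- do.call(rbind, lapply(x$results, function(res)
      data.frame(kappa = res$kappa,
                 median_balance = median(res$balance),
                 rmse = res$error$rmse, sd = res$error$sd)))
    print(round(tab, 5))
  } else {
    cat(sprintf("True prevalence theta = %.4f\n", x$theta))
    for (m in x$methods) {
      res <- x$results[[m]]
      cat("\n", m, ": kappa = ", round(res$kappa, 4),
          ", median centroid M^2 = ",
          format(median(res$balance), digits = 4), "\n", sep = "")
      if (!is.null(res$error)) {
        tab <- do.call(rbind, lapply(res$error, function(e)
          data.frame(rmse = e$rmse, sd = e$sd)))
        print(round(tab, 5))
      }
    }
  }
  invisible(x)
}

#' @export
plot.sampling_comparison <- function(x, covariate = 1L, ...) {
  vals <- lapply(x$results, function(res)
    res$standardized_differences[, covariate])
  boxplot(vals, ylab = "standardized mean difference",
          main = paste("Balance on covariate", covariate), ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' Balance / decoupling trade-off curve over the noise weight
#'
#' For each value of `lambda_star` on the grid, draws `r` haphazard
#' allocations and records a high quantile (default the 95th percentile)
#' of the Mahalanobis balance together with Fleiss' kappa over the `r`
#' repetitions.  Small `lambda_star` gives near-optimal balance but high
#' agreement across repetitions (poor decoupling); increasing it trades
#' balance for decoupling.  The same `r` noise matrices are reused across
#' the grid (common random numbers), so the curve is monotone apart from
#' solver effects rather than Monte-Carlo noise.
#'
#' @param x Covariate matrix.
#' @param n1 Number of sampled units (two-group design).
#' @param lambda_star_grid Grid of equilibrated noise weights (default
#'   `c(0.005, 0.01, 0.05, 0.1, 0.25, 0.5)`).
#' @param r Repetitions per grid point (default 100).
#' @param k Noise dimension (default `d`).
#' @param balance_prob Quantile of the balance distribution to report
#'   (default 0.95).
#' @param time_limit,n_restarts Solver settings.
#' @param seed Optional seed.
#' @return A data frame of class `"tradeoff_curve"` with columns
#'   `lambda_star`, `lambda`, `balance` (the `balance_prob` quantile of
#'   Mahalanobis balance) and `kappa`.
#' @export
tradeoff_curve <- function(x, n1,
                           lambda_star_grid = c(0.005, 0.01, 0.05, 0.1,
                                                0.25, 0.5),
                           r = 100, k = NULL, balance_prob = 0.95,
                           time_limit = NULL, n_restarts = 10L,
                           seed = NULL) {
  if (any(lambda_star_grid < 0 | lambda_star_grid > 1))
    stop("'lambda_star_grid' must lie in [0, 1]")
  x <- as_covariate_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k)) k <- x$d
  if (is.null(time_limit)) time_limit <- default_lambda_star(x$n)$time_limit
  wh <- whiten(x)
  zs <- lapply(seq_len(r), function(a) draw_noise(x$n, k))
  solver_seeds <- sample.int(.Machine$integer.max, r)
  rows <- lapply(lambda_star_grid, function(ls) {
    lambda <- lambda_from_star(ls, k, x$d)
    allocs <- vector("list", r)
    M <- numeric(r)
    for (a in seq_len(r)) {
      problem <- milp_two_group(x, zs[[a]], lambda, n1 = n1,
                                time_limit = time_limit)
      res <- solve_milp(problem, seed = solver_seeds[a],
                        n_restarts = n_restarts)
      allocs[[a]] <- res$allocation
      M[a] <- mahalanobis_balance(res$allocation, x, whitened = wh)
    }
    data.frame(lambda_star = ls, lambda = lambda,
               balance = unname(quantile(M, balance_prob)),
               kappa = fleiss_kappa(allocation_ensemble(allocs)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tradeoff_curve", "data.frame")
  out
}

#' @export
plot.tradeoff_curve <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$lambda_star, x$balance, log = "x", type = "b",
       xlab = expression(lambda^"*"), ylab = "95th pct Mahalanobis balance",
       main = "Balance", ...)
  plot(x$lambda_star, x$kappa, log = "x", type = "b",
       xlab = expression(lambda^"*"), ylab = "Fleiss' kappa",
       main = "Decoupling", ...)
  invisible(x)
}

#' Estimator error as a function of sample size
#'
#' Repeats the method comparison at each sample size and tabulates the
#' RMSE and SD of the prevalence estimator, the basis for reading off the
#' sample size (hence field operating cost) each method needs to hit a
#' target precision.  `n1 = n` is the census case: the estimator is exact
#' and the error is zero for every method.
#'
#' @param x Covariate matrix.
#' @param p Sector prevalences.
#' @param sizes Integer vector of sample sizes `n1` to evaluate.
#' @param ... Passed to [run_comparison()] (methods, r, seed, ...).
#' @return Data frame with columns `n1`, `method`, `rmse`, `sd`, `kappa`.
#' @export
rmse_vs_sample_size <- function(x, p, sizes, ...) {
  x <- as_covariate_matrix(x)
  rows <- lapply(sizes, function(n1) {
    if (n1 >= x$n) {
      args <- list(...)
      methods <- if (is.null(args$methods))
        c("haphazard", "rerandomization", "pure_random") else args$methods
      return(data.frame(n1 = n1, method = methods, rmse = 0, sd = 0,
                        kappa = NA_real_))
    }
    cmp <- run_comparison(x, p, n1 = n1, ...)
    do.call(rbind, lapply(cmp$methods, function(m) {
      res <- cmp$results[[m]]
      data.frame(n1 = n1, method = m, rmse = res$error$rmse,
                 sd = res$error$sd, kappa = res$kappa)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
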