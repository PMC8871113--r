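#' Draw a standard-normal noise matrix
#'
#' The artificial noise block `Z` of the haphazard objective: an `n x k`
#' matrix of independent standard normal draws, wrapped as a covariate
#' matrix.  Uses R's global RNG, so results are reproducible under
#' [set.seed()].
#'
#' @param n Number of units (rows).
#' @param k Number of noise columns.
#' @param unit_ids Optional identifiers (defaults to `"unit_1" ...`).
#' @return A `"covariate_matrix"` with columns `z1 ... zk`.
#' @export
draw_noise <- function(n, k, unit_ids = NULL) {
  if (n < 2L || k < 1L) stop("need n >= 2 and k >= 1")
  Z <- matrix(rnorm(n * k), n, k)
  colnames(Z) <- paste0("z", seq_len(k))
  covariate_matrix(Z, unit_ids = unit_ids)
}

#' Map the equilibrated noise weight to the raw objective weight
#'
#' The raw mixing weight `lambda` multiplies whole loss blocks whose scale
#' depends on the dimensions `d` (covariates) and `k` (noise columns).  The
#' reparametrization
#' \deqn{\lambda = \lambda^* / (\lambda^* (1 - k/d) + k/d)}
#' equilibrates the weight given to the covariate and noise terms across
#' dimensions; when `k = d` it is the identity.
#'
#' @param lambda_star Equilibrated weight in `[0, 1]`.
#' @param k Noise dimension (columns of `Z`).
#' @param d Covariate dimension (columns of `X`).
#' @return The raw weight `lambda` in `[0, 1]`.
#' @examples
#' lambda_from_star(0.1, k = 5, d = 15)  # 0.25
#' @export
lambda_from_star <- function(lambda_star, k, d) {
  if (lambda_star < 0 || lambda_star > 1)
    stop("'lambda_star' must be in [0, 1]")
  if (k < 1 || d < 1) stop("'k' and 'd' must be >= 1")
  lambda_star / (lambda_star * (1 - k / d) + k / d)
}

#' Default noise weight and solver time limit by instance size
#'
#' The empirically calibrated schedule keyed on the number of candidate
#' units: fewer units mean fewer near-optimal allocations, so good
#' decoupling needs a larger noise weight; larger instances need more
#' solver time.
#'
#' @param n_units Number of candidate units.
#' @return List with `lambda_star` and `time_limit` (seconds):
#'   `< 50` units: (0.1, 5); `50--4000`: (0.01, 30); `> 4000`: (0.001, 120).
#' @export
default_lambda_star <- function(n_units) {
  if (n_units < 2) stop("'n_units' must be >= 2")
  if (n_units < 50) list(lambda_star = 0.1, time_limit = 5)
  else if (n_units <= 4000) list(lambda_star = 0.01, time_limit = 30)
  else list(lambda_star = 0.001, time_limit = 120)
}

#' Haphazard intentional allocation
#'
#' The main fitting function of the package.  Draws a fresh Gaussian noise
#' block `Z`, mixes its hybrid balance loss into the covariate balance
#' objective with weight `lambda` (derived from the equilibrated
#' `lambda_star`), and solves the resulting MILP for the best group
#' assignment.  With `lambda_star = 0` this is pure intentional (fully
#' deterministic) allocation; with `lambda_star = 1` the assignment is
#' driven by noise alone and is uniform over feasible allocations.
#' Intermediate values give near-optimal balance while decoupling the
#' selection from any unobserved confounder.
#'
#' @param x Covariate matrix of candidate units (matrix, data frame with an
#'   id column, or [covariate_matrix()]).
#' @param n1 Size of group 1 for a two-group design (sampled / treated
#'   units).  Give either `n1` or `group_sizes`.
#' @param group_sizes Integer vector of group sizes for a multi-group
#'   design.
#' @param lambda_star Equilibrated noise weight; default from
#'   [default_lambda_star()] keyed on `n`.
#' @param k Noise dimension; default `d`, which makes `lambda = lambda_star`.
#' @param lambda Raw noise weight; overrides `lambda_star` when supplied.
#' @param time_limit Solver time limit (seconds); default keyed on `n`.
#' @param mip_gap Relative MIP gap (default `1e-6`).
#' @param seed Optional integer seed for full reproducibility.
#' @param regularization Ridge passed to [whiten()].
#' @param node_budget,n_restarts Passed to [solve_milp()].
#' @return An object of class `"haphazard"`: list with `allocation`,
#'   `objective_value`, `optimality`, `balance` (Mahalanobis and hybrid
#'   losses of the returned allocation on `X`), `config` (lambda_star,
#'   lambda, k, time_limit), `x` (the covariate matrix), `whitened_x`,
#'   `solve` (solver details) and `call`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 3), 40, 3)
#' fit <- haphazard(x, n1 = 20)
#' fit
#' @seealso [simulate.haphazard()] for repeated draws,
#'   [summary.haphazard()] for balance diagnostics.
#' @export
haphazard <- function(x, n1 = NULL, group_sizes = NULL, lambda_star = NULL,
                      k = NULL, lambda = NULL, time_limit = NULL,
                      mip_gap = 1e-6, seed = NULL, regularization = 1e-8,
                      node_budget = 2e6, n_restarts = 10L) {
  cl <- match.call()
  x <- as_covariate_matrix(x)
  if (is.null(n1) == is.null(group_sizes))
    stop("give exactly one of 'n1' or 'group_sizes'")
  sizes <- if (!is.null(n1)) c(n1, x$n - n1) else as.integer(group_sizes)
  if (!is.null(seed)) set.seed(seed)
  defaults <- default_lambda_star(x$n)
  if (is.null(lambda_star)) lambda_star <- defaults$lambda_star
  if (is.null(time_limit)) time_limit <- defaults$time_limit
  if (is.null(k)) k <- x$d
  if (is.null(lambda)) lambda <- lambda_from_star(lambda_star, k, x$d)
  wh_x <- whiten(x, regularization = regularization)

  z <- draw_noise(x$n, k)
  problem <- if (!is.null(n1))
    milp_two_group(x, z, lambda, n1 = sizes[1L], n0 = sizes[2L],
                   time_limit = time_limit, mip_gap = mip_gap,
                   regularization = regularization)
  else
    milp_multi_group(x, z, lambda, group_sizes = sizes,
                     time_limit = time_limit, mip_gap = mip_gap,
                     regularization = regularization)
  res <- solve_milp(problem, node_budget = node_budget,
                    n_restarts = n_restarts)
  balance <- if (!is.null(n1))
    list(mahalanobis = mahalanobis_balance(res$allocation, x, whitened = wh_x),
         hybrid = hybrid_loss(res$allocation, x, whitened = wh_x))
  else
    list(centroid_mahalanobis_sq =
           centroid_mahalanobis_sq(res$allocation, x, whitened = wh_x),
         centroid_hybrid = centroid_hybrid_loss(res$allocation, x,
                                                whitened = wh_x))
  structure(list(
    allocation = res$allocation,
    objective_value = res$objective_value,
    optimality = res$optimality,
    balance = balance,
    config = list(lambda_star = lambda_star, lambda = lambda, k = k,
                  time_limit = time_limit, mip_gap = mip_gap,
                  regularization = regularization,
                  node_budget = node_budget, n_restarts = n_restarts),
    sizes = sizes, two_group = !is.null(n1),
    x = x, whitened_x = wh_x,
    solve = res, call = cl
  ), class = "haphazard")
}

#' Pure random allocation
#'
#' Uniform draw over all allocations with the given group sizes, by a
#' seeded shuffle sliced by sizes.
#'
#' @param n Number of units.
#' @param sizes Group sizes summing to `n`.  Length 2 gives an
#'   [allocation()] (`sizes[1]` is `n1`); longer gives a
#'   [multi_allocation()].
#' @return An `"allocation"` or `"multi_allocation"`.
#' @export
pure_random_sample <- function(n, sizes) {
  sizes <- as.integer(sizes)
  if (sum(sizes) != n) stop("sizes must sum to n")
  labels <- integer(n)
  labels[sample.int(n)] <- rep(seq_along(sizes), sizes)
  if (length(sizes) == 2L) allocation(as.integer(labels == 1L))
  else multi_allocation(labels, group_sizes = sizes)
}

#' Calibrate a rerandomization acceptance threshold
#'
#' Rerandomization accepts a random allocation only when its balance
#' criterion falls below a threshold.  Following the quantile construction,
#' the threshold is set to the empirical `p_a`-quantile of the criterion
#' (Mahalanobis balance for two groups, centroid squared Mahalanobis for
#' multi-group) over `n_draws` pure random allocations, so the acceptance
#' probability is approximately `p_a`.
#'
#' @param x Covariate matrix.
#' @param sizes Group sizes.
#' @param p_a Target acceptance probability in `(0, 1]` (default 0.01).
#' @param n_draws Monte-Carlo draws for the quantile (default `1e4`).
#' @param max_draws Cap on draws per accepted sample in
#'   [rerandomization_sample()]; default `ceiling(50 / p_a)`.
#' @param regularization Ridge passed to [whiten()].
#' @return An object of class `"rerand_config"`: list with `p_a`,
#'   `threshold`, `criterion`, `sizes`, `max_draws`, `n_draws`.
#' @export
calibrate_rerandomization <- function(x, sizes, p_a = 0.01, n_draws = 1e4,
                                      max_draws = ceiling(50 / p_a),
                                      regularization = 1e-8) {
  if (p_a <= 0 || p_a > 1) stop("'p_a' must be in (0, 1]")
  if (n_draws < 100) stop("'n_draws' must be >= 100")
  x <- as_covariate_matrix(x)
  wh <- whiten(x, regularization = regularization)
  sizes <- as.integer(sizes)
  crit <- rerand_criterion_values(wh, sizes, n_draws)
  if (diff(range(crit)) < .Machine$double.eps^0.5) {
    warning("degenerate balance criterion: all simulated values equal; ",
            "threshold set to that value")
    threshold <- crit[1L]
  } else {
    threshold <- unname(quantile(crit, probs = p_a, type = 7))
  }
  structure(list(p_a = p_a, threshold = threshold,
                 criterion = if (length(sizes) == 2L) "mahalanobis"
                             else "centroid_mahalanobis_sq",
                 sizes = sizes, max_draws = as.integer(max_draws),
                 n_draws = as.integer(n_draws)),
            class = "rerand_config")
}

#' @export
print.rerand_config <- function(x, ...) {
  cat("Rerandomization config: p_a =", x$p_a, "; criterion =", x$criterion,
      "; threshold =", format(x$threshold, digits = 6), "\n")
  invisible(x)
}

# internal: vectorized criterion values over pure random draws
rerand_criterion_values <- function(wh, sizes, n_draws) {
  n <- wh$n
  A <- wh$values
  g <- length(sizes)
  if (g == 2L) {
    n1 <- sizes[1L]; n0 <- sizes[2L]
    sel <- replicate(n_draws, {
      ind <- numeric(n); ind[sample.int(n, n1)] <- 1; ind
    })
    s1 <- crossprod(sel, A)            # n_draws x m sums over group 1
    tot <- matrix(colSums(A), n_draws, wh$m, byrow = TRUE)
    delta <- s1 / n1 - (tot - s1) / n0
    sqrt(rowSums(delta^2)) / wh$m
  } else {
    overall <- colMeans(A)
    vapply(seq_len(n_draws), function(i) {
      alloc <- pure_random_sample(n, sizes)
      mns <- rowsum(A, alloc$labels) / sizes
      sum(sweep(mns, 2L, overall)^2) / wh$m
    }, numeric(1L))
  }
}

# internal: criterion of a single allocation under a rerand config
rerand_criterion_one <- function(alloc, wh, config) {
  if (config$criterion == "mahalanobis") {
    gm <- group_means(alloc, wh)
    sqrt(sum((gm$group1 - gm$group0)^2)) / wh$m
  } else {
    mns <- multi_group_means(alloc, wh)
    sum(sweep(mns, 2L, colMeans(wh$values))^2) / wh$m
  }
}

#' Draw one rerandomized allocation
#'
#' Repeatedly draws pure random allocations until the balance criterion
#' falls at or below the calibrated threshold, returning the first
#' acceptable draw.  The number of draws used is recorded in attribute
#' `"draws"` (geometric with mean approximately `1 / p_a`).
#'
#' @param x Covariate matrix.
#' @param config A `"rerand_config"` from [calibrate_rerandomization()].
#' @param regularization Ridge passed to [whiten()].
#' @param whitened Optional precomputed [whiten()] result for `x`.
#' @return An `"allocation"` or `"multi_allocation"` with attribute
#'   `"draws"`.
#' @export
rerandomization_sample <- function(x, config, regularization = 1e-8,
                                   whitened = NULL) {
  stopifnot(inherits(config, "rerand_config"))
  x <- as_covariate_matrix(x)
  wh <- as_whitened(x, whitened, regularization)
  # tolerance guards against one-ulp summation differences when the
  # threshold coincides with an attainable criterion value (tiny instances)
  cut <- config$threshold * (1 + 1e-9) + 1e-12
  for (i in seq_len(config$max_draws)) {
    alloc <- pure_random_sample(x$n, config$sizes)
    if (rerand_criterion_one(alloc, wh, config) <= cut) {
      attr(alloc, "draws") <- i
      return(alloc)
    }
  }
  stop("no acceptable allocation in ", config$max_draws,
       " draws (observed acceptance rate 0; threshold ",
       format(config$threshold, digits = 6), ")")
}
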