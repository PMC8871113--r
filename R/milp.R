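#' Build the two-group haphazard allocation MILP
#'
#' Constructs the mixed-integer linear program that minimizes
#' `(1 - lambda) * H(w, X) + lambda * H(w, Z)` subject to `sum(w) = n1`,
#' where `H` is the hybrid (L1 + Linf) balance loss on the whitened
#' matrices.  Because the group sizes `n1`, `n0` are fixed, the whitened
#' group-mean difference in every column is linear in the binary assignment
#' vector `w`; each absolute value is modeled by a nonnegative pair
#' `t+ - t- = d_j`, and each Linf term by one max variable per block, so
#' the model has `n` binaries plus `2 * (d + k)` absolute-value auxiliaries
#' plus `2` max auxiliaries.
#'
#' @param x Covariate matrix `X` (`n x d`), the covariates of interest.
#' @param z Covariate matrix `Z` (`n x k`) of artificial noise (standard
#'   normal draws; see [draw_noise()]).  May be `NULL` when `lambda = 0`.
#' @param lambda Noise weight in `[0, 1]`.
#' @param n1 Size of group 1 (the sampled / treated group).
#' @param n0 Size of group 0; defaults to `n - n1`.
#' @param time_limit Solver time limit in seconds; default from
#'   [default_lambda_star()]'s schedule keyed on `n`.
#' @param mip_gap Relative optimality gap tolerance (default `1e-6`).
#' @param regularization Ridge passed to [whiten()].
#' @return An object of class `"milp_problem"`.
#' @seealso [solve_milp()], [milp_multi_group()], [write_lp()]
#' @export
milp_two_group <- function(x, z, lambda, n1, n0 = NULL,
                           time_limit = NULL, mip_gap = 1e-6,
                           regularization = 1e-8) {
  x <- as_covariate_matrix(x)
  n <- x$n
  if (is.null(n0)) n0 <- n - n1
  if (n1 < 1L || n0 < 1L || n1 + n0 != n)
    stop("inconsistent group sizes: need n1 >= 1, n0 >= 1, n1 + n0 = n")
  build_problem(x, z, lambda, sizes = c(n1, n0), type = "two_group",
                time_limit = time_limit, mip_gap = mip_gap,
                regularization = regularization)
}

#' Build the multi-group haphazard allocation MILP
#'
#' Constructs the MILP minimizing
#' `(1 - lambda) * Hcentroid(W, X) + lambda * Hcentroid(W, Z)` subject to
#' every unit belonging to exactly one group and group `q` having exactly
#' `group_sizes[q]` units ([centroid_hybrid_loss()]).  Deviations of each
#' whitened group mean from the fixed overall mean are linear in the `g x n`
#' binary matrix `W`; the model has `g * n` binaries, `2 * g * (d + k)`
#' absolute-value auxiliaries and `2 * g` max auxiliaries.
#'
#' @inheritParams milp_two_group
#' @param group_sizes Integer vector of group sizes summing to `n`.
#' @return An object of class `"milp_problem"`.
#' @export
milp_multi_group <- function(x, z, lambda, group_sizes,
                             time_limit = NULL, mip_gap = 1e-6,
                             regularization = 1e-8) {
  x <- as_covariate_matrix(x)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L)) stop("all group sizes must be >= 1")
  if (sum(group_sizes) != x$n)
    stop("group sizes sum to ", sum(group_sizes), ", not n = ", x$n)
  build_problem(x, z, lambda, sizes = group_sizes, type = "multi_group",
                time_limit = time_limit, mip_gap = mip_gap,
                regularization = regularization)
}

# internal: shared builder.  The solver works on the centroid form, which
# for g = 2 coincides exactly with the two-group hybrid objective.
build_problem <- function(x, z, lambda, sizes, type, time_limit, mip_gap,
                          regularization) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("'lambda' must be a single value in [0, 1]")
  wh_x <- whiten(x, regularization = regularization)
  d <- wh_x$m
  if (is.null(z)) {
    if (lambda > 0) stop("'z' is required when lambda > 0")
    wh_z <- NULL
    k <- 0L
  } else {
    z <- as_covariate_matrix(z)
    if (z$n != x$n) stop("'z' must have the same number of rows as 'x'")
    wh_z <- whiten(z, regularization = regularization)
    k <- wh_z$m
  }
  g <- length(sizes)
  if (is.null(time_limit))
    time_limit <- default_lambda_star(x$n)$time_limit
  if (is.null(wh_z)) {
    C <- wh_x$values
    block <- rep(0L, d)
    l1w <- rep((1 - lambda) / d, d)
    linfw <- (1 - lambda) * d
  } else {
    C <- cbind(wh_x$values, wh_z$values)
    block <- c(rep(0L, d), rep(1L, k))
    l1w <- c(rep((1 - lambda) / d, d), rep(lambda / k, k))
    linfw <- c((1 - lambda) * d, lambda * k)
  }
  nb <- length(linfw)
  n_bin <- if (type == "two_group") x$n else g * x$n
  n_abs <- if (type == "two_group") 2L * (d + k) else 2L * g * (d + k)
  n_max <- if (type == "two_group") nb else g * nb
  structure(list(
    type = type, n = x$n, d = d, k = k, lambda = lambda,
    sizes = as.integer(sizes), g = g,
    C = C, block = block, l1w = l1w, linfw = linfw,
    whitened_x = wh_x, whitened_z = wh_z,
    unit_ids = x$unit_ids,
    time_limit = time_limit, mip_gap = mip_gap,
    variables = list(binary = n_bin, abs = n_abs, max = n_max,
                     total = n_bin + n_abs + n_max),
    constraints = if (type == "two_group")
      sprintf("sum(w) = %d", sizes[1L])
    else
      sprintf("column sums of W = 1 (n = %d); row sums of W = (%s)",
              x$n, paste(sizes, collapse = ", "))
  ), class = "milp_problem")
}

#' @export
print.milp_problem <- function(x, ...) {
  cat("Haphazard allocation MILP (", x$type, "): n = ", x$n,
      ", d = ", x$d, ", k = ", x$k, ", lambda = ", signif(x$lambda, 4),
      "\n", sep = "")
  cat("Variables:", x$variables$binary, "binary +", x$variables$abs,
      "abs +", x$variables$max, "max =", x$variables$total, "\n")
  cat("Constraints:", x$constraints, "\n")
  cat("Time limit:", x$time_limit, "s; MIP gap:", x$mip_gap, "\n")
  invisible(x)
}

#' Solve an allocation MILP
#'
#' Solves a problem built by [milp_two_group()] or [milp_multi_group()]
#' with the package's exact depth-first branch-and-bound (per-column
#' achievable-interval lower bounds, units explored in a random order so
#' that tie-breaking among exactly tied optima is symmetric).  Instances
#' whose feasible-allocation count exceeds the node budget are handled by
#' multi-start pairwise-swap local search within the time limit and
#' reported as incumbents rather than proven optima — mirroring how large
#' municipalities are handled in practice under a solver time cap.
#'
#' @param problem A `"milp_problem"`.
#' @param seed Optional integer seed (sets R's RNG; the solver stream is
#'   derived from it).  With a seed, results are reproducible.
#' @param node_budget Maximum branch-and-bound nodes (default `2e6`).
#' @param n_restarts Local-search restarts for large instances (default 10).
#' @param n_kicks Basin-hopping kick/re-polish cycles per restart
#'   (default 25).
#' @return An object of class `"solve_result"`: list with `allocation`
#'   (an [allocation()] or [multi_allocation()]), `objective_value`,
#'   `optimality` (`"proven_optimal"` or `"time_limit_incumbent"`), `gap`
#'   (0 when proven, `NA` otherwise), `solver_seconds`, `nodes`.
#' @export
solve_milp <- function(problem, seed = NULL, node_budget = 2e6,
                       n_restarts = 10L, n_kicks = 25L) {
  stopifnot(inherits(problem, "milp_problem"))
  if (!is.null(seed)) set.seed(seed)
  cpp_seed <- sample.int(.Machine$integer.max, 1L)
  res <- .hz_solve_cpp(problem$C, problem$block, problem$l1w, problem$linfw,
                       problem$sizes, problem$time_limit, node_budget,
                       as.integer(n_restarts), as.integer(n_kicks), cpp_seed)
  alloc <- if (problem$type == "two_group")
    allocation(as.integer(res$labels == 1L))
  else
    multi_allocation(res$labels, group_sizes = problem$sizes)
  structure(list(
    allocation = alloc,
    objective_value = res$objective,
    optimality = if (res$proven_optimal) "proven_optimal"
                 else "time_limit_incumbent",
    gap = if (res$proven_optimal) 0 else NA_real_,
    solver_seconds = res$seconds,
    nodes = res$nodes
  ), class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat("Allocation solve:", x$optimality, "\n")
  cat("Objective:", format(x$objective_value, digits = 8),
      sprintf(" (%.3f s, %g nodes)\n", x$solver_seconds, x$nodes))
  print(x$allocation)
  invisible(x)
}

#' Enumerate all feasible allocations for small instances
#'
#' Lists every labeled partition of `n` units into groups of the given
#' sizes.  Refuses instances with more than `limit` feasible allocations.
#'
#' @param n Number of units.
#' @param sizes Integer vector of group sizes summing to `n`.  For a
#'   two-group problem, pass `c(n1, n0)`; labels 1 and 2 then mean group 1
#'   and group 0.
#' @param limit Maximum number of allocations (default `1e6`).
#' @return Integer matrix, one row per feasible allocation, entries are
#'   group labels in `1..g`.
#' @export
enumerate_allocations <- function(n, sizes, limit = 1e6) {
  sizes <- as.integer(sizes)
  if (sum(sizes) != n) stop("sizes must sum to n")
  count <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (count > limit)
    stop("instance too large: ", format(count, digits = 4),
         " feasible allocations exceed the limit of ", format(limit))
  recurse <- function(units, sizes_left, label) {
    if (length(sizes_left) == 1L) {
      m <- matrix(label, nrow = 1L, ncol = length(units))
      colnames(m) <- as.character(units)
      return(m)
    }
    picks <- combn(length(units), sizes_left[1L])
    out <- vector("list", ncol(picks))
    for (p in seq_len(ncol(picks))) {
      sel <- picks[, p]
      sub <- recurse(units[-sel], sizes_left[-1L], label + 1L)
      full <- matrix(label, nrow = nrow(sub), ncol = length(units))
      colnames(full) <- as.character(units)
      full[, as.character(units[-sel])] <- sub
      out[[p]] <- full
    }
    do.call(rbind, out)
  }
  res <- recurse(seq_len(n), sizes, 1L)
  colnames(res) <- NULL
  res
}

#' Exhaustive-enumeration optimum (verification oracle)
#'
#' Finds the exact optimum of the mixed balance objective by enumerating
#' every feasible allocation and evaluating the loss directly with the
#' balance functions of this package.  Intended as an independent check of
#' [solve_milp()] on small instances; it shares no code with the
#' branch-and-bound.  With `objective = "mahalanobis"` it evaluates the
#' exact (quadratic) Mahalanobis criterion — the objective the hybrid loss
#' is a surrogate for — which is never formulated as a solver model here.
#'
#' @inheritParams milp_two_group
#' @param group_sizes Group sizes; `c(n1, n0)` for two groups.
#' @param objective `"hybrid"` (the MILP objective) or `"mahalanobis"`
#'   (the quadratic criterion: `M` for two groups, centroid squared
#'   Mahalanobis for multi-group).
#' @param limit Maximum feasible-allocation count (default `1e6`).
#' @return A `"solve_result"` with `optimality = "proven_optimal"`.
#' @export
brute_force_optimum <- function(x, z = NULL, lambda = 0, group_sizes,
                                objective = c("hybrid", "mahalanobis"),
                                regularization = 1e-8, limit = 1e6) {
  objective <- match.arg(objective)
  x <- as_covariate_matrix(x)
  if (lambda > 0 && is.null(z)) stop("'z' is required when lambda > 0")
  wh_x <- whiten(x, regularization = regularization)
  wh_z <- if (!is.null(z)) whiten(as_covariate_matrix(z),
                                  regularization = regularization)
  sizes <- as.integer(group_sizes)
  two <- length(sizes) == 2L
  labels_all <- enumerate_allocations(x$n, sizes, limit = limit)
  t0 <- proc.time()[["elapsed"]]
  loss <- function(lab) {
    if (two) {
      a <- allocation(as.integer(lab == 1L))
      f <- if (objective == "hybrid") hybrid_loss else mahalanobis_balance
    } else {
      a <- multi_allocation(lab, group_sizes = sizes)
      f <- if (objective == "hybrid") centroid_hybrid_loss
           else centroid_mahalanobis_sq
    }
    v <- (1 - lambda) * f(a, x, whitened = wh_x)
    if (lambda > 0) v <- v + lambda * f(a, x, whitened = wh_z)
    v
  }
  vals <- apply(labels_all, 1L, loss)
  best <- which.min(vals)
  lab <- labels_all[best, ]
  alloc <- if (two) allocation(as.integer(lab == 1L))
           else multi_allocation(lab, group_sizes = sizes)
  structure(list(
    allocation = alloc,
    objective_value = vals[best],
    optimality = "proven_optimal",
    gap = 0,
    solver_seconds = proc.time()[["elapsed"]] - t0,
    nodes = nrow(labels_all),
    all_values = vals
  ), class = "solve_result")
}

#' Export an allocation MILP in LP file format
#'
#' Writes the full linearization (binaries, absolute-value pairs, max
#' variables, cardinality constraints) in CPLEX LP format for audit with
#' any external MILP tool.
#'
#' @param problem A `"milp_problem"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(problem, path) {
  stopifnot(inherits(problem, "milp_problem"))
  p <- problem
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  M <- ncol(p$C)
  nb <- length(p$linfw)
  if (p$type == "two_group") {
    n1 <- p$sizes[1L]; n0 <- p$sizes[2L]
    coef <- (1 / n1 + 1 / n0) * p$C
    rhs <- colSums(p$C) / n0
    obj <- c(
      unlist(lapply(seq_len(M), function(j)
        sprintf("+ %.12g tp_%d + %.12g tn_%d", p$l1w[j], j, p$l1w[j], j))),
      sprintf("+ %.12g u_%d", p$linfw, seq_len(nb)))
    wl("Minimize"); wl(" obj: ", paste(obj, collapse = " "))
    wl("Subject To")
    for (j in seq_len(M)) {
      terms <- sprintf("%+.12g w_%d", coef[, j], seq_len(p$n))
      wl(sprintf(" absdef_%d: %s - tp_%d + tn_%d = %.12g",
                 j, paste(terms, collapse = " "), j, j, rhs[j]))
      wl(sprintf(" maxlink_%d: tp_%d + tn_%d - u_%d <= 0",
                 j, j, j, p$block[j] + 1L))
    }
    wl(" card: ", paste(sprintf("+ w_%d", seq_len(p$n)), collapse = " "),
       " = ", n1)
    wl("Bounds")
    for (j in seq_len(M)) wl(sprintf(" 0 <= tp_%d", j), "\n 0 <= tn_", j)
    wl("Binaries")
    wl(" ", paste(sprintf("w_%d", seq_len(p$n)), collapse = " "))
  } else {
    abar <- colMeans(p$C)
    obj <- character(0)
    for (q in seq_len(p$g)) {
      obj <- c(obj,
        unlist(lapply(seq_len(M), function(j)
          sprintf("+ %.12g tp_%d_%d + %.12g tn_%d_%d",
                  p$l1w[j], q, j, p$l1w[j], q, j))),
        sprintf("+ %.12g u_%d_%d", p$linfw, q, seq_len(nb)))
    }
    wl("Minimize"); wl(" obj: ", paste(obj, collapse = " "))
    wl("Subject To")
    for (q in seq_len(p$g)) {
      for (j in seq_len(M)) {
        terms <- sprintf("%+.12g w_%d_%d", p$C[, j] / p$sizes[q], q,
                         seq_len(p$n))
        wl(sprintf(" absdef_%d_%d: %s - tp_%d_%d + tn_%d_%d = %.12g",
                   q, j, paste(terms, collapse = " "), q, j, q, j, abar[j]))
        wl(sprintf(" maxlink_%d_%d: tp_%d_%d + tn_%d_%d - u_%d_%d <= 0",
                   q, j, q, j, q, j, q, p$block[j] + 1L))
      }
      wl(sprintf(" row_%d: %s = %d", q,
                 paste(sprintf("+ w_%d_%d", q, seq_len(p$n)), collapse = " "),
                 p$sizes[q]))
    }
    for (i in seq_len(p$n))
      wl(sprintf(" col_%d: %s = 1", i,
                 paste(sprintf("+ w_%d_%d", seq_len(p$g), i), collapse = " ")))
    wl("Binaries")
    for (q in seq_len(p$g))
      wl(" ", paste(sprintf("w_%d_%d", q, seq_len(p$n)), collapse = " "))
  }
  wl("End")
  invisible(path)
}
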