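#' Ensemble of repeated allocations
#'
#' Collects `r` allocations of the same `n` units (from repeated runs of a
#' sampler) and tabulates the per-unit assignment counts `r[i, j]` — the
#' number of times unit `i` landed in group `j` — which drive the
#' decoupling diagnostics.
#'
#' @param allocations List of `"allocation"` or `"multi_allocation"`
#'   objects over the same units.
#' @return An object of class `"allocation_ensemble"`: list with
#'   `allocations`, `counts` (`n x g` integer matrix), `r`, `n`, `g`.
#' @export
allocation_ensemble <- function(allocations) {
  if (length(allocations) < 1L) stop("need at least one allocation")
  labs <- lapply(allocations, alloc_labels)
  n <- length(labs[[1L]])
  if (!all(vapply(labs, length, 1L) == n))
    stop("all allocations must cover the same units")
  g <- max(vapply(labs, max, 1L))
  counts <- matrix(0L, n, g)
  for (lab in labs)
    counts[cbind(seq_len(n), lab)] <- counts[cbind(seq_len(n), lab)] + 1L
  structure(list(allocations = allocations, counts = counts,
                 r = length(allocations), n = n, g = g),
            class = "allocation_ensemble")
}

#' @export
print.allocation_ensemble <- function(x, ...) {
  cat("Allocation ensemble:", x$r, "repetitions over", x$n, "units,",
      x$g, "groups\n")
  invisible(x)
}

#' Fleiss' kappa over repeated allocations
#'
#' Chance-corrected agreement among `r` repeated allocations, treating each
#' repetition as a rater assigning every unit to a group.  Observed
#' agreement is the average proportion of concordant repetition pairs per
#' unit; chance agreement is the sum of squared overall group-assignment
#' proportions.  `kappa = 1` means the sampler returns the same allocation
#' every time (no decoupling); values near 0 mean chance-level agreement
#' (full decoupling, as under pure randomization).
#'
#' @param x An [allocation_ensemble()], or an `n x g` assignment-count
#'   matrix whose rows all sum to the same number of repetitions (at
#'   least 2).
#' @return Kappa (scalar `<= 1`).
#' @examples
#' # two repetitions over 3 units, group sizes (1, 2):
#' a1 <- allocation(c(1, 0, 0)); a2 <- allocation(c(0, 1, 0))
#' fleiss_kappa(allocation_ensemble(list(a1, a2)))  # -1/2
#' @export
fleiss_kappa <- function(x) {
  counts <- if (inherits(x, "allocation_ensemble")) x$counts else as.matrix(x)
  r <- unique(rowSums(counts))
  if (length(r) != 1L) stop("all rows of the count matrix must sum to r")
  if (r < 2L) stop("need r >= 2 repetitions")
  N <- nrow(counts)
  p_obs <- sum(counts * (counts - 1)) / (N * r * (r - 1))
  p_j <- colSums(counts) / (N * r)
  p_exp <- sum(p_j^2)
  if (1 - p_exp < .Machine$double.eps)
    stop("chance agreement is 1 (all mass in one group): kappa undefined")
  (p_obs - p_exp) / (1 - p_exp)
}

#' Standardized between-group mean differences on the raw covariate scale
#'
#' For each allocation and covariate `j`, the difference between the raw
#' (unwhitened) group-1 and group-0 covariate means divided by the
#' reference scale `s_j` (see [reference_scale()]).
#'
#' @param allocations List of `"allocation"` objects (or a single one).
#' @param x Covariate matrix.
#' @param scale Length-`d` positive vector of reference scales.
#' @return Numeric matrix with one row per allocation and one column per covariate (covariate names as columns).
#' @export
standardized_differences <- function(allocations, x, scale) {
  if (inherits(allocations, "allocation")) allocations <- list(allocations)
  x <- as_covariate_matrix(x)
  if (any(scale <= 0)) stop("all reference scales must be > 0")
  if (length(scale) != x$d) stop("'scale' must have one entry per covariate")
  A <- x$values
  out <- vapply(allocations, function(a) {
    stopifnot(inherits(a, "allocation"))
    w <- a$assignment
    (colMeans(A[w == 1L, , drop = FALSE]) -
       colMeans(A[w == 0L, , drop = FALSE])) / scale
  }, numeric(x$d))
  out <- if (x$d == 1L) matrix(out, ncol = 1L) else t(out)
  colnames(out) <- colnames(A)
  out
}

#' Reference scale for standardized differences
#'
#' Per-covariate standard deviation of the between-group raw mean
#' difference over `n_draws` pure random allocations — the yardstick
#' against which each method's balance is standardized.  For multi-group
#' sizes the difference between the first two groups is used.
#'
#' @param x Covariate matrix.
#' @param sizes Group sizes.
#' @param n_draws Number of pure random draws (default 300).
#' @return Length-`d` vector of scales (named by covariate).  A constant
#'   covariate yields scale 0, which is an error downstream.
#' @export
reference_scale <- function(x, sizes, n_draws = 300) {
  if (n_draws < 2) stop("'n_draws' must be >= 2")
  x <- as_covariate_matrix(x)
  sizes <- as.integer(sizes)
  A <- x$values
  diffs <- vapply(seq_len(n_draws), function(i) {
    lab <- alloc_labels(pure_random_sample(x$n, sizes))
    colMeans(A[lab == 1L, , drop = FALSE]) -
      colMeans(A[lab == 2L, , drop = FALSE])
  }, numeric(x$d))
  diffs <- if (x$d == 1L) matrix(diffs, ncol = 1L,
                                 dimnames = list(NULL, colnames(A)))
           else t(diffs)
  apply(diffs, 2L, sd)
}

#' Maximum pairwise standardized difference per covariate
#'
#' For a multi-group allocation, the largest absolute standardized
#' difference in each covariate over all pairs of groups.
#'
#' @param alloc A [multi_allocation()] (a two-group [allocation()] is
#'   accepted and gives the single pair).
#' @param x Covariate matrix.
#' @param scale Length-`d` positive reference scale.
#' @return Length-`d` vector.
#' @export
max_pairwise_std_diff <- function(alloc, x, scale) {
  x <- as_covariate_matrix(x)
  if (any(scale <= 0)) stop("all reference scales must be > 0")
  lab <- alloc_labels(alloc)
  g <- max(lab)
  mns <- rowsum(x$values, lab) / as.integer(table(factor(lab, seq_len(g))))
  out <- numeric(x$d)
  for (q1 in seq_len(g - 1L))
    for (q2 in seq(q1 + 1L, g))
      out <- pmax(out, abs(mns[q1, ] - mns[q2, ]) / scale)
  names(out) <- colnames(x$values)
  out
}

#' RMSE and SD of repeated estimates
#'
#' Root mean square error about the truth (divisor `r`) and standard
#' deviation about the estimate mean (divisor one less than the number of estimates), so that
#' `RMSE^2 = ((r - 1) / r) * SD^2 + bias^2` exactly.
#'
#' @param estimates Numeric vector of at least 2 estimates.
#' @param truth The true value of the estimand.
#' @return List with `rmse`, `sd`, `bias`, `r`.
#' @export
rmse_sd <- function(estimates, truth) {
  r <- length(estimates)
  if (r < 2L) stop("need r >= 2 estimates for SD")
  list(rmse = sqrt(mean((estimates - truth)^2)),
       sd = sd(estimates),
       bias = mean(estimates) - truth,
       r = r)
}

#' Assemble a balance / decoupling report
#'
#' Gathers the decoupling and balance diagnostics of an ensemble into a
#' plain list suitable for JSON export: Fleiss' kappa, the per-covariate
#' reference scale, quartiles of the standardized differences, and (when
#' estimates are supplied) RMSE and SD.
#'
#' @param ensemble An [allocation_ensemble()] of two-group allocations.
#' @param x Covariate matrix.
#' @param scale Reference scale (from [reference_scale()]).
#' @param estimates,truth Optional repeated estimates and estimand for
#'   [rmse_sd()].
#' @param file Optional path; when given (and the `jsonlite` package is
#'   available) the report is also written as JSON.
#' @return A list.
#' @export
balance_report <- function(ensemble, x, scale, estimates = NULL,
                           truth = NULL, file = NULL) {
  sdiff <- standardized_differences(ensemble$allocations, x, scale)
  rep <- list(
    kappa = fleiss_kappa(ensemble),
    reference_scale = as.list(setNames(scale, colnames(sdiff))),
    standardized_difference_quartiles = apply(
      sdiff, 2L, quantile, probs = c(0.25, 0.5, 0.75), simplify = FALSE)
  )
  if (!is.null(estimates)) rep <- c(rep, rmse_sd(estimates, truth))
  if (!is.null(file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON export needs the 'jsonlite' package")
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  }
  rep
}
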