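#' Whiten a covariate matrix by the Cholesky factor of its inverse covariance
#'
#' Computes `A* = A L`, where `L` is the lower-triangular Cholesky factor of
#' the inverse of the sample covariance matrix of `A`, i.e.
#' `Cov(A)^{-1} = L L'`.  After whitening, the sample covariance of the
#' columns of `A*` is the identity, so Euclidean distances between whitened
#' group means are Mahalanobis distances on the original scale.
#'
#' The covariance is the unbiased (divisor `n - 1`) sample covariance over
#' all `n` candidate units, computed once from `A` before any allocation.
#' When the covariance is numerically singular (collinear columns, or `d`
#' close to `n`), a ridge of `regularization * mean(diag(Cov(A)))` is added
#' before inversion and the amount actually applied is recorded; with
#' `regularization = 0` a singular covariance is an error naming the
#' collinear columns.
#'
#' @param x A covariate matrix (anything accepted by
#'   [as_covariate_matrix()]).
#' @param regularization Nonnegative ridge multiplier applied to the mean
#'   diagonal of the covariance when plain inversion fails (default `1e-8`).
#'   Set to `0` for a strict mode that errors instead.
#' @return An object of class `"whitened_matrix"`: list with `values` (the
#'   `n x m` matrix `A*`), `cholesky_factor` (`m x m` lower-triangular `L`),
#'   `regularization_used` (0 when no ridge was needed), `m`, `n`.
#' @examples
#' set.seed(1)
#' w <- whiten(matrix(rnorm(40), 20, 2))
#' round(cov(w$values), 8)   # identity
#' @export
whiten <- function(x, regularization = 1e-8) {
  if (regularization < 0) stop("'regularization' must be nonnegative")
  A <- cov_values(x)
  n <- nrow(A)
  S <- cov(A)
  m <- ncol(A)
  reg_used <- 0
  R <- tryCatch(chol(S), error = function(e) NULL)
  # reject factorizations of numerically singular matrices that chol() let through
  if (!is.null(R) && rcond(S) < 1e-12) R <- NULL
  if (is.null(R)) {
    if (regularization == 0) {
      qrA <- qr(scale(A, center = TRUE, scale = FALSE))
      bad <- colnames(A)[qrA$pivot[seq(qrA$rank + 1L, length.out = m - qrA$rank)]]
      stop("singular covariance: collinear column(s) ",
           paste(bad, collapse = ", "),
           " (use regularization > 0 to proceed)")
    }
    reg_used <- regularization * mean(diag(S))
    R <- chol(S + diag(reg_used, m))
  }
  Sinv <- chol2inv(R)
  L <- t(chol(Sinv))
  dimnames(L) <- list(colnames(A), colnames(A))
  structure(list(values = A %*% L, cholesky_factor = L,
                 regularization_used = reg_used, m = m, n = n),
            class = "whitened_matrix")
}

#' @export
print.whitened_matrix <- function(x, ...) {
  cat("Whitened matrix:", x$n, "x", x$m,
      if (x$regularization_used > 0)
        sprintf("(ridge %.3g applied to covariance)", x$regularization_used)
      else "(no regularization)", "\n")
  invisible(x)
}

# internal: accept a whitened_matrix or whiten on the fly
as_whitened <- function(x, whitened = NULL, regularization = 1e-8) {
  if (!is.null(whitened)) {
    stopifnot(inherits(whitened, "whitened_matrix"))
    return(whitened)
  }
  if (inherits(x, "whitened_matrix")) return(x)
  whiten(x, regularization = regularization)
}

#' Per-group whitened column means
#'
#' For a two-group allocation `w`, returns the averages of each whitened
#' column over the units of group 1 and group 0 respectively.
#'
#' @param alloc An [allocation()].
#' @param whitened A `"whitened_matrix"` (or covariate matrix, whitened on
#'   the fly).
#' @return List with components `group1` and `group0`, each a length-`m`
#'   vector.
#' @export
group_means <- function(alloc, whitened) {
  stopifnot(inherits(alloc, "allocation"))
  wh <- as_whitened(whitened)
  w <- alloc$assignment
  if (length(w) != wh$n) stop("allocation length does not match matrix rows")
  if (alloc$n1 < 1L || alloc$n0 < 1L) stop("empty group in allocation")
  A <- wh$values
  list(group1 = colSums(A[w == 1L, , drop = FALSE]) / alloc$n1,
       group0 = colSums(A[w == 0L, , drop = FALSE]) / alloc$n0)
}

# internal: g x m matrix of whitened group means for a multi-group allocation
multi_group_means <- function(alloc, wh) {
  stopifnot(inherits(alloc, "multi_allocation"))
  if (alloc$n != wh$n) stop("allocation length does not match matrix rows")
  A <- wh$values
  mns <- rowsum(A, group = alloc$labels) / alloc$group_sizes
  mns[order(as.integer(rownames(mns))), , drop = FALSE]
}

#' Mahalanobis balance between two groups
#'
#' The Mahalanobis distance between the covariate means of the two groups,
#' computed as `(1/m) * ||mean1(A*) - mean0(A*)||_2` on the whitened matrix
#' `A*`.  Invariant under any invertible affine recoding of the columns of
#' `A`.
#'
#' @inheritParams group_means
#' @param x Covariate matrix.
#' @param whitened Optional precomputed [whiten()] result for `x` (avoids
#'   re-whitening inside loops).
#' @param regularization Passed to [whiten()] when whitening on the fly.
#' @return Nonnegative scalar.
#' @export
mahalanobis_balance <- function(alloc, x, whitened = NULL,
                                regularization = 1e-8) {
  wh <- as_whitened(x, whitened, regularization)
  gm <- group_means(alloc, wh)
  sqrt(sum((gm$group1 - gm$group0)^2)) / wh$m
}

#' Hybrid (L1 + Linf) balance loss between two groups
#'
#' The linear surrogate for the Mahalanobis balance:
#' `(1/m) * ||delta||_1 + m * ||delta||_inf`, where `delta` is the
#' difference of whitened group means.  Always bounds the Mahalanobis
#' balance from above (`||v||_1 >= ||v||_2`), and is linearizable, which is
#' what turns the allocation problem into a MILP.
#'
#' @inheritParams mahalanobis_balance
#' @return Nonnegative scalar.
#' @export
hybrid_loss <- function(alloc, x, whitened = NULL, regularization = 1e-8) {
  wh <- as_whitened(x, whitened, regularization)
  gm <- group_means(alloc, wh)
  delta <- gm$group1 - gm$group0
  sum(abs(delta)) / wh$m + wh$m * max(abs(delta))
}

#' Centroid hybrid loss for multi-group allocations
#'
#' Sum over groups of the hybrid (L1 + Linf) deviation of each whitened
#' group mean from the overall whitened mean (the mean over all `n` units):
#' `sum_q [ (1/m) ||meanq - mean||_1 + m ||meanq - mean||_inf ]`.
#'
#' @param alloc A [multi_allocation()].
#' @inheritParams mahalanobis_balance
#' @return Nonnegative scalar.
#' @export
centroid_hybrid_loss <- function(alloc, x, whitened = NULL,
                                 regularization = 1e-8) {
  wh <- as_whitened(x, whitened, regularization)
  mns <- multi_group_means(alloc, wh)
  overall <- colMeans(wh$values)
  dev <- sweep(mns, 2L, overall)
  sum(rowSums(abs(dev)) / wh$m + wh$m * apply(abs(dev), 1L, max))
}

#' Pairwise and centroid squared Mahalanobis balance for multiple groups
#'
#' `pairwise_mahalanobis_sq()` sums the squared Euclidean distances between
#' all pairs of whitened group means, divided by `m`.
#' `centroid_mahalanobis_sq()` sums the squared deviations of each whitened
#' group mean from the overall mean over all `n` units, divided by `m`.
#' For equal group sizes the two coincide up to the factor `g` (the
#' pairwise sum equals `g` times the centroid sum about the unweighted mean
#' of group means, which then equals the overall mean).
#'
#' @inheritParams centroid_hybrid_loss
#' @return Nonnegative scalar.
#' @export
pairwise_mahalanobis_sq <- function(alloc, x, whitened = NULL,
                                    regularization = 1e-8) {
  wh <- as_whitened(x, whitened, regularization)
  mns <- multi_group_means(alloc, wh)
  g <- nrow(mns)
  tot <- 0
  for (q1 in seq_len(g - 1L))
    for (q2 in seq(q1 + 1L, g))
      tot <- tot + sum((mns[q1, ] - mns[q2, ])^2)
  tot / wh$m
}

#' @rdname pairwise_mahalanobis_sq
#' @export
centroid_mahalanobis_sq <- function(alloc, x, whitened = NULL,
                                    regularization = 1e-8) {
  wh <- as_whitened(x, whitened, regularization)
  mns <- multi_group_means(alloc, wh)
  overall <- colMeans(wh$values)
  sum(sweep(mns, 2L, overall)^2) / wh$m
}
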