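# small random problem instances used across tests

rand_instance <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covariate_matrix(matrix(rnorm(n * d), n, d))
}

# independent Mahalanobis balance oracle: raw group-mean difference fed
# through the inverse covariance quadratic form (no whitening code shared
# with the implementation)
oracle_mahalanobis <- function(w, A) {
  m <- ncol(A)
  d <- colMeans(A[w == 1, , drop = FALSE]) - colMeans(A[w == 0, , drop = FALSE])
  sqrt(drop(t(d) %*% solve(cov(A)) %*% d)) / m
}

# independent hybrid-loss oracle built from base-R chol/solve only
oracle_hybrid <- function(w, A) {
  m <- ncol(A)
  L <- t(chol(solve(cov(A))))
  dstar <- drop((colMeans(A[w == 1, , drop = FALSE]) -
                   colMeans(A[w == 0, , drop = FALSE])) %*% L)
  sum(abs(dstar)) / m + m * max(abs(dstar))
}
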