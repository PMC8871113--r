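#' @export
print.haphazard <- function(x, ...) {
  cat("Haphazard intentional allocation\n")
  cat("  units:", x$x$n, " covariates:", x$x$d, "\n")
  if (x$two_group)
    cat("  design: two groups, n1 =", x$sizes[1L], ", n0 =", x$sizes[2L], "\n")
  else
    cat("  design:", length(x$sizes), "groups of sizes (",
        paste(x$sizes, collapse = ", "), ")\n")
  cat(sprintf("  lambda* = %g (lambda = %g, k = %d), %s\n",
              x$config$lambda_star, signif(x$config$lambda, 4),
              x$config$k, x$optimality))
  cat("  objective:", format(x$objective_value, digits = 6), "\n")
  for (nm in names(x$balance))
    cat("  ", nm, ": ", format(x$balance[[nm]], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Balance summary of a haphazard allocation
#'
#' Reports the balance losses of the fitted allocation together with
#' per-covariate standardized between-group mean differences, using the
#' pure-randomization reference scale.
#'
#' @param object A `"haphazard"` fit.
#' @param reference_draws Pure random draws used for the reference scale
#'   (default 300).
#' @param seed Optional seed for the reference draws.
#' @param ... Unused.
#' @return An object of class `"summary.haphazard"`.
#' @export
summary.haphazard <- function(object, reference_draws = 300, seed = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  scale <- reference_scale(object$x, object$sizes, n_draws = reference_draws)
  sdiff <- if (object$two_group)
    drop(standardized_differences(object$allocation, object$x, scale))
  else
    max_pairwise_std_diff(object$allocation, object$x, scale)
  structure(list(fit = object, reference_scale = scale,
                 standardized_differences = sdiff,
                 two_group = object$two_group),
            class = "summary.haphazard")
}

#' @export
print.summary.haphazard <- function(x, ...) {
  print(x$fit)
  cat(if (x$two_group)
    "\nStandardized group-mean differences (pure-randomization scale):\n"
    else
    "\nMax pairwise standardized differences (pure-randomization scale):\n")
  print(round(x$standardized_differences, 4))
  invisible(x)
}

#' Repeated haphazard draws
#'
#' Re-runs the fitted allocation procedure `nsim` times, each with a fresh
#' Gaussian noise block, and returns the ensemble of allocations together
#' with per-repetition balance statistics.  This is the sampling
#' distribution the decoupling diagnostics ([fleiss_kappa()]) and the
#' estimator error summaries are computed from.
#'
#' @param object A `"haphazard"` fit.
#' @param nsim Number of repetitions.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return An [allocation_ensemble()] with an extra `stats` element: a
#'   data frame with one row per repetition (`objective`, the balance
#'   losses on `X`, and `optimality`).
#' @export
simulate.haphazard <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  allocs <- vector("list", nsim)
  stats <- vector("list", nsim)
  for (a in seq_len(nsim)) {
    fit <- haphazard(object$x,
                     n1 = if (object$two_group) object$sizes[1L],
                     group_sizes = if (!object$two_group) object$sizes,
                     lambda_star = cfg$lambda_star, k = cfg$k,
                     lambda = cfg$lambda, time_limit = cfg$time_limit,
                     mip_gap = cfg$mip_gap,
                     regularization = cfg$regularization,
                     node_budget = cfg$node_budget,
                     n_restarts = cfg$n_restarts)
    allocs[[a]] <- fit$allocation
    stats[[a]] <- data.frame(objective = fit$objective_value,
                             as.data.frame(fit$balance),
                             optimality = fit$optimality,
                             stringsAsFactors = FALSE)
  }
  ens <- allocation_ensemble(allocs)
  ens$stats <- do.call(rbind, stats)
  ens
}

#' Plot the balance profile of a haphazard allocation
#'
#' Bar chart of per-covariate standardized between-group mean differences
#' of the fitted allocation (maximum pairwise differences for multi-group
#' fits), on the pure-randomization reference scale.
#'
#' @param x A `"haphazard"` fit.
#' @param reference_draws,seed Passed to [summary.haphazard()].
#' @param ... Further arguments for [graphics::barplot()].
#' @return The summary object, invisibly.
#' @export
plot.haphazard <- function(x, reference_draws = 300, seed = NULL, ...) {
  s <- summary(x, reference_draws = reference_draws, seed = seed)
  sd <- s$standardized_differences
  barplot(sd, las = 2, cex.names = 0.7,
          ylab = "standardized mean difference",
          main = "Covariate balance of haphazard allocation", ...)
  abline(h = 0)
  invisible(s)
}
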