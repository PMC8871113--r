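#' Default marginal specification for census-sector covariates
#'
#' Fifteen socio-demographic covariates of the kind reported per census
#' sector (each sector being roughly 200 households): an average-income
#' column, percentage-scale columns for income/wealth, education, age
#' structure, sanitation and housing, and a household-size column.
#' Income-like columns are lognormal; percentage columns are logit-normal,
#' hence always inside `[0, 100]`.
#'
#' @return Named list, one element per covariate: `list(type = "lognormal",
#'   meanlog, sdlog)` or `list(type = "percentage", mu, sigma)` (`mu`,
#'   `sigma` on the logit scale of the proportion).
#' @export
census_marginals <- function() {
  pct <- function(p, sigma) list(type = "percentage", mu = qlogis(p),
                                 sigma = sigma)
  list(
    income                  = list(type = "lognormal", meanlog = 7.0, sdlog = 0.5),
    pct_zero_income         = pct(0.10, 0.8),
    pct_two_plus_bathrooms  = pct(0.25, 1.0),
    pct_literate            = pct(0.88, 0.6),
    pct_age_under15         = pct(0.24, 0.3),
    pct_age_over65          = pct(0.08, 0.4),
    household_size          = list(type = "lognormal", meanlog = log(3.2), sdlog = 0.12),
    pct_piped_water         = pct(0.85, 1.0),
    pct_sewage              = pct(0.60, 1.2),
    pct_garbage_collection  = pct(0.90, 1.0),
    pct_white               = pct(0.45, 0.8),
    pct_paved_street        = pct(0.70, 1.0),
    pct_owner_occupied      = pct(0.70, 0.5),
    income_per_capita       = list(type = "lognormal", meanlog = 6.0, sdlog = 0.55),
    pct_crowded             = pct(0.15, 0.6)
  )
}

#' Default correlation structure for census-sector covariates
#'
#' A one-factor ("wealth") correlation model: each covariate loads on a
#' common latent factor with a sign and strength reflecting how it tracks
#' sector affluence (income positively, zero-income and crowding
#' negatively, sanitation and wealth-proxy columns positively), giving the
#' strongly inter-correlated mixed-sign structure typical of
#' socio-demographic tables.  The matrix is positive definite by
#' construction.
#'
#' @param loadings Optional numeric vector of factor loadings in
#'   `(-1, 1)`, one per covariate.
#' @return A correlation matrix.
#' @export
census_correlation <- function(loadings = NULL) {
  if (is.null(loadings))
    loadings <- c(income = 0.80, pct_zero_income = -0.65,
                  pct_two_plus_bathrooms = 0.75, pct_literate = 0.60,
                  pct_age_under15 = -0.50, pct_age_over65 = 0.40,
                  household_size = -0.45, pct_piped_water = 0.55,
                  pct_sewage = 0.60, pct_garbage_collection = 0.50,
                  pct_white = 0.45, pct_paved_street = 0.40,
                  pct_owner_occupied = 0.20, income_per_capita = 0.80,
                  pct_crowded = -0.60)
  if (any(abs(loadings) >= 1)) stop("factor loadings must lie in (-1, 1)")
  R <- tcrossprod(loadings)
  diag(R) <- 1
  R
}

#' Generate a synthetic census-sector population
#'
#' Draws `n` sectors with `d` correlated mixed-scale covariates by a
#' Gaussian copula: latent standard normals with the given correlation are
#' mapped through the probability integral transform to the specified
#' marginals (lognormal for income-like columns, logit-normal in
#' `[0, 100]` for percentage columns).  Defaults emulate a 15-covariate
#' socio-demographic table; the first three columns are the prevalence
#' predictors used by [simulate_prevalence()] (average income, zero-income
#' percentage, percentage of households with two or more bathrooms).
#'
#' @param n Number of sectors (units).
#' @param d Number of covariates (default 15; must be >= 3 so the three
#'   prevalence predictors exist).
#' @param correlation `d x d` positive-definite correlation matrix;
#'   default [census_correlation()] (truncated/recycled to `d`).
#' @param marginals List of `d` marginal specs as in [census_marginals()].
#' @param unit_ids Optional unit identifiers (default `"sector_1" ...`).
#' @return A `"covariate_matrix"`.
#' @examples
#' pop <- generate_population(40, seed = NULL)  # uses the current RNG state
#' @export
generate_population <- function(n, d = 15, correlation = NULL,
                                marginals = NULL, unit_ids = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (d < 3) stop("need d >= 3 (the three prevalence predictors)")
  if (is.null(marginals)) {
    base <- census_marginals()
    if (d <= length(base)) marginals <- base[seq_len(d)]
    else {
      extra <- rep(base, length.out = d - length(base))
      names(extra) <- paste0("extra_", seq_along(extra))
      marginals <- c(base, extra)
    }
  }
  if (length(marginals) != d) stop("'marginals' must have d entries")
  if (is.null(correlation)) {
    ld <- rep(c(0.80, -0.65, 0.75, 0.60, -0.50, 0.40, -0.45, 0.55, 0.60,
                0.50, 0.45, 0.40, 0.20, 0.80, -0.60), length.out = d)
    correlation <- census_correlation(ld)
  }
  if (!isSymmetric(unname(correlation)) || nrow(correlation) != d)
    stop("'correlation' must be a symmetric d x d matrix")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) stop("'correlation' is not positive definite")
  U <- chol(correlation)
  Zl <- matrix(rnorm(n * d), n, d) %*% U
  u <- pnorm(Zl)
  X <- matrix(0, n, d)
  for (j in seq_len(d)) {
    spec <- marginals[[j]]
    X[, j] <- switch(spec$type,
      lognormal = qlnorm(u[, j], meanlog = spec$meanlog, sdlog = spec$sdlog),
      percentage = 100 * plogis(qnorm(u[, j]) * spec$sigma + spec$mu),
      stop("unknown marginal type: ", spec$type))
  }
  colnames(X) <- names(marginals)
  if (is.null(unit_ids)) unit_ids <- paste0("sector_", seq_len(n))
  covariate_matrix(X, unit_ids = unit_ids)
}

#' Logit-linear sector prevalence model
#'
#' Specification of the auxiliary response model: the log-odds of the
#' infection prevalence in sector `i` is linear in three sector covariates
#' (average income, zero-income population percentage, percentage of
#' households with two or more bathrooms) plus Gaussian noise:
#' `logit(p_i) = b0 + b1 x_i1 + b2 x_i2 + b3 x_i3 + e_i`.
#'
#' Default coefficients are chosen so that, on the default synthetic
#' population of [generate_population()], simulated prevalences fall in a
#' plausible 2--25% range: wealthier sectors (higher income, more
#' bathrooms) have lower prevalence, sectors with more zero-income
#' population higher prevalence.
#'
#' @param beta Length-4 coefficient vector `(b0, b1, b2, b3)`.
#' @param columns The three predictor columns (names or indices into the
#'   covariate matrix).
#' @param noise_sd Standard deviation of the noise on the linear predictor
#'   (default 0.2).
#' @return An object of class `"prevalence_model"`.
#' @export
prevalence_model <- function(beta = c(-1.95, -4e-4, 0.04, -0.015),
                             columns = c(1L, 2L, 3L), noise_sd = 0.2) {
  if (length(beta) != 4L) stop("'beta' must have 4 entries (b0..b3)")
  if (length(columns) != 3L) stop("'columns' must name 3 predictor columns")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  structure(list(beta = as.numeric(beta), columns = columns,
                 noise_sd = noise_sd),
            class = "prevalence_model")
}

#' Simulate sector prevalences
#'
#' Evaluates the logit-linear model of [prevalence_model()] on a covariate
#' matrix: `eta = b0 + b1 x1 + b2 x2 + b3 x3 + e`, `e ~ N(0, noise_sd^2)`
#' iid, and `p = exp(eta) / (1 + exp(eta))`.  With `noise_sd = 0` the
#' result is a deterministic function of the covariates.
#'
#' @param x Covariate matrix containing the model's predictor columns.
#' @param model A `"prevalence_model"` (default [prevalence_model()]).
#' @return Length-`n` vector of prevalences, strictly inside `(0, 1)`.
#' @export
simulate_prevalence <- function(x, model = prevalence_model()) {
  x <- as_covariate_matrix(x)
  stopifnot(inherits(model, "prevalence_model"))
  P <- x$values[, model$columns, drop = FALSE]
  if (ncol(P) != 3L) stop("predictor columns not found in 'x'")
  eta <- model$beta[1L] + drop(P %*% model$beta[2:4])
  if (model$noise_sd > 0) eta <- eta + rnorm(x$n, sd = model$noise_sd)
  plogis(eta)
}

#' Municipality-level prevalence and its sample estimator
#'
#' `municipality_prevalence()` is the estimand: the unweighted mean
#' prevalence over all sectors (sectors are exchangeable units of roughly
#' equal household counts).  `sample_estimator()` is the corresponding
#' estimate from an allocation: the mean prevalence over the sampled
#' sectors (group 1).  A population-weighted variant is available through
#' `weights`.
#'
#' @param p Length-`n` vector of sector prevalences.
#' @param weights Optional nonnegative sector weights (e.g. populations);
#'   default unweighted.
#' @return Scalar.
#' @export
municipality_prevalence <- function(p, weights = NULL) {
  if (is.null(weights)) mean(p) else sum(p * weights) / sum(weights)
}

#' @rdname municipality_prevalence
#' @param alloc An [allocation()] over the same units as `p` (group 1 is
#'   the sampled set).
#' @export
sample_estimator <- function(alloc, p, weights = NULL) {
  stopifnot(inherits(alloc, "allocation"))
  if (length(p) != length(alloc$assignment))
    stop("'p' must have one entry per unit")
  sel <- alloc$assignment == 1L
  if (!any(sel)) stop("empty sample: no unit allocated to group 1")
  if (is.null(weights)) mean(p[sel])
  else sum(p[sel] * weights[sel]) / sum(weights[sel])
}

#' Published vaccine efficacy rates
#'
#' Manufacturer-published efficacy rates (proportions) for the four
#' COVID-19 vaccines of the multi-group case study: Coronavac/Sinovac
#' (control) 50.4%, AstraZeneca/Oxford 70.4%, Moderna 94.5%,
#' Pfizer/BioNTech 95%.
#'
#' @format Named numeric vector of proportions in `[0, 1]`.
#' @export
covid_vaccine_efficacies <- c(coronavac = 0.504, astrazeneca = 0.704,
                              moderna = 0.945, pfizer = 0.95)

#' Vaccine trial scenario
#'
#' Bundles vaccine efficacy rates with the group sizes of a multi-group
#' allocation (group `q` receives vaccine `q`).
#'
#' @param efficacies Named vector of efficacy rates `ER_v` in `[0, 1]`.
#' @param group_sizes Integer group sizes, one per vaccine.
#' @return An object of class `"vaccine_scenario"`.
#' @export
vaccine_scenario <- function(efficacies = covid_vaccine_efficacies,
                             group_sizes = c(12L, 11L, 11L, 11L)) {
  if (any(efficacies < 0 | efficacies > 1))
    stop("efficacy rates must lie in [0, 1]")
  if (length(group_sizes) != length(efficacies))
    stop("need one group size per vaccine")
  structure(list(efficacies = efficacies,
                 group_sizes = as.integer(group_sizes)),
            class = "vaccine_scenario")
}

#' Post-vaccination infection rates
#'
#' The expected infection rate of sector `i` under vaccine `v` is the
#' pre-vaccination prevalence scaled by the vaccine's failure rate:
#' `IR[v, i] = p_i * (1 - ER_v)`.
#'
#' @param p Length-`n` vector of sector prevalences.
#' @param scenario A `"vaccine_scenario"`, or a named vector of efficacy
#'   rates.
#' @return `v x n` matrix of infection rates (rows named by vaccine).
#' @export
vaccine_infection_rates <- function(p, scenario = vaccine_scenario()) {
  er <- if (inherits(scenario, "vaccine_scenario")) scenario$efficacies
        else scenario
  if (any(er < 0 | er > 1)) stop("efficacy rates must lie in [0, 1]")
  IR <- outer(1 - er, p)
  rownames(IR) <- names(er)
  IR
}
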