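# haphazard

Covariate-balanced allocation of sampling units by **haphazard intentional
sampling**, with rerandomization and pure-randomization comparators and the
simulation machinery to compare them.

## The problem

Epidemiological surveys and trials routinely select a small set of units —
census sectors, clinics — that must represent a larger pool with respect to
socio-demographic covariates, or assemble treatment groups that are mutually
comparable on those covariates.  Pure randomization decouples the selection
from unobserved confounders but leaves large chance imbalances at realistic
sample sizes; fully optimized ("intentional") selection balances perfectly
but ties the selection deterministically to the data, inviting systematic
bias.  This package is for statisticians and field epidemiologists who want
both: near-optimal balance with a controlled, quantifiable amount of
randomness.

## The method

Balance between groups is the Mahalanobis distance between group covariate
means: with `A* = A L` the whitened covariates (`L` the lower-triangular
Cholesky factor of the inverse sample covariance),

    M(w, A) = (1/m) ||mean1(A*) - mean0(A*)||_2 .

Minimizing `M` is a mixed-integer quadratic program, so the allocation
instead minimizes the linearizable hybrid surrogate

    H(w, A) = (1/m) ||.||_1 + m ||.||_inf   (H >= M always),

mixed with the same loss on a freshly drawn Gaussian noise block `Z`:

    minimize (1 - lambda) H(w, X) + lambda H(w, Z)
    subject to sum(w) = n1,  w binary,

a MILP solved by the package's exact branch-and-bound (small instances)
or basin-hopping local search under a time limit (large ones).  The noise
weight is parameterized through the dimension-equilibrated `lambda*`
(`lambda = lambda*` at the default `k = d`), with size-keyed defaults.
Multi-group designs minimize the centroid form of `H` over a `g x n`
assignment matrix.  Decoupling is quantified by Fleiss' kappa across
repeated draws; balance by standardized mean differences against a
pure-randomization reference scale; estimator quality by RMSE and SD of
the prevalence estimator over repeated allocations.

## Worked example

A synthetic 100-sector municipality, 25 sectors to be sampled:

```r
library(haphazard)
pop <- generate_population(100, seed = 42)   # 15 census-like covariates
set.seed(43)
p <- simulate_prevalence(pop)                # logit-linear sector prevalence

fit <- haphazard(pop, n1 = 25, seed = 44)
fit
#> Haphazard intentional allocation
#>   units: 100  covariates: 15
#>   design: two groups, n1 = 25 , n0 = 75
#>   lambda* = 0.01 (lambda = 0.01, k = 15), time_limit_incumbent
#>   objective: 0.793057
#>   mahalanobis: 0.00709986
#>   hybrid: 0.718681
```

The Mahalanobis balance of the selected sample (0.0071) is an order of
magnitude below what pure randomization typically yields on this
population (median 0.062, below).  Repeated draws quantify decoupling and
estimator error:

```r
ens <- simulate(fit, nsim = 100, seed = 45)
fleiss_kappa(ens)
#> [1] 0.0062      # chance-level agreement: draws are well decoupled

cmp <- run_comparison(pop, p, n1 = 25, r = 100, seed = 46)
cmp
#> Allocation method comparison: 100 repetitions, group sizes ( 25, 75 )
#> True prevalence theta = 0.0967
#>
#>                    kappa median_balance    rmse      sd
#> haphazard        0.00709        0.00697 0.00474 0.00432
#> rerandomization  0.00119        0.03407 0.00755 0.00742
#> pure_random     -0.00121        0.06155 0.01372 0.01373
```

Reading the table: sampling 25 of 100 sectors, the haphazard estimator's
RMSE for municipality prevalence (0.47 percentage points) beats
rerandomization (0.76) and pure randomization (1.37) at identical sample
size, while its kappa stays at chance level — the extra precision costs no
measurable coupling.  `tradeoff_curve()` exposes the balance/decoupling
trade-off as `lambda*` varies, and `rmse_vs_sample_size()` the sample size
(hence field cost) each method needs for a target precision.

Command-line wrappers for allocation and synthetic-data generation are
installed under `inst/cli/` (`allocate.R`, `synth.R`).

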