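---
title: "Haphazard intentional sampling: model, solver and simulation design"
author: "haphazard package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haphazard intentional sampling: model, solver and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haphazard)
```

## The problem

Survey designs and trials often need a *small* set of units — census
sectors, clinics, municipalities — that represents a larger candidate pool
with respect to a set of covariates, or several treatment groups that are
mutually comparable on those covariates.  Pure randomization guarantees
decoupling from unobserved confounders but wastes balance: with 25 sectors
drawn from a few hundred, sample and population covariate means can diverge
substantially.  Fully intentional (optimized) selection achieves excellent
balance but couples the selection deterministically to the data, opening the
door to systematic bias and manipulation.

Haphazard intentional sampling is the compromise implemented here: optimize
a covariate-balance loss *plus* a freshly drawn random noise loss with a
small weight $\lambda$.  The result is, with high probability, a
near-optimally balanced allocation whose identity still varies randomly
from draw to draw.

## Balance losses

Let $X \in \mathbb{R}^{n \times d}$ hold $d$ covariates for $n$ candidate
units, and let $w \in \{0,1\}^n$ assign each unit to group 1 (sampled /
treated, $\mathbf{1}w^t = n_1$) or group 0.  All balance metrics act on the
whitened matrix $A^* = A L$, where $L$ is the lower-triangular Cholesky
factor of the inverse sample covariance, $\mathrm{Cov}(A)^{-1} = L L^t$
(`whiten()`); the covariance is the unbiased estimate over all $n$ units,
computed once before any allocation.  Writing $\bar A^*_1$ and
$\bar A^*_0$ for the whitened column means of the two groups, the
Mahalanobis balance is

$$M(w, A) = \tfrac{1}{m}\,\lVert \bar A^*_1 - \bar A^*_0 \rVert_2 ,$$

with $m$ the number of columns of $A$.  Minimizing $M$ directly is a
mixed-integer *quadratic* program.  The package instead minimizes the
hybrid surrogate

$$H(w, A) = \tfrac{1}{m}\,\lVert \bar A^*_1 - \bar A^*_0 \rVert_1
          + m\,\lVert \bar A^*_1 - \bar A^*_0 \rVert_\infty ,$$

which dominates $M$ (since $\lVert v\rVert_1 \ge \lVert v\rVert_2$) and,
because group sizes are fixed, is *linear* in $w$ after introducing one
absolute-value pair per whitened column and one max variable per block —
a MILP (`milp_two_group()`).  The exact quadratic criterion is retained
only as an enumeration oracle for verification
(`brute_force_optimum(objective = "mahalanobis")`).

For $g$ groups with sizes $n_1,\dots,n_g$ fixed by an assignment matrix
$W \in \{0,1\}^{g\times n}$ ($W\mathbf{1} = n$, $\mathbf{1}W = \mathbf{1}$),
the pairwise sum of squared Mahalanobis distances between group means is
equivalent, at equal group sizes, to $g$ times the sum of squared
deviations from the centroid of the group means; the package therefore
optimizes the centroid form of the hybrid loss,

$$H_{\mathrm{centroid}}(W, A) = \sum_{q=1}^g \tfrac{1}{m}
  \lVert \bar A^*_q - \bar A^* \rVert_1 + m \lVert \bar A^*_q -
  \bar A^* \rVert_\infty ,$$

with $\bar A^*$ the overall mean over all $n$ units (`milp_multi_group()`,
`centroid_hybrid_loss()`).  Note that the printed overall mean and the
unweighted centroid of group means coincide only at equal group sizes; the
implementation uses the overall mean, and the pairwise/centroid
equivalence is asserted in the tests only at equal sizes.  The two-group
hybrid loss is recovered exactly as the $g = 2$ case of the centroid form
(the deviations of the two group means from the overall mean are the
$n_0/n$ and $n_1/n$ shares of their difference), which is why a single
solver core serves both designs.

A caveat worth stating precisely: $M$ is invariant under *any* invertible
affine recoding $A \mapsto AB + \mathbf{1}c$ of the covariates, but $H$ is
not — the whitening frame is unique only up to rotation and the
$L_1$/$L_\infty$ norms are not rotation-invariant.  $H$ is invariant under
lower-triangular $B$ with positive diagonal (in particular, any rescaling
of covariate units), where Cholesky uniqueness pins the frame.  The test
suite asserts exactly these two invariance groups.

## The haphazard sampler

Each draw generates a noise matrix $Z \in \mathbb{R}^{n\times k}$ of iid
standard normals (`draw_noise()`), whitens it, and solves

$$\min_w\;(1-\lambda)\,H(w, X) + \lambda\,H(w, Z)
\quad\text{s.t.}\quad \mathbf{1}w^t = n_1 .$$

At $\lambda = 0$ the allocation is deterministic pure intentional
sampling; at $\lambda = 1$ it is uniform over feasible allocations
(exchangeability of the iid Gaussian rows).  Because the covariate and
noise blocks have different dimensions, the user-facing knob is the
equilibrated weight $\lambda^*$, mapped through

$$\lambda = \frac{\lambda^*}{\lambda^*(1 - k/d) + k/d},$$

which is the identity when $k = d$.  The package defaults to $k = d$ — the
neutral point of the equilibration — leaving $\lambda = \lambda^*$.  The
default $\lambda^*$ and solver time limit are keyed on instance size:
$(0.1, 5\,\mathrm{s})$ below 50 units, $(0.01, 30\,\mathrm{s})$ up to
4000, $(0.001, 120\,\mathrm{s})$ beyond — small pools have few
near-optimal allocations, so decoupling needs more noise, while large
pools need more solver time.  (The published calibration grid for
$\lambda^*$ starts at 0.005 while the large-instance default is 0.001;
both are exposed unchanged.)

`haphazard()` is the fitting function; `simulate()` on its result redraws
$Z$ afresh for every repetition — this per-repetition noise is what makes
the procedure a *sampler* with a decoupling distribution rather than a
one-off optimization.

## Comparators

*Rerandomization* (`calibrate_rerandomization()`,
`rerandomization_sample()`) repeatedly draws pure random allocations until
a balance criterion falls below a threshold.  The criterion is $M$ for two
groups and the centroid squared Mahalanobis for multi-group designs; the
threshold is the empirical $p_a$-quantile of the criterion over $10^4$
pure-random draws (default acceptance probability $p_a = 0.01$), the
quantile-based construction of the classical method.  Since $M$ and $M^2$
are monotone-equivalent, calibrating on $M$ accepts exactly the same set
as calibrating on $M^2$.  Accepted-draw counts are geometric with mean
$\approx 1/p_a$.

*Pure randomization* (`pure_random_sample()`) draws uniformly over labeled
partitions via a seeded shuffle sliced by group sizes.

## Decoupling and balance diagnostics

Across $r$ repeated allocations, with $r_{i,j}$ the number of times unit
$i$ entered group $j$, Fleiss' kappa (`fleiss_kappa()`) contrasts the
observed pairwise agreement

$$\bar P_o = \frac{1}{N r (r-1)} \sum_{i}\sum_{j} r_{i,j}(r_{i,j} - 1)$$

with the chance agreement $\bar P_e = \sum_j p_j^2$,
$p_j = \sum_i r_{i,j} / (N r)$, as
$\kappa = (\bar P_o - \bar P_e)/(1 - \bar P_e)$.  The chance term follows
the classical Fleiss definition (squared overall group proportions); a
plausible alternative reading of the typeset formula — squaring the
individual counts inside the double sum — does not reproduce the
hand-workable anchor cases (three units, two repetitions, $\kappa = -1/2$)
and was rejected.  $\kappa = 1$ means the sampler is deterministic; pure
randomization gives $\kappa \to 0$.

Per-covariate balance is summarized by standardized differences
$(\bar X_{\cdot,j}^1 - \bar X_{\cdot,j}^0)/s_j$ on the *raw* covariate
scale, where the reference scale $s_j$ is the standard deviation of the
group-mean difference over 300 pure random allocations
(`reference_scale()`); for multi-group designs the maximum over group
pairs is reported (`max_pairwise_std_diff()`), with $s_j$ computed from
the difference between the first two groups of the pure-random reference
draws.  Estimator quality uses
$\mathrm{RMSE} = \sqrt{\tfrac1r \sum_a (\hat\theta_a - \theta)^2}$
(divisor $r$) and the standard deviation with divisor $r - 1$, so
$\mathrm{RMSE}^2 = \tfrac{r-1}{r}\mathrm{SD}^2 + \mathrm{bias}^2$ exactly.

## The MILP solver

No external MILP engine is assumed: the package ships its own solver for
this specific problem family, behind a thin build/solve adapter so any
engine could be substituted.  Two components:

* **Exact branch and bound** for instances whose feasible-allocation count
  is within the node budget (default $2\times 10^6$; e.g. any two-group
  instance up to $n \approx 21$ balanced).  Units are assigned
  depth-first in a random order; at each node, a lower bound is computed
  per group and whitened column from the interval of column sums
  achievable by the group's remaining picks (sums of the $c_q$ smallest
  and largest remaining values, precomputed from sorted suffixes).  The
  random exploration order also makes tie-breaking symmetric: at
  $n_1 = n_0$ the objective satisfies $H(w) = H(\mathbf{1}-w)$, so optima
  come in mirror pairs, and a deterministic search order would
  systematically prefer one member — visible as non-uniformity of the
  $\lambda = 1$ sampler.  With the randomized order the returned member is
  uniform on the pair, and a $\chi^2$ test over all $\binom{6}{3} = 20$
  allocations at 4000 draws passes comfortably.

* **Multi-start basin-hopping local search** for larger instances:
  pairwise-swap descent to a local optimum, then repeated random
  kicks (1–4 cross-group swaps) with re-polishing, keeping the best
  labeling; several independent restarts.  Results are reported as
  `time_limit_incumbent`, never as proven optima.  The kick cycles matter
  scientifically, not just computationally: with plain restart descent the
  solver's run-to-run variability dominates the tiny noise term at small
  $\lambda^*$, flattening the decoupling curve; basin hopping makes the
  solver nearly deterministic at fixed $(X, Z, \lambda)$ so that the
  observed decoupling is attributable to $\lambda$, as intended.

Solved objectives always equal the loss recomputed from the returned
allocation (the linearization's auxiliaries are tight at the optimum), and
the branch-and-bound agrees with an independent plain-R enumeration oracle
on every small instance tested.  The full linearization — binaries,
absolute-value pairs, max variables, cardinality constraints — can be
exported in LP format for audit with any external tool (`write_lp()`).
The MIP gap is exposed (`mip_gap`, default $10^{-6}$) since no published
value exists.  At $\lambda = 0$ with non-unique optima the returned
allocation is solver-dependent; tests that need determinism engineer
unique optima (unequal group sizes).

Numerical details: whitening uses the unbiased covariance and
`chol2inv()`; a covariance with reciprocal condition number below
$10^{-12}$ is treated as singular and receives a ridge of
$10^{-8} \times$ the mean diagonal (reported in the result), or an error
naming the collinear columns in strict mode.  Rerandomization acceptance
uses a one-ulp relative tolerance so a threshold that coincides with an
attainable criterion atom (tiny instances) cannot be missed through
floating-point summation-order differences.

## Synthetic census-sector populations

`generate_population()` emulates the public socio-demographic tables that
drive such designs: 15 mixed-scale covariates per census sector (a sector
being roughly 200 households) — average income, percentage of zero-income
population, percentage of households with two or more bathrooms (a
standard indirect wealth measure), literacy, age structure, sanitation,
housing quality.  Draws use a Gaussian copula: latent normals correlated
by a one-factor "wealth" model (income, bathrooms and sanitation load
positively; zero income, crowding and under-15 share negatively), mapped
to lognormal marginals for income-like columns and logit-normal marginals
(hence bounded in $[0, 100]$) for percentage columns.

The response surface is a logit-linear prevalence model
(`simulate_prevalence()`):

$$\log\frac{p_i}{1-p_i} = \beta_0 + \beta_1 x_{i,1} + \beta_2 x_{i,2}
  + \beta_3 x_{i,3} + \epsilon_i,\qquad \epsilon_i \sim N(0,
  \sigma_\epsilon^2),$$

with $x_{i,1}$ average income, $x_{i,2}$ zero-income percentage and
$x_{i,3}$ two-plus-bathroom percentage, and noise entering on the linear
predictor as printed.  The regression coefficients behind the original
studies were never published, so the defaults
$\beta = (-1.95, -4\times10^{-4}, 0.04, -0.015)$,
$\sigma_\epsilon = 0.2$ were fixed once so that, on the default
population, simulated prevalences center near 10% with a central 95%
range of roughly 2–25% — an endemic-phase range a field epidemiologist
would call plausible — and so that the covariate signal (linear-predictor
SD $\approx 0.7$ from covariates) dominates the noise
($\sigma_\epsilon = 0.2$).  The estimand $\theta$ is the unweighted mean
sector prevalence (sectors have roughly equal household counts); a
population-weighted variant sits behind the `weights` argument.

For the multi-group trial, group $q$ receives vaccine $q$ and the
post-vaccination infection rate is $IR_{v,i} = p_i (1 - ER_v)$ with the
manufacturer-published efficacies (Coronavac 50.4%, AstraZeneca 70.4%,
Moderna 94.5%, Pfizer 95%); the reference design allocates 45 sectors
into groups of sizes (12, 11, 11, 11).

What the generator does *not* emulate: spatial contiguity of sectors,
household-level structure within sectors, serological test error,
under-reporting corrections, and the true (unreleased) census marginals
and regression coefficients.  Passing simulation checks therefore
establishes the *method orderings* (haphazard beats rerandomization beats
pure randomization; the balance/decoupling trade-off in $\lambda^*$), not
the published error magnitudes, which depended on the proprietary data.

## Simulation studies and problem sizes

`run_comparison()` runs the full repeated-allocation protocol (default
$r = 300$ repetitions, 25 sampled sectors) with per-task seeds derived
from a master seed by fixed offsets, so adding or removing a method never
perturbs another's draws.  `tradeoff_curve()` sweeps
$\lambda^* \in \{0.005, 0.01, 0.05, 0.1, 0.25, 0.5\}$ and reuses the same
noise matrices across grid points (common random numbers), so the
reported monotone trade-off is not clouded by Monte-Carlo noise;
`rmse_vs_sample_size()` tabulates error against sample size, the basis of
operating-cost comparisons.

The shipped tests and the acceptance script run deliberately scaled-down
versions of these studies — populations of 34–200 sectors, 100–150
repetitions per method, $10^4$ calibration draws — sizes the package
chooses so the full suite re-runs quickly on a single core while leaving
every qualitative conclusion intact; all of them are configuration
arguments, and the defaults reproduce the full protocol.

## Known limitations

* Large instances return time-limited incumbents, not proven optima; the
  quality of the incumbent (hence the balance half of the trade-off)
  depends on the local-search budget (`n_restarts`, `n_kicks`).
* The hybrid loss is a surrogate: its minimizer need not minimize $M$,
  and it is only invariant under triangular covariate recodings (see
  above).
* Fleiss' kappa treats repetitions symmetrically and says nothing about
  *which* confounder might couple to the allocation; it is a proxy for
  decoupling, not a guarantee.
* The synthetic populations are exchangeable by construction; with real
  census tables the covariance estimate can be near-singular (many
  collinear percentage columns), which is why the ridge and the strict
  mode exist.
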