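---
title: "Scoring spatial smoothing: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spatial smoothing: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bayesian disease-mapping models exist to smooth: small-area counts are
noisy, and a conditional autoregressive (CAR) prior borrows strength from
neighbouring areas so that the estimated relative risks are stable enough
to act on. But the amount of smoothing a fitted model actually delivers is
controlled largely by the hyperprior on the structured-effect variance, and
classical model-choice criteria — DIC, WAIC, CPO — measure fit, not
smoothing. A model that chases the raw ratios (under-smoothing) fits well
and scores well; a model that flattens genuine hot spots (over-smoothing)
can also look acceptable. Neither is the map you want. `gosmooth` fits the
two standard CAR models and scores competing hyperprior variants on a
family of *goodness-of-smoothing* statistics, alongside the usual
goodness-of-fit criteria, so that under- and over-smoothed variants can be
identified and excluded.

## Models

Counts are Poisson with offsets given by expected counts:
$y_i \sim \mathrm{Pois}(E_i e^{\mu_i})$. The Leroux model puts
$\mu_i = \beta^T x_i + s_i$ with the structured effect defined by its full
conditionals

$$ s_i \mid s_{-i} \sim N\!\left(
  \frac{\rho \sum_j w_{ij} s_j}{\rho \sum_j w_{ij} + 1 - \rho},\;
  \frac{\sigma_s^2}{\rho \sum_j w_{ij} + 1 - \rho}\right),
  \qquad \rho \sim \mathrm{Unif}(0, 1), $$

which mixes intrinsic-CAR dependence and independent noise through the
single parameter $\rho$. The BYM model uses
$\mu_i = \beta^T x_i + s_i + u_i$ with an intrinsic CAR (ICAR) prior on $s$
(conditional mean equal to the neighbour average, conditional variance
$\sigma_s^2 / \sum_j w_{ij}$) and iid $u_i \sim N(0, \sigma_u^2)$,
$\sigma_u^2 \sim N(0, 10)^+$. Weights $w_{ij}$ are binary first-order
adjacency throughout; coefficients have $N(0, 100)$ priors. The hyperprior
on $\sigma_s^2$ — inverse-gamma IG($\alpha$, $\eta$) or a left-truncated
normal $N(\pi, \nu)^+$ — is the smoothing dial: `hyperprior_grid()` ships
twelve settings per family, labelled A–L in approximately descending
smoothing intensity, spanning essentially-degenerate-at-zero to diffuse.
The grid is this package's own; any grid whose members genuinely differ in
prior concentration will exercise the statistics the same way.

### Sampler

`fit_car()` runs a Metropolis-within-Gibbs sampler written for exactness
and reproducibility rather than raw speed:

* each $s_i$ (and each $u_i$) gets a single-site random-walk Metropolis
  update. Sites are grouped by a greedy graph colouring; within a colour
  class no two areas are adjacent, so they are conditionally independent
  and a whole class can be proposed and accepted vectorised without
  changing the kernel;
* $\beta$ is a random-walk block update on the log-linear predictor;
* $\sigma_s^2$ is a conjugate Gibbs draw under IG (the CAR quadratic form
  supplies the rate), and a log-scale Metropolis step under LTN;
* $\rho$ moves on the logit scale; the determinant term
  $\tfrac12 \sum_k \log(\rho \lambda_k + 1 - \rho)$ uses eigenvalues of
  the graph Laplacian computed once per fit;
* the ICAR field is re-centred to sum to zero every iteration, with the
  compensating shift absorbed into the intercept, resolving the ICAR
  impropriety without changing $\mu$;
* step sizes adapt by Robbins–Monro during burn-in only (targets: 0.4 for
  single-site updates, 0.3 for blocks), so the post-burn-in chain is a
  fixed, valid Markov kernel. Seeded runs are bit-reproducible.

Defaults are 20&nbsp;000 iterations, 10&nbsp;000 burn-in, thinning 10. The
package's own tests and experiments use much shorter chains (typically
2&nbsp;000–5&nbsp;000 iterations on 56–100 areas); at these sizes the
within-chain effective sample sizes are in the tens-to-hundreds, which is
enough for the rank- and ratio-based smoothing statistics, though not for
publication-grade interval estimates.

## Derived surfaces

The raw standardised incidence ratio (SIR) is $y_i / E_i$; the model SIR is
$e^{\mu_i}$. Because a spatially structured covariate contributes
smoothness (or roughness) of its own, the SIR can *look* rougher when more
smoothing is applied. The surfaces the smoothing statistics compare are
therefore covariate-adjusted:

* CASIR$_i = \exp(\mu_i - \beta^T x_i)$, which equals $\exp(s_i)$ (the BYM
  unstructured effect is removed too) — the smoothed surface;
* CARSIR$_i = (y_i / E_i)\exp(-\beta^T x_i)$ — its raw counterpart, zero
  where $y_i = 0$.

CARSIR needs a value of $\beta$; the package adjusts each posterior draw by
its own $\beta^{(m)}$ and averages, with `point_beta = TRUE` switching to a
single posterior-mean adjustment. The two differ only through the
(small) posterior spread of $\beta$; the per-draw form is the default
because it keeps CARSIR a proper posterior functional. Residuals are
$\epsilon_i = E_i e^{\mu_i} - y_i$, with $u_i$ subtracted from $\mu_i$ first
in the BYM model (unstructured noise is not spatial signal). Ratio surfaces
are summarised by posterior means, residuals and structured effects by
posterior medians — the medians feed $\psi$ and Moran's I.

## The five smoothing statistics

**Variogram ratio.** The areal variogram at lag $h$ for area $i$ averages
squared differences over all areas within $h$ boundary crossings:
$\gamma_i(h) = \frac{1}{2N_i(h)} \sum_{j} (z_i - z_j)^2$ over
$0 < d_{ij} \le h$, where $d_{ij}$ is the graph geodesic ("minimum number
of boundaries crossed"). Two numerical choices deserve note. First, a
strict inequality $d_{ij} < h$ with integer distances would leave lag 1
empty; the implementation uses $d_{ij} \le h$, matching the verbal
definition "no more distant than the lag". Second, "averaged over areas
and lags" is ambiguous between averaging per-area ratios and the ratio of
averages; the package averages the *area-averaged* variograms first and
takes the mean over lags of $\gamma_{CASIR}(h) / \gamma_{CARSIR}(h)$,
which keeps each lag's ratio an interpretable quantity and makes the
statistic exactly $b^2$ for affine surfaces $CASIR = a + b \cdot CARSIR$
(a property the tests assert). The maximum lag defaults to the graph
diameter; lags where the raw variogram vanishes are dropped with a
warning. Ratio near 0 = over-smoothing, near 1 = under-smoothing.

**Kurtosis preservation.** The areal analogue of first differences is the
deviation of each area from its first-order neighbour mean,
$e_i = z_i - \bar z(w_i)$. Excess kurtosis
$\mathrm{E}[e^4]/\mathrm{E}[e^2]^2 - 3$ (moments averaged over areas) is
large when variation is dominated by rare extreme deviations; roughness is
the sample standard deviation of the $e_i$. A good smoother minimises
roughness while preserving the kurtosis of the unsmoothed surface. The
criterion compares the smoothed surface's roughness against the minimum
across the set of competing variants — it is the only statistic that is
relative to a comparison set. Following the observation that the
SIR-based version is more stable, the default surfaces are the posterior
SIR against the raw SIR; `kurtosis_surface = "casir"` switches to
CASIR/CARSIR.

**Kappa.** CASIR and CARSIR are each categorised by their own empirical
quantiles (3 categories with cuts 0.25/0.75, or 5 with cuts
0.1/0.3/0.7/0.9) and compared by Cohen's
$\kappa = (\Pr(A_o) - \Pr(A_e)) / (1 - \Pr(A_e))$ with CARSIR as the
baseline. Quantiles are type-7 (the R default) and category assignment
uses half-open intervals $[q_{k-1}, q_k)$; both conventions are stated
because category sizes under ties depend on them. Smaller $\kappa$ means
the smoothed ranks have moved further from the raw ranks, i.e. more
smoothing; $\kappa$ near 1 flags under-smoothing.

**Fraction of spatial variation.**
$\psi = \mathrm{Var}(s^*) / (\mathrm{Var}(s^*) + \mathrm{Var}(\epsilon^*))$
with per-area posterior medians and sample variances (divisor $N - 1$).
There are no accepted cut-offs for $\psi$, so it is reported but not used
in the consensus.

**Relative position of CASIR.** Shrinkage moves an area's CASIR from its
raw value (CARSIR, position 0) toward the posterior mean of its
neighbours' CASIR (position 1). The position is computed on the log scale
— the natural scale for ratio surfaces, and the one on which the exclusion
rule is defined: areas are excluded when the log-range between the two
endpoints is below 0.03 (noise dominates), when $y_i = 0$ (no log CARSIR),
or when the area has no neighbours. The upper endpoint is estimated as the
neighbour mean of the posterior-mean CASIR; because the neighbour mean is
linear, averaging per-draw neighbour means gives the identical estimate,
so no option is needed. Positions are capped at $[-0.2, 1.2]$ for
reporting; the PASS criterion counts uncapped values of non-excluded
areas. Median position near 1 = over-smoothing, near 0 = under-smoothing.

## Cut-off profiles and consensus

`cutoff_profile()` encodes three verdict profiles: *unbiased* `"u"`
(variogram ratio in 0.2–0.8, kappa in 0.05–0.95, ≥75% of positions in
0.01–0.99, roughness within +30% of the comparison minimum),
*conservative* `"c"` (0.25–0.75, 0.1–0.9, ≥85% in 0.02–0.98, +10%), and
*penalise-under-smoothing* `"pu"` (variogram ratio 0.1–0.4, kappa
0.05–0.7, ≥75% in 0.2–0.98; the kurtosis criterion has no natural
penalised form and is disabled). The roughness tolerance "+30%" is read
multiplicatively (minimum × 1.3). `consensus()` counts, per variant, how
many of the three `"pu"` criteria pass; two or more is consensus. All
bounds are user-overridable — they are calibrated conventions, not
estimated quantities.

## Goodness-of-fit criteria

DIC is $2 p_D - 2\log p(y \mid \bar\theta)$ with the plug-in taken on the
linear predictor (posterior mean of $\mu_i$) — DIC is only defined up to
this choice, which is therefore stated. WAIC uses
$p_W = \sum_i \mathrm{var}_m[\log p(y_i \mid \theta_i^{(m)})]$ with the
sample variance (divisor $M - 1$) and a max-shifted log-mean-exp. CPO is
estimated by the harmonic-mean identity; the estimator is known to be
unstable when a draw assigns the observation near-zero likelihood, so such
areas are excluded from $-\sum_i \log CPO_i$ with a warning rather than
silently dominating it, and scaled CPOs below 0.01 flag poorly fitted
areas. Moran's I is computed on the posterior-median residuals (matching
the $\psi$ convention) with the normal-approximation two-sided p-value;
its type-I error is verified at the nominal rate in the test suite.
`compare_models()` applies the within-2 / within-7 support bands to DIC
and WAIC.

## The synthetic generator

The generators exist so every statistic is testable against known truth
with no data download. `simulate_leroux_field()` draws from the exact
joint GMRF via the Cholesky factor of
$(\rho(D - W) + (1 - \rho)I)/\sigma_s^2$;
`simulate_icar_field()` uses the Laplacian eigendecomposition with the
null space removed and a sum-to-zero constraint; `simulate_counts()`
completes the Poisson layer. `smoothing_gradient_fixture()` is the study
bed used by the acceptance tests: 56 areas on a 7×8 rook lattice (the
scale of a small national county map), expected counts log-uniform on
[5, 50] to mimic small-area disease counts, one spatially autocorrelated
covariate (itself a Leroux field with $\rho = 0.9$, so the
smoothing-paradox contrast between SIR and CASIR is present), a structured
field with $\rho = 0.8$, $\sigma_s = 0.4$, and coefficients (0.1, 0.3).
Its three hyperprior settings — IG(100, 0.001), IG(3, 0.32), IG(2.1, 5) —
were chosen once to pin $\sigma_s^2$ near zero, to centre on the
generating variance, and to favour large variances respectively, inducing
over-, moderate and under-smoothing by construction.

What passing on this fixture does *not* show: lattices are more regular
than county maps (degrees 2–4, no islands, short diameter), expected
counts are independent of the covariate, and there is exactly one
covariate with a correctly specified linear effect. Statistics that
behave monotonically here can be noisier on irregular graphs with island
areas and confounded covariates; the exclusion rules (isolated areas,
zero counts, narrow ranges) are the package's handling of exactly those
features, and they are unit-tested, but their real-data prevalence is
dataset-specific.

## Degenerate inputs and tie-breaks

Constant surfaces: the variogram ratio treats a flat *smoothed* surface
as 0 (total over-smoothing) but refuses a flat raw surface; spatial
kurtosis is undefined on constant fields and errors; a degenerate surface
collapses to a single quantile category with a warning (and kappa then
reflects the lack of agreement structure). Isolated areas are retained in
graphs, excluded from neighbour-mean statistics with a warning, and
refused by the BYM ICAR update. Unreachable pairs get infinite boundary
distance and never enter a variogram lag. Draws with zero total spatial
variation make the BYM identifiability rescaling error rather than divide
by zero.

## Known limitations

The sampler is plain random-walk Metropolis within Gibbs: adequate at the
tested sizes (hundreds of areas), but no match for specialised CAR
software on large maps. The harmonic-mean CPO estimator has infinite
variance in unlucky configurations; the exclusion rule bounds the damage
but a Pareto-smoothed estimator would be better. The kurtosis-preservation
criterion is the least stable of the five statistics (its verdict depends
on a comparison-set minimum), and $\psi$ has no calibrated cut-offs; both
are reported, neither drives the consensus.
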