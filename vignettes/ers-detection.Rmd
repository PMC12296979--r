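---
title: "Detecting extreme response style with posterior predictive checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extreme response style with posterior predictive checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Extreme response style (ERS) is the tendency of a respondent to over- or
under-use the endpoint categories of a rating scale relative to the norm
population, independent of item content. ERS adds construct-irrelevant
variance to Likert-type measurements and can bias group comparisons, so
detecting it — for a whole sample and for individual respondents — matters
before any substantive modeling. Dedicated ERS questionnaires or mixture /
multidimensional IRT models exist, but each commits to a specific
operationalization of ERS. The approach implemented here avoids that
commitment: fit an ordinary unidimensional (or between-item
multidimensional) generalized partial credit model (GPCM) and ask, through
posterior predictive checks, whether the observed pattern of extreme
responding is compatible with data the fitted model itself would produce.

## Measurement model and estimation

For an item with `c` ordered categories (internally scored `0..c-1`), the
GPCM gives

$$P(X = x \mid \theta) \propto \exp\!\Big(\sum_{j \le x} \alpha\,(\theta - \tau_j)\Big),$$

with the empty sum for the lowest category, so the `c` probabilities
normalize to one by construction. Internally the package uses the
equivalent cumulative-intercept form $\exp(x\,\alpha\,\theta + d_x)$ with
$d_0 = 0$, which stays numerically stable for arbitrarily small slopes;
`thresholds_to_intercepts()` maps between the two. All probability
evaluations subtract the running maximum on the log scale
(log-sum-exp), keeping linear predictors of magnitude up to about 40 exact.

Estimation is Bayesian MCMC under diffuse priors: $\theta \sim N(0, 1)$
per dimension (multivariate with an estimated correlation matrix under a
uniform prior over positive-definite correlation matrices when `V > 1`),
$\alpha_i \sim N(1, \sqrt5)$ — not truncated, so negative slopes remain
possible — and free intercepts $d_{ij} \sim N(0, \sqrt5)$. The `N(1, 5)`
slope prior is read as variance 5; this is configurable in
`mcmc_config()` should a standard deviation of 5 be preferred.

The sampler is an adaptive random-walk Metropolis-within-blocks scheme
written in C++: persons given items, items given persons (scalar updates
plus a per-item joint move along a proposal covariance learned during
burn-in, because the cumulative intercepts are strongly correlated a
posteriori), and the trait correlation given the traits. Two additional
likelihood-invariant "ridge" moves per dimension traverse the soft
identification ridges that coordinate-wise walks cross slowly: a scale
move $(\alpha, \theta) \to (s\alpha, \theta/s)$ with its Jacobian, and a
location move $\theta \to \theta + m$ with the intercepts sheared to
compensate. All adaptation stops at the end of burn-in, so the retained
draws come from a fixed-kernel chain. Any correct sampler targeting this
posterior would do; the results depend on the posterior, not the sampler.

Scale and location are identified by the trait prior; slopes are
initialized at +1 and a residual reflection of a dimension (majority
negative slopes within a chain) is flipped post hoc and logged.
Convergence is assessed with rank-normalized split-$\widehat R$ and
bulk/tail effective sample size on every scalar parameter (defaults:
$\widehat R < 1.01$, ESS > 400). A failed check triggers a retry with
doubled sampling length and a new seed, at most twice, after which the fit
is returned flagged rather than discarded. `split_rhat()` returns the bulk
rank-normalized statistic, which is invariant under monotone transforms of
the draws; the tail side is covered by `ess_tail()`.

## The four checks

Let $NE^{(n)}_{obs}$ be person $n$'s observed extreme count (responses in
category 1 or `c`) over their observed items, and $ER^{(n)}_{obs}$ the
corresponding proportion. For each retained draw $t$ a full replicated
dataset is sampled from the GPCM at that draw, with missing cells kept
missing, giving $NE^{(t,n)}_{rep}$, and the expected extreme count
$E(NE^{(t,n)})$ is the sum over the person's observed items of the bottom-
plus-top category probabilities at draw $t$.

* **Person proportion check** (two-sided): the PPP value is the proportion
  of draws with $ER_{rep} > ER_{obs}$, counting ties as one half. Ties are
  decided on integer extreme counts — both proportions share the person's
  observed-item denominator — so no floating-point tolerance is involved.
  Values below .05 flag H-ERS (more observed extremes than the model
  reproduces), above .95 L-ERS.
* **Person discrepancy check** (one-sided): with
  $D^{(t,n)} = (NE - E(NE^{(t,n)}))^2$ for the observed and replicated
  counts, the PPP value is the proportion of draws with
  $D_{rep} \ge D_{obs}$; values below .1 flag a person, with direction read
  from the mean expected count versus the observed count (exact equality
  is reported as `indeterminate` rather than resolved arbitrarily).
* **Group discrepancy check**: same comparison on the per-draw person sums
  of $D$.
* **Group variance check**: individual ERS differences inflate the spread
  of per-person extreme proportions without necessarily moving their mean,
  so the variance (sample variance, denominator $N-1$; the indicator is
  unaffected by the choice since both sides scale identically) of observed
  proportions is compared with that of each replicate. One-sided, flag
  below .1.

All four families are accumulated in a single pass over the draws;
replicates are consumed one at a time and never stored (`run_ppc()`), with
a materialized mode kept solely as an internal cross-check that must agree
exactly. Cutoffs (.05/.95 two-sided, .1 one-sided) are defaults in
`ppc_cutoffs()`; stricter cutoffs would trade the already conservative
false-positive rate for power.

Persons with no observed responses have no defined extreme proportion and
are excluded with a warning. Expected counts sum over observed items only,
so they are commensurable with the observed counts under missingness —
the replication scheme reproduces the missingness pattern exactly for the
same reason.

## The synthetic-data generator

Simulated questionnaires come from an IRTree process model: a
four-category response is three binary pseudo-decisions, each a logistic
model. Node 1 chooses agree (categories 3/4) versus disagree (1/2) and
carries no ERS influence; node 2 splits the disagree side (mild versus
extreme), node 3 the agree side. The ERS trait enters nodes 2 and 3 with
equal magnitude and opposite signs (−1.4 and +1.4), so positive ERS
inflates both endpoint categories and never moves the agree/disagree
split; the substantive slope is shared by nodes 2 and 3 (1.1) and steepest
in node 1 (1.9). Node difficulties are (0, −1, 1) with intercepts
$d_m = -\alpha_m b_m$ on the item's substantive dimension only. These
defaults give balanced items: marginal category profile
(0.2, 0.3, 0.3, 0.2) over a standard-normal trait and an exactly 50%
agree probability (at fixed $\theta = 0$ the same item gives
(0.125, 0.375, 0.375, 0.125); the rounded profile is the trait-marginal).
With the ERS trait at zero the tree item is practically a GPCM item:
`ccc_max_difference()` finds the best-fitting GPCM item and reports a
maximum per-category curve gap of about 0.022 for the defaults (tolerance
0.05), so misfit picked up by the checks on simulated data is attributable
to ERS, not to the generator's family.

Study conditions (`condition_spec()`) follow a fixed design: N = 250;
K ∈ {12, 24, 48}; V ∈ {1, 4} with uncorrelated traits and items split
over dimensions in contiguous blocks (V = 4 with 12 items is excluded as
unrealistic); per-item difficulty staggers equally spaced in
[−0.5, 0.5] added to all three node difficulties, in ascending item
order (any fixed assignment order works; this one is documented); and an
optional difficulty shift of −1 applied to every node. Null data set the
ERS value of every person to zero; experimental data draw ERS from the
discrete grid −3(0.5)3 with probabilities proportional to the
standard-normal density, which makes person-level true/false-positive
rates well defined at each ERS magnitude. Whether the shift is added
before or after the stagger is immaterial (addition commutes).

Marginal category probabilities are integrated by quadrature on a fixed
grid of 4001 equally spaced points over ±10 prior standard deviations
with normalized normal weights; the error against a 10-fold finer grid is
far below 1e−6, and no additional dependency is needed.

What the generator does *not* emulate: content-related local dependence,
correlated substantive traits, acquiescence or midpoint styles,
person-specific slopes, and real missingness mechanisms. Passing the
simulation-based tests therefore shows the checks behave as designed under
this ERS process, not that they are robust to everything real data can do.

## The study harness and problem sizes

`run_condition()` chains generator → GPCM fit → checks per replication and
aggregates group flag rates (false-positive rate under the null,
true-positive rate under ERS), pooled person false-positive rates (persons
with true ERS zero), and per-ERS-value true-positive rates
(`tpr_by_ers()`, including a positive/negative asymmetry table — negative
ERS is easier to detect with one substantive dimension because extreme
positive patterns can masquerade as extreme traits). Replication seeds
derive from the master seed by a counter (`seed + 1000003 · r`), so any
subset of replications can be reproduced independently and results are
byte-identical across runs. Non-converged replications are retained and
marked; `study_rates(converged_only = TRUE)` re-aggregates without them.

Two problem scales are built in. Desk scale — the package's default for
tests and exploration — uses 10 replications per condition and chains of
1,000 iterations (400 burn-in + 600 retained) per chain with relaxed
thresholds ($\widehat R < 1.1$, ESS > 50); a full condition runs in a few
minutes on one core. Full scale (`full_scale = TRUE`) uses the condition's
200 replications and production chains (1,000 burn-in + 2,000 retained,
$\widehat R < 1.01$, ESS > 400); a full grid takes hours of CPU and is the
setting under which the fine-grained rate values (for example the group
variance-check false-positive rate of .11 in the four-dimensional shifted
condition, or reliable detection of ERS ≤ −2.5 with 12 items) are
reproducible. Desk-scale runs reproduce the qualitative pattern: group
true-positive rates of 1, person false-positive rates at or below .05.

## Numerical and design choices

* Externally categories are coded `1..c`; internally `0..c-1`. One
  constructor (`response_matrix()`) owns the conversion and validation.
* Probability normalization is exact by construction (softmax over all
  `c` categories including the zero baseline).
* Tie handling: proportion-check ties count one half (a deliberate
  conservative correction for a discrete statistic); discrepancy-check
  ties count fully, consistent with its one-sided use.
* The correlation matrix is sampled per off-diagonal element with a
  positive-definiteness rejection; with unit trait variances fixed by the
  prior, the uniform prior over correlation matrices is the natural
  reading of an uninformative prior on the trait covariance.
* Degenerate inputs: all-missing persons are excluded with a warning from
  checks; an all-missing item simply contributes nothing; zero-variance
  chains make $\widehat R$/ESS undefined and return `NA` with a warning;
  slope exactly zero has no threshold representation and is rejected by
  the inverse parameter map.
* `ess_bulk()` caps the autocorrelation time from below at
  $1/\log_{10}(S)$, so antithetic chains may legitimately report more
  effective draws than nominal.

## Worked hand examples

The four PPP computations on paper-sized fixtures:

```{r}
library(erspc)
person_ppp_er(0.5, c(0.25, 0.5, 0.5, 0.75))   # (1 + .5 + .5 + 0)/4 = 0.5
person_ppp_d(4, c(3, 4, 5, 6), rep(2, 4))      # D_obs 4 vs (1,4,9,16): 0.75
group_ppp_er(c(0.4, 0.6), c(0.01, 0.02, 0.03)) # var_obs .02: 2/3
```

## Limitations

The checks detect misfit *related to extreme responding*; a flagged group
or person is evidence against the GPCM reproducing the extremes, not a
measurement of an ERS trait. Power at the person level is modest for
short questionnaires (with 12 items only strong negative ERS is reliably
flagged) and asymmetric in the sign of ERS unless several substantive
dimensions are measured. The posterior predictive p values are
conservative rather than uniform under the null, a known property of
PPCs; calibration procedures exist but are out of scope here, as is the
fitting of the IRTree model itself (it is generator-only) and checks for
other response styles.
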