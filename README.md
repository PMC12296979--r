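# erspc — posterior predictive checks for extreme response style

`erspc` detects **extreme response style (ERS)** — the tendency of
questionnaire respondents to over- or under-use the endpoint categories of
a rating scale regardless of item content — in polytomous (Likert-type)
data, at both the group and the person level, without fitting a dedicated
response-style model.

The idea: fit an ordinary Bayesian **generalized partial credit model
(GPCM)**,

P(X = x | θ) ∝ exp( Σ_{j≤x} α (θ − τ_j) ),

by MCMC, replicate the dataset from each posterior draw, and compare
observed against replicated extreme responding through four tailored
posterior predictive p (PPP) values:

| check | statistic | sided | flag |
|---|---|---|---|
| person proportion | proportion of extreme responses (ties count ½) | two-sided | PPP < .05 → H-ERS, > .95 → L-ERS |
| person discrepancy | squared observed-minus-expected extreme count | one-sided | PPP < .1, direction from mean expected count |
| group discrepancy | person-summed squared discrepancies | one-sided | PPP < .1 |
| group variance | variance over persons of extreme proportions | one-sided | PPP < .1 |

The package provides the full pipeline: GPCM estimation in C++
(adaptive Metropolis-within-blocks, rank-normalized split-R̂ and bulk/tail
ESS diagnostics, automatic retries), single-pass streaming PPCs, an
IRTree-based synthetic-data generator with a discrete ERS trait, a
simulation harness measuring false/true-positive rates across study
conditions, a flag-vs-covariate χ² utility, and a small CLI
(`inst/cli/erspc`) with `simulate`, `fit`, `ppc`, `study` and `fixtures`
subcommands.

## Worked example

Simulate a 250-person, 24-item questionnaire affected by ERS, fit the
GPCM, and run all checks (short desk-scale chains):

```r
library(erspc)
spec <- condition_spec(K = 24, V = 1, shift = 0, N = 250)
sim  <- generate_dataset(spec, type = "experimental", seed = 42)
fit  <- fit_gpcm(sim$data, config = mcmc_config(n_burnin = 400, n_sampling = 600,
                                                rhat_max = 1.1, ess_min = 50, seed = 42))
ppc  <- run_ppc(sim$data, fit, seed = 43)
ppc
#> <ers_ppc> 1200 draws, 250 persons; group PPP_ER = 0.000, PPP_D = 0.000
#>   person flags: ER 102, D 97
```

Both group PPP values are 0 — far below the .1 cutoff — so the GPCM
cannot reproduce the observed pattern of extreme responding: ERS is
present at the group level (correct: the generator injected it). Person
flags come with directions:

```r
head(subset(ppc$person, flag_er != "none"), 4)
#>     person     er_obs ne_obs n_obs      ppp_er       ppp_d mean_expected_ne flag_er flag_d
#> P4      P4 0.83333333     20    24 0.004583333 0.014166667        12.600623   H-ERS  H-ERS
#> P6      P6 0.04166667      1    24 0.999583333 0.003333333         7.834846   L-ERS  L-ERS
#> P7      P7 0.25000000      6    24 0.969583333 0.072500000        11.147913   L-ERS  L-ERS
#> P20    P20 0.25000000      6    24 0.972083333 0.075000000        10.792995   L-ERS  L-ERS
```

Person P4 gave 20 extreme answers where the fitted model expects about
12.6 — flagged H-ERS; P6 gave 1 where ≈7.8 were expected — L-ERS.
Cross-tabulating flags against the generator's true ERS values shows
detection rising with |ERS| (all 7 persons at ERS ≤ −2 flagged, 2 of 40
at ERS = 0).

The methods vignette (`vignettes/ers-detection.Rmd`) documents the model,
the four checks, the IRTree generator, and the numerical choices;
`run_condition()` / `paper_conditions()` run whole simulation conditions
at desk scale (10 replications, minutes) or full scale
(`full_scale = TRUE`: 200 replications and production chains, hours).

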