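---
title: "Season-specific state-space modelling and temporal transferability of lemming outbreak abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Season-specific state-space modelling and temporal transferability of lemming outbreak abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Norwegian lemming (*Lemmus lemmus*) populations in Fennoscandian tundra go
through 4–5-year cycles, and the abundance reached during the outbreak
(peak) phase varies strongly in space. A compact explanation combines three
predictors: intra-specific density dependence (a site's own lemming density
in the previous trapping season), inter-specific density dependence (the
density of the co-occurring grey-sided vole, *Myodes rufocanus*, mediated by
shared predators), and site elevation as a proxy for spatial climate
variation (roughly 0.6 °C per 100 m).

`lemcast` implements this model as a reusable pipeline and — its second
purpose — tests the model's *temporal transferability*: whether the dynamics
fitted to one cyclic peak predict the site-specific abundances of the next
peak. Over-summer (autumn) dynamics are expected to transfer well; the
over-winter (spring) dynamics are where elevation may stop being a faithful
climate proxy from one winter to another, so the package ships a synthetic
regime-shift scenario emulating exactly that failure mode.

## The state-space model

Trapping counts are noisy; the model therefore separates observation from
process. For site $i$, trapping season $k \in \{1,2,3\}$ (pre-peak autumn,
peak spring, peak autumn) and peak $t$:

$$y_{i,k,t} \sim \mathrm{Poisson}(\lambda y_{i,k,t})$$

$$\log(\lambda y_{i,k,t}) \sim \mathrm{Norm}\big(\beta_{0_{k,t}}
 + \beta_{dvole_{k,t}}\,\log(\lambda x_{i,k-1,t})
 + \beta_{elev_{k,t}}\,elev_{i}
 + \beta_{dlem_{k,t}}\,\log(\lambda y_{i,k-1,t}),\ \sigma_t\big)$$

for the dynamic seasons $k \in \{2,3\}$, where $y$ are lemming and $x$
grey-sided vole counts and $elev_i$ is the standardised site elevation. This
is a Gompertz-type log-linear formulation: $\beta_{dlem} = 1$ is a random
walk (no density regulation), $\beta_{dlem} = 0$ is no carry-over at all,
which is why summaries report $\beta_{dlem} - 1$ (values near $-1$ mean the
previous season's density leaves no trace). Because no delayed effects can
enter the first season, the initial-season lemming and the vole in *all*
seasons get site-intercept models: their latent log abundances are drawn
around season-level means with their own SDs, with no density dependence.
The elevation coefficient is indexed by season and peak, consistent with how
the coefficients are reported and used in the prediction equation.

Elevation is standardised per fitted peak: centred at the site-network mean
and divided by the sample SD (n − 1 convention). The SD in metres is
reported (`elev_scale_m`) so a user can state what one scaled unit means on
their network — 86 m in the reference study design.

### Priors and sampling

Priors are weakly informative on the log scale and configurable
(`default_priors()`): Normal(0, sd 10) for all coefficients and season-level
means, Uniform(0, 10) for all SDs. Posteriors are drawn with JAGS (via
`rjags`), the standard engine for this model family. Desk-scale defaults are
2 chains × 4000 iterations with 1000 burn-in — sized for simulation studies
where each replicate needs a full fit; production-scale settings
(e.g. 4 × 50000 / 15000) are one `mcmc_settings()` call away. Latent log
abundances are initialised at $\log(\mathrm{count} + 0.5)$ — finite at zero
counts and close to the data. Every chain's RNG is seeded deterministically
from the settings seed, so fits are bit-reproducible.

Convergence is diagnosed with the classic Gelman–Rubin statistic
(`compute_rhat()`; $\hat R < 1.1$ taken as converged) on the structural
parameters, and a failing run is *flagged*, not aborted — mirroring
diagnose-then-decide practice. At desk scale some runs will carry the flag;
the pipeline reports it in every output.

Two structural options reflect genuinely open choices: $\sigma_t$ is shared
across the two dynamic seasons within a peak by default (the model statement
writes a single $\sigma_t$), with `sigma_per_season = TRUE` as the
alternative; and `autumn_lemming_only = TRUE` drops the vole and elevation
terms from the autumn process, a reduced variant useful for checking that
the initial-season treatment does not drive conclusions.

### The density oracle

`log_joint()` assembles the model's full log density (Poisson observation
terms, normal process terms, season-level initial/vole terms, optionally the
priors) in closed form. JAGS does not expose its internal target density, so
equivalence is established the other way round: the JAGS model string is
generated from the same declarations `log_joint()` sums, and the test suite
compares `log_joint()` against a structurally independent vectorised
re-assembly at random parameter/latent points to $10^{-6}$. The same
function provides the $\sigma \to 0$ closed-form recursion checks for the
simulator.

## The synthetic-data generator

The generator *is* the study conditions, not a tuning knob. Defaults
(`default_peak_parameters()`, 98 sites uniform on 30–346 m elevation):

* Dynamic coefficients: the published first-peak estimates — spring
  $\beta_{dvole} = 0.267$, $\beta_{elev} = 0.845$, $\beta_{dlem} = 0.001$;
  autumn $0.100$, $0.528$, $0.091$.
* Season-level log-normal parameters for the initial-season lemming and the
  vole: back-solved from the published abundance means and SDs by matching
  log-normal moments (e.g. initial lemming: mean 0.31, CV 2.07 ⟹
  $\mu = -2.0$, $s = 1.29$). The intercepts $\beta_0$ are then set so the
  marginal spring and autumn lemming abundances land near the published
  0.47 and 2.16 individuals per site ($\beta_0 = -1.38, 0.76$).
* $\sigma = 0.3$: the process SD is not printed in the reference tables;
  0.3 is a realistic log-scale process SD for seasonal rodent dynamics.
* Elevation uniform over the range (the design reports range and a mean of
  about 200 m; the uniform draw matches the range and near-matches the mean).
* Voles carry no density dependence, matching their site-intercept treatment
  in the model; per-site heterogeneity enters through `vole_sd`.
* Counts are unbounded Poisson — no trap-saturation cap, matching the
  observation model rather than the 12-trap field bound.

`make_transfer_scenario()` simulates two peaks over one site table; the
peak-2 spring coefficients are shifted by `spring_shift`.
`reference_spring_shift()` returns the published between-peak deltas, the
default being the flip of the spring elevation effect from 0.845 to −0.134 —
the documented over-winter regime change. True parameters and latents
travel in metadata, separate from the counts, so recovery tests can read
them but fits cannot.

What the generator does *not* emulate: multi-annual cycle phases beyond two
three-season peaks, trap-level (sub-site) structure, spatial
autocorrelation (the reference analysis found none was needed), or
non-Poisson overdispersion in the observation process. Passing tests
therefore certify the method under the model's own assumptions, not the
full messiness of field data.

## Transferability validation

The prediction equation applies the training peak's posterior-mean
coefficients to the validation peak's predictors:

$$\log(p\lambda y_{i,k}) = \beta_{0_{k,t=1}}
 + \beta_{dvole_{k,t=1}}\,\log(\lambda x_{i,k-1,t=2})
 + \beta_{elev_{k,t=1}}\,elev_{i,t=2}
 + \beta_{dlem_{k,t=1}}\,\log(\lambda y_{i,k-1,t=2})$$

a deterministic plug-in (posterior means of coefficients and of the
predictor latents; no process noise). Full posterior propagation would be a
natural extension but is deliberately not the default, matching how the
prediction equation is defined. Predictions are validated against the
validation peak's *estimated* (posterior-mean) abundances, not raw counts,
because raw counts re-introduce the sampling noise the state-space model
exists to remove.

The score is the mean-centered MAE on the natural abundance scale,

$$MAE = n^{-1} \sum_i \left| (P_i - \bar P) - (O_i - \bar O) \right|,$$

whose centering removes season-level abundance offsets so that the
statistic scores the spatial pattern; it is symmetric, invariant to adding
constants and linear in common scaling. The MAE must be judged relative to
the mean season-specific abundance, which the report carries, together with
a log-scale bias diagnostic (positive = over-prediction) and the log-log
predicted/estimated pairs for the identity-line scatter. With a single site
the centered MAE is identically zero; the report flags that degenerate case.

One consequence of scoring on the natural scale is worth stating plainly:
absolute errors scale with abundance. Autumn abundances run 3–4× spring
abundances in this system, so under a *shared* regime the autumn MAE sits
well above the spring MAE, and the spring/autumn MAE ratio is informative
relative to that baseline, not relative to 1.

## Numerical and design choices

* Credible intervals: 2.5%/97.5% quantiles with linear interpolation
  between order statistics (R's default quantile rule), oracle-tested
  against a hand-rolled sort-and-interpolate.
* R-hat: classic non-split Gelman–Rubin,
  $\hat R = \sqrt{((n-1)W/n + B/n)/W}$; with zero between-chain variance it
  equals $\sqrt{(n-1)/n}$, slightly below 1.
* Elevation scaling refuses a zero-SD gradient (degenerate design) rather
  than returning NaNs; site generation refuses `n_sites < 2` for the same
  reason.
* All randomness funnels through integer seeds; the pipeline derives
  per-stage substream seeds from one master seed by a seeded
  `sample.int(2^31 - 2)` draw, recorded in `run.log`.
* Datasets round-trip through plain CSV plus a JSON metadata sidecar;
  readers validate counts, season/species domains, key uniqueness and grid
  completeness and point at the offending row or gap.

## Problem sizes used in the checks

The simulation studies in the test suite use what a desk machine fits
comfortably: parameter recovery over 20 replicates of 150-site peaks, run
with longer thinned chains (2 × 9000, burn-in 1500, thin 2) because
credible-*interval* placement needs a better-computed posterior than point
estimates do; the transferability contrast over 20 shift and 20
null replicates of 98-site two-peak scenarios (the reference network's
site count); moment checks at 2000 sites where only the generator runs. The
acceptance script runs one full 98-site two-peak pipeline plus the
closed-form worked examples.

## Known limitations

* Poisson observation only; overdispersed trapping (e.g. trap saturation,
  behavioural responses) is not modelled.
* The plug-in prediction understates predictive uncertainty; MAE compares
  point predictions with point estimates.
* Desk-scale MCMC settings can leave $\hat R$ above 1.1 for weakly
  identified parameters (notably SD components with one observation per
  site-season); runs carry the convergence flag and production settings
  resolve it at the cost of runtime.
* Exact prior families of the original analysis are not public; the
  documented weakly-informative defaults are a choice, kept configurable.
* The spring intra-specific coefficient is regressed on the initial-season
  latent log abundance, which at ~0.3 individuals per site is weakly
  identified from single counts; its shrunken posterior attenuates the
  coefficient slightly, so frequentist coverage of its credible interval at
  a fixed truth runs a few points below nominal even with long chains.
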