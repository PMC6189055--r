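# lemcast

Season-specific Bayesian state-space modelling of Norwegian lemming
outbreak abundance, and validation of its temporal transferability.

## What it is for

Lemming populations in Fennoscandian tundra cycle every 4–5 years, and the
abundance reached in the outbreak (peak) phase varies strongly between
sites. A compact model explains that spatial variability with three
predictors: the site's own lemming density in the previous trapping season
(intra-specific density dependence), the density of the co-occurring
grey-sided vole (inter-specific density dependence via shared predators),
and elevation as a proxy for spatial climate variation. `lemcast` is for
ecologists who want to

1. fit that model to site × season trapping counts from one cyclic peak,
   with trapping noise handled by a state-space formulation, and
2. ask whether the fitted dynamics *transfer in time* — whether they
   predict the site-specific abundances of the next peak.

## The model

For site *i*, season *k* ∈ {1 pre-peak autumn, 2 peak spring, 3 peak
autumn} and peak *t*, lemming counts *y* and vole counts *x* are Poisson
observations of latent abundances λ:

    y[i,k,t] ~ Poisson(λy[i,k,t])
    log(λy[i,k,t]) ~ Norm(β0[k,t] + β_dvole[k,t]·log(λx[i,k−1,t])
                          + β_elev[k,t]·elev[i] + β_dlem[k,t]·log(λy[i,k−1,t]), σ[t])

with standardised elevation, and season-level (site-intercept) models for
the initial-season lemming and for the vole in all seasons. The
intra-specific coefficient is reported as β_dlem − 1 (≈ −1 means no
carry-over of the previous season's density). Posteriors come from JAGS;
convergence is diagnosed with Gelman–Rubin R̂ (< 1.1) and flagged, not
enforced.

Transferability is scored by applying peak-1 posterior-mean coefficients to
peak-2 predictors,

    log(pλy[i,k]) = β0[k,t=1] + β_dvole[k,t=1]·log(λx[i,k−1,t=2])
                    + β_elev[k,t=1]·elev[i,t=2] + β_dlem[k,t=1]·log(λy[i,k−1,t=2])

and comparing against peak-2 estimated (posterior-mean) abundances with the
mean-centered mean absolute error `MAE = n⁻¹ Σ |(Pᵢ − P̄) − (Oᵢ − Ō)|`,
plus a log-scale bias diagnostic and a predicted-vs-estimated scatter.

A seeded synthetic-data generator reproduces the generative structure the
model assumes (98 sites spanning 30–346 m, two species, three seasons, two
peaks) and can inject a between-peak regime change in the spring
(over-winter) coefficients — emulating the documented failure of elevation
to proxy winter conditions consistently across peaks.

## Worked example

```r
library(lemcast)

sites <- generate_sites(98, 30, 346, seed = 1)
scen  <- make_transfer_scenario(sites, default_peak_parameters(),
                                spring_shift = reference_spring_shift(),
                                seed = 1)
f1 <- fit_peak(model_spec(scen$peak1), mcmc_settings(seed = 2))
f2 <- fit_peak(model_spec(scen$peak2), mcmc_settings(seed = 3))

subset(coefficient_table(f1), term %in% c("beta_elev", "beta_dlem_minus1"))
#>   season             term   mean    sd ci_lower ci_upper rhat
#> 3 spring        beta_elev  0.859 0.203    0.525    1.259 1.22
#> 7 autumn        beta_elev  0.600 0.270    0.069    0.986 1.34
#> 4 spring beta_dlem_minus1 -1.301 0.268   -2.076   -1.011 1.13
#> 8 autumn beta_dlem_minus1 -0.891 0.311   -1.373   -0.386 1.35
```

The peak-1 fit recovers the generating coefficients (spring elevation
effect 0.86 vs truth 0.845; autumn 0.60 vs 0.528), and the β_dlem − 1
values near −1 say the previous season's density barely carries over. The
seasonal abundance summary shows the characteristic spring-to-autumn
outbreak growth, with the spatial CV quantifying between-site variability:

```r
subset(abundance_table(f1), species == "lemming")
#>   season   season_label species mean_abundance sd_abundance    cv n_sites
#> 1      1 prepeak_autumn lemming          0.168       0.0772 0.459      98
#> 2      2         spring lemming          0.473       0.4172 0.882      98
#> 3      3         autumn lemming          2.229       1.6848 0.756      98

transfer_report(f1, f2)
#> Temporal-transferability validation (peak 1 -> peak 2)
#>  season   mae   bias n_sites mean_abundance degenerate
#>  spring 0.265 -0.124      98          0.304      FALSE
#>  autumn 0.254 -0.197      98          2.339      FALSE
#> spring/autumn MAE ratio: 1.04
```

MAE is in individuals per site and must be read against the mean
season-specific abundance: here the spring error (0.265) is comparable to
the *whole* mean spring abundance (0.30) because the simulated peak-2
winter regime differs from the trained one, while the autumn error (0.254)
is an order of magnitude below the mean autumn abundance (2.34) — good
over-summer transfer, poor over-winter transfer. At these desk-scale MCMC
settings the convergence flag often trips (R̂ up to ~1.3); production
settings (`mcmc_settings(4, 50000, 15000)`) are available through the same
interface.

The one-command pipeline runs simulate → fit ×2 → transfer and writes every
table (coefficients with the β_dlem − 1 column, abundance/CV, R̂ report,
transfer metrics JSON, log with all seeds):

```r
run_pipeline(default_config(seed = 1, output_dir = "demo-run"))
```

or from a shell, `inst/scripts/lemcast run-all --config cfg.yaml --seed 1`.

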