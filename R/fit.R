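#' Prior settings for the state-space model
#'
#' Weakly informative defaults on the log-abundance scale: Normal(0, sd 10)
#' for all process coefficients and season-level means, Uniform(0, 10) for
#' every SD. All are configurable.
#'
#' @param beta_mean,beta_sd normal prior for the process coefficients.
#' @param mu_mean,mu_sd normal prior for the initial-season and vole
#'   season-level log-abundance means.
#' @param sigma_upper upper bound of the uniform prior on SD parameters.
#' @return A list of prior settings.
#' @export
default_priors <- function(beta_mean = 0, beta_sd = 10,
                           mu_mean = 0, mu_sd = 10, sigma_upper = 10) {
  stopifnot(beta_sd > 0, mu_sd > 0, sigma_upper > 0)
  list(beta_mean = beta_mean, beta_sd = beta_sd,
       mu_mean = mu_mean, mu_sd = mu_sd, sigma_upper = sigma_upper)
}

#' Model specification for one peak
#'
#' Binds one peak's trapping data to the state-space model: extracts the
#' count matrices, standardises the elevations and records the prior and
#' structural settings.
#'
#' @param dataset a `trapping_dataset` for a single peak.
#' @param priors prior settings, see [default_priors()].
#' @param sigma_per_season if `TRUE`, a separate process SD per dynamic
#'   season; default is one SD shared within the peak.
#' @param autumn_lemming_only if `TRUE`, the autumn (season 3) process drops
#'   the vole and elevation terms, leaving spring lemming density as the only
#'   predictor (a reduced over-summer model variant).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(dataset, priors = default_priors(),
                       sigma_per_season = FALSE,
                       autumn_lemming_only = FALSE) {
  stopifnot(inherits(dataset, "trapping_dataset"))
  validate_dataset_frame(dataset$data)
  sc <- scale_elevation(dataset$sites$elevation_m)
  structure(list(
    dataset = dataset,
    y = count_matrix(dataset, "lemming"),
    x = count_matrix(dataset, "vole"),
    scaled_elev = sc$scaled, elev_center_m = sc$center_m,
    elev_scale_m = sc$scale_m,
    n_sites = nrow(dataset$sites),
    priors = priors,
    sigma_per_season = isTRUE(sigma_per_season),
    autumn_lemming_only = isTRUE(autumn_lemming_only)
  ), class = "model_spec")
}

#' MCMC settings
#'
#' Desk-scale defaults (2 chains of 4000 iterations, burn-in 1000) suited to
#' simulation studies; production-scale runs (e.g. 4 chains of 50000 with
#' burn-in 15000) are configured through the same object.
#'
#' @param n_chains number of chains (>= 2; the Gelman-Rubin diagnostic needs
#'   at least two).
#' @param n_iterations iterations per chain, including burn-in.
#' @param n_burnin burn-in iterations discarded per chain (< n_iterations).
#' @param thin thinning interval for retained draws.
#' @param n_adapt JAGS adaptation steps before burn-in.
#' @param seed integer seed; per-chain RNG seeds are derived from it.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2L, n_iterations = 4000L,
                          n_burnin = 1000L, thin = 1L, n_adapt = 500L,
                          seed = 1L) {
  if (n_chains < 2L) stop("'n_chains' must be >= 2 (R-hat needs >= 2 chains)")
  if (n_burnin >= n_iterations) stop("'n_burnin' must be < 'n_iterations'")
  if (thin < 1L) stop("'thin' must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_adapt = as.integer(n_adapt), seed = as.integer(seed)),
            class = "mcmc_settings")
}

# JAGS translation of the model; dynamic-season arrays are indexed
# s = 1 (spring), 2 (autumn) so every declared node is monitorable
jags_model_string <- function(spec) {
  p <- spec$priors
  tau_beta <- 1 / p$beta_sd^2
  tau_mu <- 1 / p$mu_sd^2
  sig_proc <- if (spec$sigma_per_season) "sigma[k-1]" else "sigma"
  sig_decl <- if (spec$sigma_per_season)
    sprintf("for (s in 1:2) { sigma[s] ~ dunif(0, %g); tau_proc[s] <- pow(sigma[s], -2) }",
            p$sigma_upper)
  else
    sprintf("sigma ~ dunif(0, %g); tau_proc <- pow(sigma, -2)", p$sigma_upper)
  tau_proc <- if (spec$sigma_per_season) "tau_proc[k-1]" else "tau_proc"
  lin <- c(
    spring = "beta0[1] + beta_dvole[1]*log_lx[i,1] + beta_elev[1]*elev[i] + beta_dlem[1]*log_ly[i,1]",
    autumn = if (spec$autumn_lemming_only)
      "beta0[2] + beta_dlem[2]*log_ly[i,2]"
    else
      "beta0[2] + beta_dvole[2]*log_lx[i,2] + beta_elev[2]*elev[i] + beta_dlem[2]*log_ly[i,2]"
  )
  # beta_dvole/beta_elev keep their priors in the reduced autumn variant so
  # the monitored parameter set is identical across model variants
  dvole_elev_priors <- sprintf(
    "    beta_dvole[s] ~ dnorm(%g, %g)\n    beta_elev[s] ~ dnorm(%g, %g)",
    p$beta_mean, tau_beta, p$beta_mean, tau_beta)
  paste0("model {
  for (i in 1:nsite) {
    for (k in 1:3) {
      log_lx[i,k] ~ dnorm(mu_vole[k], tau_vole[k])
      x[i,k] ~ dpois(exp(log_lx[i,k]))
    }
    log_ly[i,1] ~ dnorm(mu_init, tau_init)
    y[i,1] ~ dpois(exp(log_ly[i,1]))
    m[i,1] <- ", lin[["spring"]], "
    m[i,2] <- ", lin[["autumn"]], "
    for (k in 2:3) {
      log_ly[i,k] ~ dnorm(m[i,k-1], ", tau_proc, ")
      y[i,k] ~ dpois(exp(log_ly[i,k]))
    }
  }
  for (s in 1:2) {
    beta0[s] ~ dnorm(", p$beta_mean, ", ", tau_beta, ")
    beta_dlem[s] ~ dnorm(", p$beta_mean, ", ", tau_beta, ")
", dvole_elev_priors, "
  }
  for (k in 1:3) {
    mu_vole[k] ~ dnorm(", p$mu_mean, ", ", tau_mu, ")
    sd_vole[k] ~ dunif(0, ", p$sigma_upper, ")
    tau_vole[k] <- pow(sd_vole[k], -2)
  }
  mu_init ~ dnorm(", p$mu_mean, ", ", tau_mu, ")
  sd_init ~ dunif(0, ", p$sigma_upper, ")
  tau_init <- pow(sd_init, -2)
  ", sig_decl, "
}
")
}

# structural (non-latent) parameters monitored for convergence
structural_params <- function(spec) {
  c("beta0", "beta_dvole", "beta_elev", "beta_dlem", "sigma",
    "mu_vole", "sd_vole", "mu_init", "sd_init")
}

#' Fit the state-space model to one peak by MCMC
#'
#' Compiles the model for JAGS and draws posterior samples of the process
#' coefficients, season-level means, SDs and (optionally) all latent log
#' abundances. Latent log abundances are initialised at `log(count + 0.5)`.
#' The run is reproducible: all chain RNGs are seeded deterministically from
#' `settings$seed`.
#'
#' Convergence is diagnosed, not enforced: the Gelman-Rubin statistic is
#' computed for every structural parameter and the fit is flagged
#' `converged = FALSE` if any R-hat is >= 1.1, but the fit is still returned.
#'
#' @param spec a [model_spec()].
#' @param settings an [mcmc_settings()] object.
#' @param monitor_latents monitor the latent log abundances (needed for
#'   abundance tables and transfer validation).
#' @param sample_prior if `TRUE`, the counts are withheld and the sampler
#'   draws from the prior (prior-dominance checks).
#' @param quiet suppress JAGS progress output.
#' @return An object of class `peak_fit`: `draws` (a [coda::mcmc.list]),
#'   `rhat` (named vector over structural parameters), `converged`, `spec`,
#'   `settings`.
#' @export
fit_peak <- function(spec, settings = mcmc_settings(),
                     monitor_latents = TRUE, sample_prior = FALSE,
                     quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(settings, "mcmc_settings"))
  dat <- list(nsite = spec$n_sites, elev = spec$scaled_elev)
  if (!sample_prior) { dat$y <- spec$y; dat$x <- spec$x }
  chain_seeds <- derive_seeds(settings$seed, settings$n_chains)
  inits <- lapply(seq_len(settings$n_chains), function(c) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = chain_seeds[c])
    if (!sample_prior) {
      ini$log_ly <- log(spec$y + 0.5)
      ini$log_lx <- log(spec$x + 0.5)
    }
    ini
  })
  monitors <- structural_params(spec)
  if (monitor_latents) monitors <- c(monitors, "log_ly", "log_lx")
  run <- function() {
    jm <- rjags::jags.model(textConnection(jags_model_string(spec)),
                            data = dat, inits = inits,
                            n.chains = settings$n_chains,
                            n.adapt = settings$n_adapt, quiet = TRUE)
    stats::update(jm, settings$n_burnin, progress.bar = "none")
    rjags::coda.samples(jm, monitors,
                        n.iter = settings$n_iterations - settings$n_burnin,
                        thin = settings$thin, progress.bar = "none")
  }
  draws <- if (quiet) suppressWarnings(run()) else run()
  struct_cols <- grep("^(beta|sigma|mu_|sd_)", coda::varnames(draws),
                      value = TRUE)
  rhat <- compute_rhat(draws[, struct_cols, drop = FALSE])
  structure(list(draws = draws, rhat = rhat,
                 converged = all(rhat < 1.1, na.rm = TRUE),
                 spec = spec, settings = settings,
                 monitor_latents = monitor_latents,
                 sample_prior = sample_prior),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("State-space fit: %d sites, %d chains x %d kept draws\n",
              x$spec$n_sites, x$settings$n_chains,
              coda::niter(x$draws)))
  cat(sprintf("max R-hat (structural parameters): %.3f -> %s\n",
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged (all < 1.1)" else "NOT converged"))
  invisible(x)
}
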