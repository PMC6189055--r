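# Shared fixtures for the test suite. Fits are memoized so several test
# files can reuse the same small MCMC runs.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noise-free parameters: every latent equals its deterministic recursion
deterministic_params <- function(beta0 = c(spring = 0, autumn = 0),
                                 beta_dvole = c(0, 0), beta_elev = c(0, 0),
                                 beta_dlem = c(0, 0), init_mu_lem = 0,
                                 vole_mu = c(0, 0, 0)) {
  peak_parameters(beta0 = beta0, beta_dvole = beta_dvole,
                  beta_elev = beta_elev, beta_dlem = beta_dlem,
                  sigma = 1e-12, init_mu_lem = init_mu_lem,
                  init_sd_lem = 0, vole_mu = vole_mu, vole_sd = c(0, 0, 0))
}

tiny_settings <- function(seed = 42L)
  mcmc_settings(n_chains = 2L, n_iterations = 1500L, n_burnin = 500L,
                n_adapt = 300L, seed = seed)

# small two-peak null scenario plus fits, shared across test files
tiny_scenario <- function() memoize("tiny_scenario", {
  sites <- generate_sites(25, seed = 101)
  make_transfer_scenario(sites, default_peak_parameters(),
                         spring_shift = numeric(0), seed = 202)
})

tiny_fit1 <- function() memoize("tiny_fit1",
  fit_peak(model_spec(tiny_scenario()$peak1), tiny_settings(7)))

tiny_fit2 <- function() memoize("tiny_fit2",
  fit_peak(model_spec(tiny_scenario()$peak2), tiny_settings(8)))

# independent vectorized assembly of the state-space density, structured
# differently from log_joint() (matrix sums over stacked season blocks);
# used as the dual-route density oracle
log_joint_reference <- function(dataset, params, latents) {
  y <- sapply(1:3, function(k) {
    d <- dataset$data
    d$count[d$species == "lemming" & d$season == k][
      order(d$site_id[d$species == "lemming" & d$season == k])]
  })
  x <- sapply(1:3, function(k) {
    d <- dataset$data
    d$count[d$species == "vole" & d$season == k][
      order(d$site_id[d$species == "vole" & d$season == k])]
  })
  e <- dataset$sites$elevation_m[order(dataset$sites$site_id)]
  se <- (e - mean(e)) / sd(e)
  ll <- latents$log_lem[order(dataset$sites$site_id), , drop = FALSE]
  lv <- latents$log_vole[order(dataset$sites$site_id), , drop = FALSE]
  obs <- sum(dpois(cbind(y, x), exp(cbind(ll, lv)), log = TRUE))
  mu_lem <- cbind(params$init_mu_lem,
                  params$beta0[1] + params$beta_dvole[1] * lv[, 1] +
                    params$beta_elev[1] * se + params$beta_dlem[1] * ll[, 1],
                  params$beta0[2] + params$beta_dvole[2] * lv[, 2] +
                    params$beta_elev[2] * se + params$beta_dlem[2] * ll[, 2])
  sd_lem <- cbind(params$init_sd_lem, params$sigma, params$sigma)[rep(1, nrow(ll)), ]
  proc <- sum(dnorm(ll, mu_lem, sd_lem, log = TRUE)) +
    sum(dnorm(lv, rep(params$vole_mu, each = nrow(lv)),
              rep(params$vole_sd, each = nrow(lv)), log = TRUE))
  obs + proc
}

random_params <- function() {
  peak_parameters(beta0 = rnorm(2), beta_dvole = rnorm(2),
                  beta_elev = rnorm(2), beta_dlem = rnorm(2),
                  sigma = runif(1, 0.1, 1),
                  init_mu_lem = rnorm(1), init_sd_lem = runif(1, 0.1, 1),
                  vole_mu = rnorm(3), vole_sd = runif(3, 0.1, 1))
}

random_latents <- function(n) list(log_lem = matrix(rnorm(n * 3), n, 3),
                                   log_vole = matrix(rnorm(n * 3), n, 3))
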