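#' Standardise site elevations
#'
#' Centers elevations at their mean and divides by the sample SD (n - 1
#' convention), so the elevation coefficient is an effect per SD of the site
#' network's elevation gradient. The SD in metres (`scale_m`) is returned so
#' users can report how many metres one scaled unit corresponds to on their
#' own site network.
#'
#' @param elevations numeric vector of site elevations in metres (>= 2 sites,
#'   non-degenerate gradient).
#' @return List with `scaled` (mean 0, SD 1), `center_m` and `scale_m`.
#' @examples
#' scale_elevation(c(100, 200, 300))
#' @export
scale_elevation <- function(elevations) {
  if (length(elevations) < 2L)
    stop("at least 2 elevations are required")
  s <- stats::sd(elevations)
  if (!is.finite(s) || s == 0)
    stop("degenerate elevation gradient: SD of elevations is 0")
  m <- mean(elevations)
  list(scaled = (elevations - m) / s, center_m = m, scale_m = s)
}

#' Poisson observation log-probability
#'
#' Log pmf of the trapping count given the latent abundance, the observation
#' half of the state-space model.
#'
#' @param count non-negative integer count(s).
#' @param lambda_ latent abundance(s), > 0.
#' @return Log probability, vectorised over inputs.
#' @export
observation_logpmf <- function(count, lambda_) {
  if (any(!is.finite(count) | count < 0 | count != round(count)))
    stop("'count' must contain non-negative integers")
  if (any(!is.finite(lambda_) | lambda_ <= 0))
    stop("'lambda_' must be > 0")
  stats::dpois(count, lambda_, log = TRUE)
}

#' Linear predictor of the lemming process model
#'
#' Expected log abundance for a dynamic season: intercept plus inter-specific
#' density dependence on the vole's previous-season log abundance, the
#' elevation effect on standardised elevation, and intra-specific density
#' dependence on the lemming's own previous-season log abundance
#' (a Gompertz-type log-linear form).
#'
#' @param beta0,beta_dvole,beta_elev,beta_dlem scalar coefficients.
#' @param log_prev_vole,scaled_elev,log_prev_lem predictor vectors.
#' @return The linear predictor, vectorised over sites.
#' @export
process_mean <- function(beta0, beta_dvole, beta_elev, beta_dlem,
                         log_prev_vole, scaled_elev, log_prev_lem) {
  beta0 + beta_dvole * log_prev_vole + beta_elev * scaled_elev +
    beta_dlem * log_prev_lem
}

#' Joint log density of one peak's data and latents
#'
#' Assembles the full state-space density for one cyclic peak at a given
#' parameter/latent configuration: Poisson observation terms for both
#' species in all seasons, normal process terms for the dynamic-season
#' lemming latents, and normal season-level terms for the initial-season
#' lemming and all vole latents. With `priors` supplied it adds the
#' coefficient and SD prior log densities, giving the unnormalised log
#' posterior; without, it is the generative log density given the parameters.
#'
#' Serves as a closed-form oracle for the sampler's target density.
#'
#' @param dataset a `trapping_dataset`.
#' @param params a [peak_parameters()] object.
#' @param latents list with matrices `log_lem` and `log_vole`
#'   (n_sites x 3); defaults to the dataset's stored true latents.
#' @param priors optional [default_priors()]-style list.
#' @return Scalar log density.
#' @export
log_joint <- function(dataset, params, latents = dataset$latents,
                      priors = NULL) {
  stopifnot(inherits(dataset, "trapping_dataset"),
            inherits(params, "peak_parameters"))
  n <- nrow(dataset$sites)
  if (is.null(latents) || !all(c("log_lem", "log_vole") %in% names(latents)))
    stop("'latents' must provide matrices log_lem and log_vole")
  log_lem <- latents$log_lem; log_vole <- latents$log_vole
  if (!all(dim(log_lem) == c(n, 3L)) || !all(dim(log_vole) == c(n, 3L)))
    stop(sprintf("latent matrices must be %d x 3 to match the dataset", n))
  y <- count_matrix(dataset, "lemming")
  x <- count_matrix(dataset, "vole")
  se <- scale_elevation(dataset$sites$elevation_m)$scaled

  lp <- sum(observation_logpmf(y, exp(log_lem))) +
    sum(observation_logpmf(x, exp(log_vole)))
  lp <- lp + sum(stats::dnorm(log_lem[, 1], params$init_mu_lem,
                              params$init_sd_lem, log = TRUE))
  for (k in 2:3) {
    s <- k - 1L
    m <- process_mean(params$beta0[s], params$beta_dvole[s],
                      params$beta_elev[s], params$beta_dlem[s],
                      log_vole[, k - 1], se, log_lem[, k - 1])
    lp <- lp + sum(stats::dnorm(log_lem[, k], m, params$sigma, log = TRUE))
  }
  for (k in 1:3)
    lp <- lp + sum(stats::dnorm(log_vole[, k], params$vole_mu[k],
                                params$vole_sd[k], log = TRUE))
  if (!is.null(priors)) {
    betas <- c(params$beta0, params$beta_dvole, params$beta_elev,
               params$beta_dlem)
    lp <- lp + sum(stats::dnorm(betas, priors$beta_mean, priors$beta_sd,
                                log = TRUE)) +
      sum(stats::dnorm(c(params$init_mu_lem, params$vole_mu),
                       priors$mu_mean, priors$mu_sd, log = TRUE)) +
      sum(stats::dunif(c(params$sigma, params$init_sd_lem, params$vole_sd),
                       0, priors$sigma_upper, log = TRUE))
  }
  lp
}
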