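#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) R-hat: with m chains of n draws, within-chain variance
#' W, and between-chain variance B = n * Var(chain means),
#' `R-hat = sqrt((((n - 1)/n) * W + B/n) / W)`. Values below 1.1 are
#' conventionally taken to indicate convergence. With zero between-chain
#' variance the statistic equals `sqrt((n - 1)/n)`, slightly below 1.
#'
#' @param draws a matrix with one column per chain, or a [coda::mcmc.list]
#'   (R-hat is then computed per parameter).
#' @return A single R-hat, or a named vector per parameter for an mcmc.list.
#' @export
compute_rhat <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    pars <- coda::varnames(draws)
    return(stats::setNames(vapply(pars, function(p)
      compute_rhat(sapply(draws, function(ch) as.matrix(ch)[, p])),
      numeric(1)), pars))
  }
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2L) stop("R-hat requires at least 2 chains")
  if (n < 4L) stop("R-hat requires chains of length >= 4")
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(colMeans(draws))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary table
#'
#' Posterior mean, SD and central 95% credible interval (2.5% and 97.5%
#' quantiles, linear interpolation between order statistics) for every
#' monitored quantity, chains pooled, with the Gelman-Rubin R-hat alongside
#' for the structural parameters.
#'
#' @param fit a `peak_fit`, or a [coda::mcmc.list].
#' @param prob total credible-interval mass (default 0.95).
#' @return Data frame with columns `parameter`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`, `rhat` (NA where not monitored for convergence).
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  draws <- if (inherits(fit, "peak_fit")) fit$draws else fit
  if (!inherits(draws, "mcmc.list"))
    stop("'fit' must be a peak_fit or a coda::mcmc.list")
  if (length(draws) == 0L || coda::niter(draws) == 0L)
    stop("no posterior draws to summarise")
  mat <- as.matrix(draws)
  a <- (1 - prob) / 2
  qs <- t(apply(mat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  rhat <- if (inherits(fit, "peak_fit")) fit$rhat else NULL
  out <- data.frame(parameter = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2, stats::sd),
                    ci_lower = qs[, 1], ci_upper = qs[, 2],
                    rhat = if (is.null(rhat)) NA_real_ else
                      unname(rhat[colnames(mat)]),
                    row.names = NULL)
  stopifnot(all(out$ci_lower <= out$ci_upper))
  out
}

#' Season-specific coefficient table
#'
#' The fitted process coefficients per dynamic season, formatted the way
#' such models are conventionally reported: posterior mean, SD, 95% credible
#' interval and R-hat for the inter-specific (`beta_dvole`) and elevation
#' (`beta_elev`) effects, the intercept, the process SD, and the
#' intra-specific density dependence reported as `beta_dlem - 1` (the
#' transform is applied per draw, so mean and interval shift by exactly -1;
#' values near -1 mean no carry-over of the previous season's density).
#'
#' @param fit a `peak_fit`.
#' @return Data frame with columns `season`, `term`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`, `rhat`.
#' @export
coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "peak_fit"))
  mat <- as.matrix(fit$draws)
  seasons <- c("spring", "autumn")
  rows <- list()
  for (s in 1:2) {
    for (term in c("beta0", "beta_dvole", "beta_elev")) {
      p <- sprintf("%s[%d]", term, s)
      rows[[length(rows) + 1L]] <- summarize_draws_row(mat[, p], fit$rhat[[p]],
                                                       seasons[s], term)
    }
    p <- sprintf("beta_dlem[%d]", s)
    rows[[length(rows) + 1L]] <- summarize_draws_row(mat[, p] - 1,
                                                     fit$rhat[[p]],
                                                     seasons[s],
                                                     "beta_dlem_minus1")
  }
  sig <- grep("^sigma", colnames(mat), value = TRUE)
  for (p in sig)
    rows[[length(rows) + 1L]] <- summarize_draws_row(
      mat[, p], fit$rhat[[p]],
      if (fit$spec$sigma_per_season)
        seasons[as.integer(sub("sigma\\[(\\d)\\]", "\\1", p))] else "shared",
      "sigma")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summarize_draws_row <- function(d, rhat, season, term) {
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  data.frame(season = season, term = term, mean = mean(d), sd = stats::sd(d),
             ci_lower = q[1], ci_upper = q[2],
             rhat = if (is.null(rhat)) NA_real_ else rhat)
}

#' Spatial coefficient of variation
#'
#' CV = sd / mean, used to quantify across-site variability of the
#' site-level posterior-mean abundances.
#'
#' @param mean_ across-site mean abundance (> 0).
#' @param sd_ across-site SD (>= 0).
#' @return The CV, vectorised.
#' @export
spatial_cv <- function(mean_, sd_) {
  if (any(!is.finite(mean_) | mean_ <= 0))
    stop("CV is undefined for mean <= 0")
  if (any(sd_ < 0)) stop("'sd_' must be >= 0")
  sd_ / mean_
}

#' Seasonal abundance summary
#'
#' For each season and species: the across-site mean and SD of the
#' site-level posterior-mean abundances (posterior mean of `exp(log lambda)`
#' per site), and the spatial CV = SD/mean.
#'
#' @param fit a `peak_fit` with latent log abundances monitored.
#' @return Data frame with columns `season`, `season_label`, `species`,
#'   `mean_abundance`, `sd_abundance`, `cv`, `n_sites`.
#' @export
abundance_table <- function(fit) {
  lam <- posterior_mean_lambda(fit)
  labels <- c("prepeak_autumn", "spring", "autumn")
  out <- do.call(rbind, lapply(c("lemming", "vole"), function(sp) {
    m <- lam[[sp]]
    data.frame(season = 1:3, season_label = labels, species = sp,
               mean_abundance = colMeans(m),
               sd_abundance = apply(m, 2, stats::sd),
               n_sites = nrow(m))
  }))
  out$cv <- spatial_cv(out$mean_abundance, out$sd_abundance)
  rownames(out) <- NULL
  out[, c("season", "season_label", "species", "mean_abundance",
          "sd_abundance", "cv", "n_sites")]
}

# site x season matrices of posterior-mean abundance (natural scale) and of
# posterior-mean log abundance, per species
posterior_mean_lambda <- function(fit) {
  stopifnot(inherits(fit, "peak_fit"))
  if (!isTRUE(fit$monitor_latents))
    stop("latent log abundances were not monitored; refit with monitor_latents = TRUE")
  mat <- as.matrix(fit$draws)
  n <- fit$spec$n_sites
  grab <- function(stub, f) {
    m <- matrix(NA_real_, n, 3L)
    for (k in 1:3) {
      cols <- sprintf("%s[%d,%d]", stub, seq_len(n), k)
      m[, k] <- colMeans(f(mat[, cols, drop = FALSE]))
    }
    m
  }
  list(lemming = grab("log_ly", exp), vole = grab("log_lx", exp),
       lemming_log = grab("log_ly", identity),
       vole_log = grab("log_lx", identity))
}
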