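#' Plug-in abundance prediction from another peak's coefficients
#'
#' Applies one peak's fitted season-specific coefficients to another peak's
#' predictor values: `log(p_lambda) = beta0 + beta_dvole * log_prev_vole +
#' beta_elev * scaled_elev + beta_dlem * log_prev_lem`, returning the
#' natural-scale abundance `exp(log p_lambda)`. A deterministic point
#' prediction: no process noise is added.
#'
#' @param coefs named list or vector with `beta0`, `beta_dvole`, `beta_elev`
#'   and `beta_dlem` for one season (typically posterior means).
#' @param log_prev_vole previous-season vole log abundance per site
#'   (typically posterior means of the latents).
#' @param scaled_elev standardised elevation per site.
#' @param log_prev_lem previous-season lemming log abundance per site.
#' @return Predicted abundance per site (natural scale).
#' @export
predict_abundance <- function(coefs, log_prev_vole, scaled_elev,
                              log_prev_lem) {
  need <- c("beta0", "beta_dvole", "beta_elev", "beta_dlem")
  miss <- setdiff(need, names(coefs))
  if (length(miss))
    stop("missing coefficient(s): ", paste(miss, collapse = ", "))
  lens <- c(length(log_prev_vole), length(scaled_elev), length(log_prev_lem))
  if (length(unique(lens)) != 1L)
    stop(sprintf("predictor vectors must be aligned (lengths %s)",
                 paste(lens, collapse = ", ")))
  coefs <- as.list(coefs)
  exp(process_mean(coefs$beta0, coefs$beta_dvole, coefs$beta_elev,
                   coefs$beta_dlem, log_prev_vole, scaled_elev,
                   log_prev_lem))
}

#' Mean-centered mean absolute error
#'
#' `MAE = n^-1 * sum(|(P_i - mean(P)) - (O_i - mean(O))|)` on the natural
#' abundance scale. Both vectors are centered at their own means before the
#' absolute differences are taken, so a constant offset between prediction
#' and estimate (e.g. a season-level abundance difference) does not
#' contribute; the statistic scores the site-to-site pattern.
#'
#' @param P predicted abundances.
#' @param O estimated abundances.
#' @return The MAE (individuals per site).
#' @export
mae <- function(P, O) {
  if (length(P) != length(O)) stop("'P' and 'O' must have equal length")
  if (length(P) < 1L) stop("at least one pair is required")
  mean(abs((P - mean(P)) - (O - mean(O))))
}

#' Log-scale prediction bias
#'
#' Mean signed log-scale error `mean(log(P) - log(O))` and the per-site
#' residuals. Positive values mean over-prediction.
#'
#' @param P predicted abundances (> 0, natural scale).
#' @param O estimated abundances (> 0, natural scale).
#' @return List with `mean` (mean signed log error) and `residuals`.
#' @export
bias <- function(P, O) {
  if (length(P) != length(O)) stop("'P' and 'O' must have equal length")
  if (any(P <= 0) || any(O <= 0))
    stop("'P' and 'O' must be positive abundances")
  r <- log(P) - log(O)
  list(mean = mean(r), residuals = r)
}

#' Temporal-transferability validation report
#'
#' Projects the dynamics fitted to one peak onto the next: for each dynamic
#' season, the posterior-mean coefficients of `fit_peak1` are applied to the
#' second peak's predictors (the posterior-mean latent log abundances of the
#' previous season and the second peak's standardised elevations) to obtain
#' plug-in predicted abundances, which are validated against the second
#' peak's estimated (posterior-mean) abundances with the mean-centered MAE
#' and the log-scale bias.
#'
#' The MAE should be judged relative to the mean season-specific abundance,
#' which the report carries per season; the spring/autumn MAE ratio
#' summarises the seasonal contrast in transferability.
#'
#' @param fit_peak1 `peak_fit` of the training peak (coefficients).
#' @param fit_peak2 `peak_fit` of the validation peak (predictors and
#'   estimated abundances); latents must be monitored in this fit.
#' @return An object of class `transfer_report`: `metrics` (one row per
#'   dynamic season: `season`, `mae`, `bias`, `n_sites`, `mean_abundance`,
#'   `degenerate`), `pairs` (site-level `log_predicted` / `log_estimated`,
#'   the scatter input), `mae_ratio_spring_autumn`, `converged` flags.
#' @export
transfer_report <- function(fit_peak1, fit_peak2) {
  stopifnot(inherits(fit_peak1, "peak_fit"), inherits(fit_peak2, "peak_fit"))
  co <- summarize_posterior(fit_peak1)
  lam2 <- posterior_mean_lambda(fit_peak2)
  se2 <- fit_peak2$spec$scaled_elev
  sites2 <- fit_peak2$spec$dataset$sites$site_id
  n <- length(sites2)

  season_names <- c("spring", "autumn")
  metrics <- list(); pairs <- list()
  for (s in 1:2) {
    k <- s + 1L
    coefs <- lapply(c("beta0", "beta_dvole", "beta_elev", "beta_dlem"),
                    function(term)
                      co$mean[co$parameter == sprintf("%s[%d]", term, s)])
    names(coefs) <- c("beta0", "beta_dvole", "beta_elev", "beta_dlem")
    if (any(lengths(coefs) != 1L))
      stop("fit_peak1 is missing a monitored coefficient for season ",
           season_names[s])
    P <- predict_abundance(coefs,
                           log_prev_vole = lam2$vole_log[, k - 1],
                           scaled_elev = se2,
                           log_prev_lem = lam2$lemming_log[, k - 1])
    O <- lam2$lemming[, k]
    metrics[[s]] <- data.frame(
      season = season_names[s],
      mae = mae(P, O),
      bias = bias(P, O)$mean,
      n_sites = n,
      mean_abundance = mean(O),
      degenerate = n < 2L
    )
    pairs[[s]] <- data.frame(site_id = sites2, season = season_names[s],
                             log_predicted = log(P), log_estimated = log(O))
  }
  metrics <- do.call(rbind, metrics)
  structure(list(
    metrics = metrics,
    pairs = do.call(rbind, pairs),
    mae_ratio_spring_autumn =
      metrics$mae[metrics$season == "spring"] /
      metrics$mae[metrics$season == "autumn"],
    converged = c(peak1 = fit_peak1$converged, peak2 = fit_peak2$converged)
  ), class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("Temporal-transferability validation (peak 1 -> peak 2)\n")
  m <- x$metrics
  m$mae <- round(m$mae, 3); m$bias <- round(m$bias, 3)
  m$mean_abundance <- round(m$mean_abundance, 3)
  print(m, row.names = FALSE)
  cat(sprintf("spring/autumn MAE ratio: %.2f\n", x$mae_ratio_spring_autumn))
  if (!all(x$converged))
    cat("warning: fit(s) flagged not converged:",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n")
  invisible(x)
}

#' Predicted-versus-estimated scatter
#'
#' Plots the log-scale predicted against estimated abundances per season,
#' with the identity line; points on the line indicate perfect transfer.
#'
#' @param report a `transfer_report`.
#' @param file optional path; if given, a PNG is written there.
#' @return The report, invisibly.
#' @export
plot_transfer <- function(report, file = NULL) {
  stopifnot(inherits(report, "transfer_report"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 480)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  for (s in c("spring", "autumn")) {
    p <- report$pairs[report$pairs$season == s, ]
    lim <- range(c(p$log_predicted, p$log_estimated))
    plot(p$log_predicted, p$log_estimated, xlim = lim, ylim = lim,
         xlab = "log predicted abundance", ylab = "log estimated abundance",
         main = s, pch = 19, col = "grey30")
    graphics::abline(0, 1, col = "red", lty = 2)
  }
  invisible(report)
}
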