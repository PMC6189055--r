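#' Generate a table of trapping sites along an elevation gradient
#'
#' Site elevations are drawn uniformly over the configured range, emulating a
#' snap-trapping design whose sites span the local elevation (and hence
#' climate) gradient.
#'
#' @param n_sites number of sites (>= 2; the elevation standardisation is
#'   undefined for a single site).
#' @param elev_min,elev_max elevation range in metres above sea level.
#' @param seed integer seed; the table is deterministic given the seed.
#' @return A data frame with columns `site_id` (integer) and `elevation_m`.
#' @examples
#' sites <- generate_sites(98, 30, 346, seed = 1)
#' range(sites$elevation_m)
#' @export
generate_sites <- function(n_sites, elev_min = 30, elev_max = 346, seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 2)
    stop("'n_sites' must be >= 2 (elevation scaling is undefined otherwise)")
  if (elev_min >= elev_max) stop("'elev_min' must be < 'elev_max'")
  n_sites <- as.integer(n_sites)
  withr_seed(seed)
  data.frame(site_id = seq_len(n_sites),
             elevation_m = stats::runif(n_sites, elev_min, elev_max))
}

# set.seed with basic validation; all randomness in the package funnels
# through integer seeds so runs are reproducible end to end
withr_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite integer 'seed' is required")
  set.seed(as.integer(seed))
}

# derive k independent substream seeds from one master seed
derive_seeds <- function(seed, k) {
  withr_seed(seed)
  sample.int(2147483646L, k)
}

#' Simulate trapping counts for one cyclic peak
#'
#' Draws the latent log abundances of the lemming and the grey-sided vole for
#' the three trapping seasons of one cyclic peak and overlays Poisson
#' trapping counts, exactly following the generative structure of the
#' state-space model: season 1 (pre-peak autumn) lemming and all vole
#' log abundances come from season-level normal distributions, and seasons 2
#' (spring) and 3 (autumn) lemming log abundances follow the linear predictor
#' on standardised elevation and both species' previous-season latent log
#' abundances, with process SD `sigma`.
#'
#' The true parameters and latent log abundances are kept in the returned
#' object's metadata (fields `params` and `latents`) so parameter-recovery
#' checks are possible; fitting functions read only the `data` field.
#'
#' @param sites site table from [generate_sites()].
#' @param params a [peak_parameters()] object.
#' @param seed integer seed.
#' @param peak peak label stored in the data (1 or 2).
#' @return An object of class `trapping_dataset` with fields `data` (long
#'   data frame: site_id, peak, season, species, count, elevation_m),
#'   `sites`, `seed`, `params`, `latents`.
#' @export
simulate_peak <- function(sites, params, seed = 1L, peak = 1L) {
  stopifnot(inherits(params, "peak_parameters"))
  validate_sites(sites)
  n <- nrow(sites)
  se <- scale_elevation(sites$elevation_m)$scaled
  withr_seed(seed)

  log_vole <- vapply(1:3, function(k)
    stats::rnorm(n, params$vole_mu[k], params$vole_sd[k]), numeric(n))
  log_lem <- matrix(NA_real_, n, 3)
  log_lem[, 1] <- stats::rnorm(n, params$init_mu_lem, params$init_sd_lem)
  for (k in 2:3) {
    s <- k - 1L  # dynamic-season index: 1 = spring, 2 = autumn
    m <- process_mean(params$beta0[s], params$beta_dvole[s],
                      params$beta_elev[s], params$beta_dlem[s],
                      log_prev_vole = log_vole[, k - 1], scaled_elev = se,
                      log_prev_lem = log_lem[, k - 1])
    log_lem[, k] <- stats::rnorm(n, m, params$sigma)
  }
  bad <- which(!is.finite(log_lem) | !is.finite(log_vole), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite latent log abundance at site %d, season %d (extreme parameters?)",
                 sites$site_id[bad[1, 1]], bad[1, 2]))

  grid <- expand.grid(species = c("lemming", "vole"), season = 1:3,
                      site_id = sites$site_id, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lam <- ifelse(grid$species == "lemming",
                exp(log_lem)[cbind(match(grid$site_id, sites$site_id), grid$season)],
                exp(log_vole)[cbind(match(grid$site_id, sites$site_id), grid$season)])
  dat <- data.frame(
    site_id = grid$site_id,
    peak = as.integer(peak),
    season = as.integer(grid$season),
    species = grid$species,
    count = stats::rpois(nrow(grid), lam),
    elevation_m = sites$elevation_m[match(grid$site_id, sites$site_id)]
  )
  dat <- dat[order(dat$site_id, dat$season, dat$species), ]
  rownames(dat) <- NULL
  structure(list(data = dat, sites = sites, seed = as.integer(seed),
                 peak = as.integer(peak), params = params,
                 latents = list(log_lem = log_lem, log_vole = log_vole)),
            class = "trapping_dataset")
}

validate_sites <- function(sites) {
  if (!is.data.frame(sites) || !all(c("site_id", "elevation_m") %in% names(sites)))
    stop("'sites' must be a data frame with columns site_id and elevation_m")
  if (anyDuplicated(sites$site_id)) stop("site_id values must be unique")
  if (nrow(sites) < 2L) stop("at least 2 sites are required")
  invisible(sites)
}

#' @export
print.trapping_dataset <- function(x, ...) {
  cat(sprintf("Trapping dataset: peak %d, %d sites x 3 seasons x 2 species (seed %d)\n",
              x$peak, nrow(x$sites), x$seed))
  agg <- stats::aggregate(count ~ season + species, data = x$data, FUN = mean)
  agg$count <- round(agg$count, 2)
  names(agg)[3] <- "mean_count"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Build a two-peak transfer scenario
#'
#' Simulates two cyclic peaks over the same sites. Peak 2 uses the peak-1
#' parameters except for the spring (over-winter) coefficients, which are
#' shifted by `spring_shift` — emulating a between-peak regime change in the
#' winter dynamics while the summer dynamics stay put. With a zero shift the
#' two peaks are independent draws from the same process (the null scenario).
#'
#' @param sites site table shared by both peaks.
#' @param params_peak1 [peak_parameters()] for peak 1.
#' @param spring_shift named numeric vector of deltas added to the spring
#'   entries of `beta0`, `beta_dvole`, `beta_elev` and/or `beta_dlem`;
#'   see [reference_spring_shift()].
#' @param seed master seed; the two peaks use substream seeds derived from it.
#' @return List with elements `peak1`, `peak2` (trapping datasets) and
#'   `params_peak2`.
#' @export
make_transfer_scenario <- function(sites, params_peak1 = default_peak_parameters(),
                                   spring_shift = numeric(0), seed = 1L) {
  stopifnot(inherits(params_peak1, "peak_parameters"))
  allowed <- c("beta0", "beta_dvole", "beta_elev", "beta_dlem")
  if (length(spring_shift)) {
    spring_shift <- unlist(spring_shift)
    bad <- setdiff(names(spring_shift), allowed)
    if (length(bad) || is.null(names(spring_shift)))
      stop("'spring_shift' entries must be named among: ",
           paste(allowed, collapse = ", "))
  }
  params2 <- params_peak1
  for (nm in names(spring_shift))
    params2[[nm]]["spring"] <- params2[[nm]]["spring"] + spring_shift[[nm]]
  seeds <- derive_seeds(seed, 2L)
  list(peak1 = simulate_peak(sites, params_peak1, seed = seeds[1], peak = 1L),
       peak2 = simulate_peak(sites, params2, seed = seeds[2], peak = 2L),
       params_peak2 = params2)
}
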