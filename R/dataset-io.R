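#' Write / read a trapping dataset as CSV
#'
#' The counts go to a long-format CSV with header
#' `site_id,peak,season,species,count,elevation_m`; simulation metadata
#' (seed, true parameters, true latent log abundances), when present, goes
#' to a sidecar JSON file `<path>.json`, kept separate from the counts so
#' that inference never reads it implicitly. The round trip is lossless.
#'
#' @param dataset a `trapping_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   validated `trapping_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trapping_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = dataset$seed, peak = dataset$peak)
  if (!is.null(dataset$params)) meta$params <- unclass(dataset$params)
  if (!is.null(dataset$latents)) meta$latents <- dataset$latents
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset_frame(dat)
  dat <- dat[order(dat$site_id, dat$season, dat$species), ]
  rownames(dat) <- NULL
  sites <- unique(dat[, c("site_id", "elevation_m")])
  sites <- sites[order(sites$site_id), ]
  rownames(sites) <- NULL
  out <- list(data = dat, sites = sites, seed = NA_integer_,
              peak = dat$peak[1], params = NULL, latents = NULL)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    out$seed <- meta$seed
    if (!is.null(meta$params)) {
      p <- meta$params
      out$params <- peak_parameters(p$beta0, p$beta_dvole, p$beta_elev,
                                    p$beta_dlem, p$sigma, p$init_mu_lem,
                                    p$init_sd_lem, p$vole_mu, p$vole_sd)
    }
    if (!is.null(meta$latents))
      out$latents <- list(log_lem = as.matrix(meta$latents$log_lem),
                          log_vole = as.matrix(meta$latents$log_vole))
  }
  structure(out, class = "trapping_dataset")
}

# long-format invariants: columns, types, key uniqueness, grid completeness
validate_dataset_frame <- function(dat) {
  need <- c("site_id", "peak", "season", "species", "count", "elevation_m")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(dat) == 0L) stop("dataset has no rows")
  bad <- which(!is.finite(dat$count) | dat$count < 0 |
                 dat$count != round(dat$count))
  if (length(bad))
    stop(sprintf("counts must be non-negative integers; first offending row: %d (count = %s)",
                 bad[1], dat$count[bad[1]]))
  bad <- which(!dat$season %in% 1:3)
  if (length(bad))
    stop(sprintf("season must be 1, 2 or 3; first offending row: %d", bad[1]))
  bad <- which(!dat$species %in% c("lemming", "vole"))
  if (length(bad))
    stop(sprintf("species must be 'lemming' or 'vole'; first offending row: %d", bad[1]))
  key <- paste(dat$site_id, dat$peak, dat$season, dat$species)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicated (site, peak, season, species) key at row %d: %s",
                 dup[1], key[dup[1]]))
  full <- expand.grid(species = c("lemming", "vole"), season = 1:3,
                      site_id = unique(dat$site_id), peak = unique(dat$peak),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$site_id, full$peak, full$season, full$species)
  gap <- setdiff(fkey, key)
  if (length(gap))
    stop("incomplete (site, peak, season, species) grid; missing: ",
         paste(utils::head(gap, 3L), collapse = "; "),
         if (length(gap) > 3L) sprintf(" (and %d more)", length(gap) - 3L) else "")
  elev_n <- tapply(dat$elevation_m, dat$site_id, function(e) length(unique(e)))
  if (any(elev_n > 1L))
    stop("elevation_m must be constant within a site; offending site_id: ",
         names(elev_n)[which(elev_n > 1L)[1]])
  invisible(dat)
}

# counts of one species as an n_sites x 3 matrix, rows in site-table order
count_matrix <- function(dataset, species) {
  d <- dataset$data[dataset$data$species == species, ]
  m <- matrix(NA_integer_, nrow(dataset$sites), 3L)
  m[cbind(match(d$site_id, dataset$sites$site_id), d$season)] <- d$count
  m
}
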