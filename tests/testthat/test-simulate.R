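test_that("site generation respects range, count and seed determinism", {
  sites <- generate_sites(98, 30, 346, seed = 1)
  expect_equal(nrow(sites), 98)
  expect_true(all(sites$elevation_m >= 30 & sites$elevation_m <= 346))
  expect_false(anyDuplicated(sites$site_id) > 0)
  expect_identical(generate_sites(5, 100, 200, seed = 7),
                   generate_sites(5, 100, 200, seed = 7))
  expect_error(generate_sites(1, 30, 346, seed = 1), ">= 2")
  expect_error(generate_sites(10, 200, 100, seed = 1), "elev_min")
})

test_that("simulated datasets are deterministic and structurally complete", {
  sites <- generate_sites(12, seed = 3)
  d1 <- simulate_peak(sites, default_peak_parameters(), seed = 9)
  d2 <- simulate_peak(sites, default_peak_parameters(), seed = 9)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$latents, d2$latents)
  expect_equal(nrow(d1$data), 12 * 3 * 2)
  expect_no_error(lemcast:::validate_dataset_frame(d1$data))
  expect_true(all(d1$data$count >= 0 & d1$data$count == round(d1$data$count)))
})

test_that("noise-free latents follow the deterministic recursion exactly", {
  sites <- data.frame(site_id = 1:4, elevation_m = c(50, 150, 250, 350))
  se <- scale_elevation(sites$elevation_m)$scaled
  p <- deterministic_params(beta0 = c(spring = 0.4, autumn = -0.2),
                            beta_dvole = c(0.5, 0.1),
                            beta_elev = c(0.8, 0.3),
                            beta_dlem = c(0.2, 0.9),
                            init_mu_lem = -1, vole_mu = c(1, 0, 0.5))
  ds <- simulate_peak(sites, p, seed = 5)
  # closed-form recursion computed by hand from the linear predictor
  l1 <- rep(-1, 4)
  l2 <- 0.4 + 0.5 * 1 + 0.8 * se + 0.2 * l1
  l3 <- -0.2 + 0.1 * 0 + 0.3 * se + 0.9 * l2
  expect_equal(ds$latents$log_lem[, 1], l1, tolerance = 1e-9)
  expect_equal(ds$latents$log_lem[, 2], l2, tolerance = 1e-9)
  expect_equal(ds$latents$log_lem[, 3], l3, tolerance = 1e-9)
  expect_equal(ds$latents$log_vole,
               matrix(rep(c(1, 0, 0.5), each = 4), 4, 3), tolerance = 1e-12)
})

test_that("noise-free identity case gives unit spring abundance", {
  sites <- generate_sites(6, seed = 2)
  ds <- simulate_peak(sites, deterministic_params(), seed = 2)
  expect_equal(exp(ds$latents$log_lem[, 2]), rep(1, 6), tolerance = 1e-9)
})

test_that("elevation coefficient forces the prescribed spring-autumn log change", {
  sites <- generate_sites(10, seed = 4)
  se <- scale_elevation(sites$elevation_m)$scaled
  p <- deterministic_params(beta_elev = c(0, 1), beta_dlem = c(0, 1))
  ds <- simulate_peak(sites, p, seed = 4)
  change <- ds$latents$log_lem[, 3] - ds$latents$log_lem[, 2]
  expect_equal(change, se, tolerance = 1e-9)
})

test_that("counts match Poisson moments for a fixed latent abundance", {
  # lambda pinned at 2 in every season: mean count within 3 MC SEs
  sites <- generate_sites(2000, seed = 6)
  p <- deterministic_params(beta0 = c(spring = log(2), autumn = log(2)),
                            init_mu_lem = log(2),
                            vole_mu = rep(log(2), 3))
  ds <- simulate_peak(sites, p, seed = 6)
  se3 <- 3 * sqrt(2 / 2000)
  for (k in 1:3) {
    cnt <- ds$data$count[ds$data$species == "lemming" & ds$data$season == k]
    expect_lt(abs(mean(cnt) - 2), se3)
    expect_lt(abs(var(cnt) - 2), 3 * sqrt(2 * (1 + 2 * 2) / 2000) + 0.05)
  }
})

test_that("extreme parameters produce a diagnostic naming site and season", {
  sites <- generate_sites(3, seed = 1)
  p <- default_peak_parameters()
  p$beta_dlem["spring"] <- 1e308  # overflow in the linear predictor
  expect_error(simulate_peak(sites, p, seed = 1),
               "non-finite latent.*site.*season")
})

test_that("transfer scenario shifts only the spring coefficients and is seeded", {
  sites <- generate_sites(15, seed = 11)
  p1 <- default_peak_parameters()
  shift <- c(beta_elev = -0.979, beta_dvole = -0.1)
  s1 <- make_transfer_scenario(sites, p1, shift, seed = 21)
  s2 <- make_transfer_scenario(sites, p1, shift, seed = 21)
  expect_identical(s1$peak1$data, s2$peak1$data)
  expect_identical(s1$peak2$data, s2$peak2$data)
  p2 <- s1$params_peak2
  expect_equal(unname(p2$beta_elev["spring"]), 0.845 - 0.979)
  expect_equal(unname(p2$beta_dvole["spring"]), 0.267 - 0.1)
  expect_identical(p2$beta_elev[["autumn"]], p1$beta_elev[["autumn"]])
  expect_identical(p2$beta0, p1$beta0)
  expect_error(make_transfer_scenario(sites, p1, c(gamma = 1), seed = 1),
               "spring_shift")
})

test_that("with zero shift the two peaks agree within sampling error", {
  sites <- generate_sites(400, seed = 31)
  scen <- make_transfer_scenario(sites, default_peak_parameters(),
                                 spring_shift = numeric(0), seed = 32)
  for (k in 1:3) for (sp in c("lemming", "vole")) {
    c1 <- scen$peak1$data$count[scen$peak1$data$season == k &
                                  scen$peak1$data$species == sp]
    c2 <- scen$peak2$data$count[scen$peak2$data$season == k &
                                  scen$peak2$data$species == sp]
    se_diff <- sqrt(var(c1) / length(c1) + var(c2) / length(c2))
    expect_lt(abs(mean(c1) - mean(c2)), 4 * se_diff)
  }
})
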