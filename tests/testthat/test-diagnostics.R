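test_that("R-hat follows the Gelman-Rubin formula in limiting cases", {
  n <- 100
  ch <- rnorm(n)
  # zero between-chain variance: R-hat = sqrt((n-1)/n) < 1
  expect_equal(compute_rhat(cbind(ch, ch)), sqrt((n - 1) / n))
  # grossly separated chains
  expect_gt(compute_rhat(cbind(rnorm(n, 0), rnorm(n, 100))), 10)
  expect_error(compute_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(compute_rhat(matrix(rnorm(6), ncol = 2)), "length >= 4")
})

test_that("R-hat is near 1 for same-distribution chains and tracks coda", {
  set.seed(123)
  x <- matrix(rnorm(20000), ncol = 2)
  r <- compute_rhat(x)
  expect_lt(r, 1.01)
  ml <- coda::mcmc.list(coda::mcmc(x[, 1, drop = FALSE]),
                        coda::mcmc(x[, 2, drop = FALSE]))
  r_coda <- unname(coda::gelman.diag(ml, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[1, 1])
  expect_equal(r, r_coda, tolerance = 0.01)
})

test_that("posterior summaries match constant draws and a sort oracle", {
  const <- coda::mcmc.list(coda::mcmc(matrix(3.5, 100, 1,
                                             dimnames = list(NULL, "a"))),
                           coda::mcmc(matrix(3.5, 100, 1,
                                             dimnames = list(NULL, "a"))))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 3.5)
  expect_equal(s$ci_lower, 3.5)
  expect_equal(s$ci_upper, 3.5)

  set.seed(7)
  d <- rnorm(1000)
  ml <- coda::mcmc.list(coda::mcmc(matrix(d[1:500], ncol = 1,
                                          dimnames = list(NULL, "b"))),
                        coda::mcmc(matrix(d[501:1000], ncol = 1,
                                          dimnames = list(NULL, "b"))))
  s <- summarize_posterior(ml)
  # brute-force quantile: sort, linear interpolation between order statistics
  hand_quantile <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(s$ci_lower, hand_quantile(d, 0.025), tolerance = 1e-12)
  expect_equal(s$ci_upper, hand_quantile(d, 0.975), tolerance = 1e-12)
  expect_equal(s$mean, mean(d))
  expect_error(summarize_posterior(coda::mcmc.list(coda::mcmc(
    matrix(numeric(0), 0, 1)))), "no posterior draws")
})

test_that("intra-specific density dependence is reported as beta_dlem - 1", {
  f <- tiny_fit1()
  tab <- coefficient_table(f)
  s <- summarize_posterior(f)
  for (seas in c(spring = 1L, autumn = 2L)) {
    raw <- s[s$parameter == sprintf("beta_dlem[%d]", seas), ]
    rep_ <- tab[tab$term == "beta_dlem_minus1" &
                  tab$season == names(which(c(spring = 1L, autumn = 2L) == seas)), ]
    expect_equal(rep_$mean, raw$mean - 1, tolerance = 1e-12)
    expect_equal(rep_$ci_lower, raw$ci_lower - 1, tolerance = 1e-12)
    expect_equal(rep_$ci_upper, raw$ci_upper - 1, tolerance = 1e-12)
  }
  # draws pinned near zero report the transform's target format
  d <- matrix(0.001, 50, 1, dimnames = list(NULL, "x"))
  expect_equal(mean(d) - 1, -0.999)
})

test_that("spatial CV is sd/mean and guards the degenerate mean", {
  expect_equal(spatial_cv(3.41, 2.61), 2.61 / 3.41)
  expect_equal(spatial_cv(2, 0), 0)
  expect_error(spatial_cv(0, 1), "undefined")
  expect_error(spatial_cv(1, -0.1), ">= 0")
})

test_that("abundance table summarises site-level posterior-mean abundances", {
  f <- tiny_fit1()
  tab <- abundance_table(f)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$species, c("lemming", "vole"))
  expect_equal(tab$cv, tab$sd_abundance / tab$mean_abundance)
  expect_true(all(tab$mean_abundance > 0))
  expect_true(all(tab$n_sites == 25))
  # posterior-mean abundances should track the observed mean counts
  for (k in 1:3) {
    obs <- mean(tiny_scenario()$peak1$data$count[
      tiny_scenario()$peak1$data$species == "vole" &
        tiny_scenario()$peak1$data$season == k])
    est <- tab$mean_abundance[tab$species == "vole" & tab$season == k]
    expect_lt(abs(est - obs), 0.5 + 0.3 * obs)
  }
})
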