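test_that("single-detect augmentation appends the detection limit once", {
  d1 <- censored_residue_data("LF", 0.003, 2041, 0.002)
  a1 <- augment_single_detect(d1)
  expect_equal(a1$values, c(0.003, 0.002))
  expect_equal(a1$n_obs, 2L)
  expect_equal(a1$n_cen, 2041L)

  d2 <- censored_residue_data("X", c(0.01, 0.02), 10)
  expect_identical(augment_single_detect(d2), d2)

  d3 <- censored_residue_data("Y", 0.002, 0)
  a3 <- augment_single_detect(d3)
  expect_equal(a3$values, c(0.002, 0.002))
  expect_equal(a3$n_cen, 0L)
})

test_that("dataset constructor enforces its invariants", {
  expect_error(censored_residue_data("A", numeric(0), 5), "at least one")
  expect_error(censored_residue_data("A", c(0.1, -0.2), 5), "positive")
  expect_error(censored_residue_data("A", 0.1, -1), "nonnegative")
})

test_that("with no censoring the posterior matches sample geometric moments", {
  set.seed(31)
  y <- rlnorm(500, log(0.01), log(2))
  ds <- censored_residue_data("U", y, 0)
  fit <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 3, n_iter = 6000))
  expect_true(fit$converged)
  expect_equal(median(fit$gm_draws), exp(mean(log(y))), tolerance = 0.03)
  expect_equal(median(fit$gsd_draws), exp(sd(log(y))), tolerance = 0.05)
})

test_that("marginalized and latent likelihoods agree on a small dataset", {
  set.seed(5)
  y <- rlnorm(60, log(0.01), log(2.5))
  dl <- unname(quantile(y, 0.5))
  ds <- censored_residue_data("T", y[y >= dl], sum(y < dl), dl)
  fm <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 11, n_iter = 8000),
                               likelihood_mode = "marginalized")
  fl <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 12, n_iter = 15000),
                               likelihood_mode = "latent")
  expect_true(fm$converged)
  expect_equal(median(fl$gm_draws), median(fm$gm_draws), tolerance = 0.10)
  expect_equal(median(fl$gsd_draws), median(fm$gsd_draws), tolerance = 0.10)
  expect_false(is.null(fl$ycen_draws))
  # latent non-detects always lie below the reporting limit
  expect_true(all(fl$ycen_draws <= max(fl$rl_draws)))
})

test_that("posterior-predictive censoring fraction matches the data", {
  tr <- rv_truth()
  ds <- generate_residue_dataset(1760, tr$gm, tr$gsd, seed = 42)
  fit <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 7, n_iter = 6000))
  expect_true(fit$converged)
  pp <- mean(sample_posterior_residues(fit, 2e5, seed = 9) <
               ds$detection_limit)
  emp <- ds$n_cen / (ds$n_cen + ds$n_obs)
  expect_lt(abs(pp - emp), 0.02)
})

test_that("arithmetic moment draws satisfy the lognormal identities", {
  tr <- rv_truth()
  ds <- generate_residue_dataset(800, tr$gm, tr$gsd, seed = 2)
  fit <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 8))
  i <- seq(1, length(fit$gm_draws), length.out = 25)
  s <- log(fit$gsd_draws[i])
  expect_equal(fit$gm_draws[i] * exp(s^2 / 2) * sqrt(expm1(s^2)),
               fit$gm_draws[i] * exp(s^2 / 2) *
                 sqrt(exp(s^2) - 1), tolerance = 1e-12)
  # mean_est/std_est are averages of per-draw moments
  sall <- log(fit$gsd_draws)
  expect_equal(fit$mean_est, mean(fit$gm_draws * exp(sall^2 / 2)),
               tolerance = 1e-12)
})

test_that("sampling from a fit honors moments, errors when unconverged", {
  tr <- rv_truth()
  ds <- generate_residue_dataset(800, tr$gm, tr$gsd, seed = 3)
  fit <- fit_censored_lognormal(ds, mcmc = fast_mcmc(seed = 4))
  expect_length(sample_posterior_residues(fit, 0), 0)
  x <- sample_posterior_residues(fit, 1e6, seed = 10)
  expect_true(all(x > 0))
  expect_equal(mean(x), fit$mean_est, tolerance = 0.03)
  expect_equal(sd(x), fit$std_est, tolerance = 0.10)
  bad <- fit
  bad$converged <- FALSE
  expect_error(sample_posterior_residues(bad, 5), "not converged")
  # simulate() S3 method routes to the same sampler
  expect_identical(simulate(fit, 50, seed = 123),
                   sample_posterior_residues(fit, 50, seed = 123))
})

test_that("residue CSV round trip preserves detects and censored counts", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(category = c("A", "A", "A", "B"),
                   value = c(0.01, NA, NA, 0.05),
                   censored = c(0L, 1L, 1L, 0L),
                   detection_limit = 0.002)
  write.csv(df, tmp, row.names = FALSE)
  ds <- read_residue_csv(tmp)
  expect_named(ds, c("A", "B"))
  expect_equal(ds$A$values, 0.01)
  expect_equal(ds$A$n_cen, 2L)
  expect_equal(ds$B$n_cen, 0L)
  unlink(tmp)
})
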