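test_that("model probabilities match closed-form special cases", {
  ql <- dichotomous_model_spec("QuantalLinear")
  expect_equal(model_probability(ql, c(g = 0.1, b = 0), c(0, 1, 10)),
               rep(0.1, 3))
  lg <- dichotomous_model_spec("Logistic")
  expect_equal(model_probability(lg, c(a = 0, b = 0), c(0, 2, 7)),
               rep(0.5, 3))
  ms <- dichotomous_model_spec("Multistage2")
  expect_equal(model_probability(ms, c(g = 0, b1 = 1, b2 = 0), log(2)), 0.5,
               tolerance = 1e-12)
  # background returned at dose zero for log-dose models
  dh <- dichotomous_model_spec("DichotomousHill")
  expect_equal(model_probability(dh, c(g = 0.07, v = 0.5, a = 1, b = 2), 0),
               0.07)
  expect_error(model_probability(ql, c(g = 1.5, b = 0), 1), "bounds")
})

test_that("closed-form benchmark doses match hand-derived values", {
  ql <- dichotomous_model_spec("QuantalLinear")
  expect_equal(bmd_from_params(ql, c(g = 0.3, b = 1)), -log(0.9),
               tolerance = 1e-12)
  expect_equal(bmd_from_params(ql, c(g = 0.2, b = 2)), -log(0.9) / 2,
               tolerance = 1e-12)
  wb <- dichotomous_model_spec("Weibull")
  expect_equal(bmd_from_params(wb, c(g = 0, b = 1, k = 2)), sqrt(-log(0.9)),
               tolerance = 1e-12)
  # flat curves have no benchmark dose
  expect_true(is.na(bmd_from_params(ql, c(g = 0.1, b = 0))))
  dh <- dichotomous_model_spec("DichotomousHill")
  expect_true(is.na(bmd_from_params(dh, c(g = 0, v = 0.05, a = 0, b = 1))))
})

test_that("closed-form BMD agrees with the numeric root-finder everywhere", {
  set.seed(77)
  specs <- lapply(dichotomous_models(), dichotomous_model_spec)
  names(specs) <- dichotomous_models()
  draw_params <- function(spec) {
    repeat {
      p <- sapply(seq_along(spec$par_names), function(j) switch(
        spec$par_names[j],
        g = runif(1, 0, 0.5), v = runif(1, 0.15, 1),
        a = runif(1, -3, 1), b = runif(1, 0.1, 5),
        b1 = runif(1, 0.05, 3), b2 = runif(1, 0, 3),
        k = runif(1, 0.3, 4)))
      names(p) <- spec$par_names
      bmd <- bmd_from_params(spec, p)
      if (is.finite(bmd) && bmd > 1e-8 && bmd < 1e6) return(p)
    }
  }
  for (nm in names(specs)) {
    for (i in 1:30) {
      p <- draw_params(specs[[nm]])
      closed <- bmd_from_params(specs[[nm]], p, method = "closed")
      numeric <- bmd_from_params(specs[[nm]], p, method = "numeric")
      expect_equal(closed, numeric, tolerance = 1e-8,
                   label = paste(nm, "closed"), expected.label = "numeric")
      # inversion identity: extra risk at the BMD equals the BMR
      p0 <- model_probability(specs[[nm]], p, 0)
      er <- (model_probability(specs[[nm]], p, closed) - p0) / (1 - p0)
      expect_equal(er, 0.10, tolerance = 1e-8)
    }
  }
})

test_that("parameter recovery for quantal-linear data with large groups", {
  spec <- dichotomous_model_spec("QuantalLinear")
  dr <- generate_dose_response(spec, c(g = 0.05, b = 0.5),
                               doses = c(0, 0.25, 0.5, 1, 2),
                               n_per_dose = 1000, seed = 21)
  fit <- fit_dichotomous_model(dr, spec,
                               mcmc = mcmc_settings(3, 8000, seed = 5))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["b"]), 0.5, tolerance = 0.1)
  # background posterior covers the empirical control rate
  ctrl <- dr$incidence[1] / dr$n[1]
  expect_true(quantile(fit$draws[, "g"], 0.02) <= ctrl + 0.02)
  expect_true(quantile(fit$draws[, "g"], 0.98) >= ctrl - 0.02)
})

test_that("fitted curves are non-decreasing in dose over the data range", {
  dr <- fipronil_convulsion_data()
  fit <- fit_dichotomous_model(dr, "Weibull",
                               mcmc = mcmc_settings(3, 6000, seed = 6))
  grid <- seq(0, max(dr$doses), length.out = 20)
  i <- seq(1, nrow(fit$draws), length.out = 50)
  for (j in i) {
    pr <- model_probability(fit$spec, fit$draws[j, ], grid)
    expect_true(all(diff(pr) >= -1e-12))
  }
})

test_that("model weights: trivial cases and permutation invariance", {
  dr <- generate_dose_response("QuantalLinear", c(g = 0.05, b = 0.5),
                               doses = c(0, 0.5, 1, 2, 4),
                               n_per_dose = 50, seed = 3)
  f1 <- fit_dichotomous_model(dr, "QuantalLinear",
                              mcmc = mcmc_settings(3, 5000, seed = 8))
  f2 <- fit_dichotomous_model(dr, "QuantalLinear",
                              mcmc = mcmc_settings(3, 5000, seed = 8))
  expect_equal(unname(compute_model_weights(list(f1))), 1)
  w <- compute_model_weights(list(f1, f2))
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-9)
  f3 <- fit_dichotomous_model(dr, "Logistic",
                              mcmc = mcmc_settings(3, 5000, seed = 9))
  w12 <- compute_model_weights(list(f1, f3))
  w21 <- compute_model_weights(list(f3, f1))
  expect_equal(unname(w12), unname(rev(w21)), tolerance = 1e-12)
  expect_equal(sum(w12), 1, tolerance = 1e-12)
})

test_that("model averaging is a faithful mixture", {
  # two pseudo-fits with disjoint BMD supports
  mk <- function(draws) structure(list(model = "m", bmd_draws = draws,
                                       bmr = 0.1), class = "dichotomous_fit")
  fits <- list(mk(runif(5000, 1, 2)), mk(runif(5000, 10, 20)))
  avg <- model_average_bmd(fits, weights = c(0.3, 0.7), n_draws = 50000,
                           seed = 11)
  expect_equal(mean(avg$draws < 5), 0.3, tolerance = 0.01)
  one <- model_average_bmd(fits, weights = c(1, 0), n_draws = 2000, seed = 2)
  expect_true(all(one$draws <= 2))
  expect_error(model_average_bmd(fits, weights = c(0.5, 0.4)), "simplex")
})

test_that("dose-response data constructor enforces invariants", {
  expect_error(dose_response_data(c(0, 1, 1), c(10, 10, 10), c(0, 1, 2)),
               "strictly increasing")
  expect_error(dose_response_data(c(1, 2), c(10, 10), c(0, 1)), "first dose")
  expect_error(dose_response_data(c(0, 1), c(10, 10), c(0, 11)),
               "incidence")
})
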