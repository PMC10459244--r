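# shared fixtures and settings for the test suite

# fast sampler settings for unit tests (small posteriors converge quickly)
fast_mcmc <- function(seed = 1L, n_iter = 4000L, n_chains = 4L) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, seed = seed)
}

# an RV-like generating truth: 97.5% censoring at DL 0.002 with a geometric
# SD close to the detected-sample value (~4)
rv_truth <- function(gsd = 4) {
  list(gm = 0.002 * gsd^(-stats::qnorm(0.975)), gsd = gsd)
}

# memoized full dose-response chain shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_chain <- function() {
  if (is.null(.acceptance_cache$fits)) {
    .acceptance_cache$fits <- fit_dichotomous_models(
      fipronil_convulsion_data(),
      mcmc = mcmc_settings(n_chains = 3L, n_iter = 50000L, seed = 76316L))
    .acceptance_cache$weights <- compute_model_weights(.acceptance_cache$fits)
    .acceptance_cache$averaged <- model_average_bmd(
      .acceptance_cache$fits, .acceptance_cache$weights,
      n_draws = 100000L, seed = 20210L)
    .acceptance_cache$hdmi <- derive_prfd(.acceptance_cache$averaged,
                                          seed = 20211L)
  }
  as.list(.acceptance_cache)
}

# small two-stratum demographics table
toy_strata <- function() {
  demographic_strata(data.frame(
    age = c(30, 30), sex = c("male", "female"),
    population_count = c(500, 500), bw_mean = c(70, 58),
    bw_sd = c(10, 9)))
}
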