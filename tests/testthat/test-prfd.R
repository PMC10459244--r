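test_that("allometric conversion matches hand arithmetic in degenerate cases", {
  # exponent fixed at 1 and unit interspecies factor: no scaling at all
  p1 <- interspecies_params(allometric_mean = 1, allometric_sd = 0,
                            tktd_gsd = 1 + 1e-12)
  hd <- animal_to_human_hd50(c(1, 5, 13.48), p1, seed = 1)
  expect_equal(hd, c(1, 5, 13.48), tolerance = 1e-6)
  # exponent fixed at 0.7: the published-scale factor (0.35/70)^0.3
  p2 <- interspecies_params(allometric_sd = 0, tktd_gsd = 1 + 1e-12)
  hd2 <- animal_to_human_hd50(13.48, p2, seed = 1)
  expect_equal(hd2, 13.48 * (0.35 / 70)^0.3, tolerance = 1e-6)
  expect_equal(hd2, 2.75, tolerance = 0.01)
})

test_that("median HD50 is insensitive to the interspecies GSD", {
  bmd <- rlnorm(200000, log(13.48), 0.3)
  m1 <- median(animal_to_human_hd50(bmd, interspecies_params(tktd_gsd = 1.95),
                                    seed = 3))
  m2 <- median(animal_to_human_hd50(bmd, interspecies_params(tktd_gsd = 3),
                                    seed = 3))
  expect_equal(m1, m2, tolerance = 0.02)
})

test_that("human-variability conversion: point mass and median preservation", {
  ip <- intraspecies_params(log10_factor_gsd = 1 + 1e-12)
  hdmi <- hd50_to_hdmi(c(2.80, 5.6), ip, seed = 2)
  expect_equal(hdmi, c(2.80, 5.6) / 10^0.746, tolerance = 1e-4)
  # widening the factor GSD leaves the HDMI median nearly unchanged
  h <- rep(2.80, 200000)
  med1 <- median(hd50_to_hdmi(h, intraspecies_params(), seed = 5))
  med2 <- median(hd50_to_hdmi(h, intraspecies_params(log10_factor_gsd = 2.2),
                              seed = 5))
  expect_equal(med1, med2, tolerance = 0.03)
})

test_that("pRfD extraction is the protection-direction percentile", {
  expect_equal(prfd_from_hdmi(rep(0.5, 100)), 0.5)
  x <- 1:1000 / 100
  expect_equal(prfd_from_hdmi(x, coverage = 0.5), median(x))
  expect_equal(prfd_from_hdmi(x), unname(quantile(x, 0.05)))
  expect_error(prfd_from_hdmi(numeric(0)), "nonempty")
})

test_that("uncertainty decomposition: exact analytic shares", {
  set.seed(9)
  a <- rnorm(5000)
  expect_equal(unname(uncertainty_decomposition(list(x = a))), 1)
  two <- uncertainty_decomposition(list(x = a, y = a))
  expect_equal(unname(two), c(0.5, 0.5), tolerance = 1e-9)
  b <- a * 2
  shares <- uncertainty_decomposition(list(x = a, y = b))
  expect_equal(unname(shares), c(0.2, 0.8), tolerance = 1e-9)
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  expect_error(uncertainty_decomposition(list(x = rep(1, 10))), "zero")
})

test_that("the full conversion chain is scale-equivariant and monotone", {
  set.seed(12)
  bmd <- rlnorm(50000, log(10), 0.4)
  r1 <- derive_prfd(bmd, seed = 7)
  r2 <- derive_prfd(bmd * 3, seed = 7)
  expect_equal(r2$prfd, 3 * r1$prfd, tolerance = 1e-9)
  expect_equal(median(r2$hd50_draws), 3 * median(r1$hd50_draws),
               tolerance = 1e-9)
  expect_equal(median(r2$hdmi_draws), 3 * median(r1$hdmi_draws),
               tolerance = 1e-9)
  # protection-direction ordering
  expect_lt(r1$prfd, median(r1$hdmi_draws))
  expect_lt(median(r1$hdmi_draws), median(r1$hd50_draws))
  # percentile table decreases down the protection direction
  expect_true(all(diff(r1$percentile_table[, "HDMI"]) < 0))
  expect_equal(sum(r1$decomposition), 1, tolerance = 1e-9)
})

test_that("degenerate uncertainty reduces the chain to hand arithmetic", {
  inter <- interspecies_params(allometric_sd = 0, tktd_gsd = 1 + 1e-12)
  intra <- intraspecies_params(log10_factor_gsd = 1 + 1e-12)
  r <- derive_prfd(rep(13.48, 1000), inter, intra, seed = 1)
  hd50 <- 13.48 * (0.35 / 70)^0.3
  expect_equal(median(r$hd50_draws), hd50, tolerance = 1e-4)
  expect_equal(median(r$hdmi_draws), hd50 / 10^0.746, tolerance = 1e-3)
  expect_equal(r$prfd, median(r$hdmi_draws), tolerance = 1e-3)
})
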