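test_that("population allocation: proportional, floored, exact totals", {
  st <- demographic_strata(data.frame(
    age = c(1, 2), sex = "male", population_count = c(1, 1),
    bw_mean = 60, bw_sd = 5))
  a <- allocate_population(st, 100, 1)
  expect_equal(unname(table(a$stratum)), c(50L, 50L), ignore_attr = TRUE)

  st2 <- demographic_strata(data.frame(
    age = c(1, 2), sex = "male", population_count = c(999, 1),
    bw_mean = 60, bw_sd = 5))
  a2 <- allocate_population(st2, 1000, 10)
  expect_equal(as.integer(table(a2$stratum)), c(990L, 10L))

  # full-scale design: 101 ages x 2 sexes
  pop <- generate_population_inputs(seed = 1)
  a3 <- allocate_population(pop$demographics, 200000L, 10L)
  counts <- table(a3$stratum)
  expect_equal(sum(counts), 200000L)
  expect_length(counts, 202L)
  expect_true(all(counts >= 10L))
  expect_error(allocate_population(st, 1, 10), "too small")
})

test_that("aggregate exposure arithmetic and homogeneity", {
  expect_equal(aggregate_exposure(258, 1.69, 74.1), 258 * 1.69 / 74100)
  expect_equal(aggregate_exposure(258, 1.69, 74.1), 5.884e-3, tolerance = 1e-4)
  expect_equal(aggregate_exposure(c(10, 20), c(0, 0), 60), 0)
  e1 <- aggregate_exposure(c(10, 20), c(0.1, 0.2), 60)
  expect_equal(aggregate_exposure(c(10, 20), c(0.1, 0.2), 120), e1 / 2)
  expect_equal(aggregate_exposure(c(20, 40), c(0.1, 0.2), 60), 2 * e1)
  expect_equal(aggregate_exposure(c(10, 20), c(0.2, 0.4), 60), 2 * e1)
  m <- matrix(c(10, 20, 30, 40), 2)
  r <- c(0.1, 0.2)
  expect_equal(aggregate_exposure(m, matrix(r, 2, 2, byrow = TRUE), c(60, 60)),
               c((10 * 0.1 + 30 * 0.2) / 60000, (20 * 0.1 + 40 * 0.2) / 60000))
  expect_error(aggregate_exposure(-1, 0.1, 60), "negative")
  expect_error(aggregate_exposure(1, 0.1, 0), "positive")
})

test_that("age groups partition 0-100 without overlap", {
  g <- age_group(0:100)
  expect_false(anyNA(g))
  expect_equal(as.vector(table(g)),
               c(3L, 3L, 6L, 4L, 3L, 47L, 35L))
})

test_that("degenerate draws reproduce the deterministic substitution estimate", {
  st <- toy_strata()
  st$bw_sd <- 0
  pop <- allocate_population(st, 20, 1)
  fits <- list(A = list(mean_est = 0.001, std_est = 0),
               B = list(mean_est = 0.002, std_est = 0))
  intakes <- data.frame(category = c("A", "B"), scenario = "LB",
                        intake_mean = c(100, 50), intake_sd = 0)
  ex <- run_exposure_scenario(pop, st, fits, intakes, "LB", seed = 1)
  expected <- (100 * 0.001 + 50 * 0.002) / (st$bw_mean[pop$stratum] * 1000)
  expect_equal(ex$individuals$exposure, expected, tolerance = 1e-12)
})

test_that("scenario runs partition the population in all summaries", {
  pop_in <- generate_population_inputs(seed = 2)
  st <- pop_in$demographics
  pop <- allocate_population(st, 3000, 1)
  cats <- fipronil_residue_summary()$category
  fits <- setNames(lapply(cats, function(cc)
    list(mean_est = 2e-4, std_est = 4e-4)), cats)
  lb <- run_exposure_scenario(pop, st, fits, pop_in$intakes, "LB", seed = 3)
  ub <- run_exposure_scenario(pop, st, fits, pop_in$intakes, "UB", seed = 3)
  expect_true(all(lb$individuals$exposure >= 0))
  byg <- lb$by_age_group
  expect_equal(sum(byg$n[byg$group != "all"]), 3000)
  expect_equal(sum(lb$by_sex$n), 3000)
  # consumer-only intake means dominate the general-population means
  expect_gt(mean(ub$individuals$exposure), mean(lb$individuals$exposure))
  expect_error(run_exposure_scenario(pop, st, fits[-1], pop_in$intakes, "LB"),
               "missing residue fit")
})

test_that("exposure is reproducible under a fixed seed", {
  st <- toy_strata()
  pop <- allocate_population(st, 50, 1)
  fits <- list(A = list(mean_est = 1e-3, std_est = 2e-3))
  intakes <- data.frame(category = "A", scenario = "LB",
                        intake_mean = 40, intake_sd = 20)
  e1 <- run_exposure_scenario(pop, st, fits, intakes, "LB", seed = 9)
  e2 <- run_exposure_scenario(pop, st, fits, intakes, "LB", seed = 9)
  expect_identical(e1$individuals$exposure, e2$individuals$exposure)
})
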