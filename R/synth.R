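#' Published fipronil residue surveillance summary
#'
#' Per-category summary of the Taiwanese fipronil residue surveillance data
#' (2014--2023): total samples, number of detects, and the mean and standard
#' deviation of the detected concentrations (ppm). The detection limit is
#' 0.002 ppm throughout. Categories: large berry fruit (LF), small berry fruit
#' (SF), citrus fruit (CF), cabbage (CB), small leafy vegetables (SV), fruit
#' vegetables (FV), legume vegetables (LV), root and stem vegetables (RV),
#' dry beans (DB), chicken egg (CG), spice (SP).
#'
#' @return data.frame with columns `category`, `n_total`, `n_detect`,
#'   `detect_mean`, `detect_sd`, `detection_limit`.
#' @export
fipronil_residue_summary <- function() {
  data.frame(
    category = c("LF", "SF", "CF", "CB", "SV", "FV", "LV", "RV", "DB", "CG", "SP"),
    n_total = c(2042L, 923L, 1046L, 1265L, 6974L, 2556L, 1867L, 1760L, 229L, 40L, 858L),
    n_detect = c(1L, 1L, 1L, 3L, 42L, 9L, 8L, 44L, 5L, 2L, 4L),
    detect_mean = c(0.003, 0.002, 0.014, 0.229, 0.115, 0.018, 0.010, 0.013,
                    0.006, 0.014, 0.051),
    detect_sd = c(NA, NA, NA, 0.138, 0.328, 0.025, 0.005, 0.013, 0.004,
                  0.011, 0.027),
    detection_limit = 0.002)
}

#' Published convulsion dose-response data (male SD rats)
#'
#' Chronic-study incidences of convulsions used as the point of departure for
#' the benchmark-dose analysis.
#'
#' @return a [dose_response_data()] object: doses 0, 0.019, 0.059, 1.27,
#'   12.68 mg/kg/day with incidences 0/50, 0/50, 3/50, 1/50, 5/50.
#' @export
fipronil_convulsion_data <- function() {
  dose_response_data(doses = c(0, 0.019, 0.059, 1.27, 12.68),
                     n = rep(50L, 5L),
                     incidence = c(0L, 0L, 3L, 1L, 5L))
}

#' Calibrate lognormal parameters to a residue summary row
#'
#' Finds `(gm, gsd)` of a lognormal concentration distribution such that the
#' censoring probability `P(Y < DL)` equals `1 - n_detect / n_total` and the
#' conditional mean above the DL equals `detect_mean`, solved by 1-D root
#' finding in `sdlog` (the censoring constraint pins `meanlog` given `sdlog`).
#' With zero censoring the constraint degenerates and the unconditional
#' moments are matched instead. The achieved conditional SD is returned as a
#' diagnostic.
#'
#' @param spec one row of [fipronil_residue_summary()] (or any list with
#'   fields `n_total`, `n_detect`, `detect_mean`, `detect_sd`,
#'   `detection_limit`).
#' @param tol relative tolerance of the root solve.
#' @return list with `gm`, `gsd`, `meanlog`, `sdlog`, `censor_prob`,
#'   `cond_mean`, `cond_sd`.
#' @export
calibrate_gm_gsd_to_spec <- function(spec, tol = 1e-9) {
  stopifnot(spec$n_detect >= 1, spec$n_detect <= spec$n_total,
            spec$detect_mean > 0, spec$detection_limit > 0)
  if (spec$n_detect >= 2 && (is.na(spec$detect_sd) || spec$detect_sd <= 0))
    stop("detect_sd must be positive when n_detect >= 2")
  dl <- spec$detection_limit
  cens <- 1 - spec$n_detect / spec$n_total
  if (cens <= 0) {
    sd <- if (is.na(spec$detect_sd)) 0 else spec$detect_sd
    p <- lognormal_params_from_moments(spec$detect_mean, sd)
    mu <- p$meanlog; s <- p$sdlog
  } else {
    zc <- stats::qnorm(cens)
    cond_mean <- function(s) {
      mu <- log(dl) - zc * s
      # E[Y | Y > DL] for lognormal(mu, s)
      exp(mu + s^2 / 2) * stats::pnorm((mu + s^2 - log(dl)) / s) / (1 - cens)
    }
    f <- function(s) cond_mean(s) - spec$detect_mean
    lo <- 1e-6; hi <- 1
    while (f(hi) < 0 && hi < 50) hi <- hi * 2
    if (f(hi) < 0) stop("infeasible residue summary: conditional mean not attainable")
    if (f(lo) > 0) stop("infeasible residue summary: detect_mean below the detection limit regime")
    s <- stats::uniroot(f, c(lo, hi), tol = tol)$root
    mu <- log(dl) - zc * s
  }
  # achieved conditional second moment above DL (diagnostic)
  cond_sd <- if (s == 0) 0 else {
    surv <- 1 - stats::plnorm(dl, mu, s)
    m1 <- exp(mu + s^2 / 2) * stats::pnorm((mu + s^2 - log(dl)) / s) / surv
    m2 <- exp(2 * mu + 2 * s^2) * stats::pnorm((mu + 2 * s^2 - log(dl)) / s) / surv
    sqrt(max(m2 - m1^2, 0))
  }
  list(gm = exp(mu), gsd = exp(s), meanlog = mu, sdlog = s,
       censor_prob = stats::plnorm(dl, mu, s),
       cond_mean = if (s == 0) spec$detect_mean else
         exp(mu + s^2 / 2) * stats::pnorm((mu + s^2 - log(dl)) / s) /
           (1 - stats::plnorm(dl, mu, s)),
       cond_sd = cond_sd)
}

#' Generate a synthetic censored residue dataset
#'
#' Draws `n_total` concentrations from lognormal(`true_gm`, `true_gsd`) and
#' censors everything below the detection limit. The ground truth is attached
#' as attribute `"truth"` for parameter-recovery tests.
#'
#' @param n_total number of samples.
#' @param true_gm,true_gsd generating geometric mean (ppm) and geometric SD.
#' @param detection_limit ppm (default 0.002).
#' @param category label for the dataset.
#' @param seed integer seed.
#' @return a [censored_residue_data()] object (detects only; censored count in
#'   `n_cen`), with attribute `truth = list(gm, gsd, values)`.
#' @export
generate_residue_dataset <- function(n_total, true_gm, true_gsd,
                                     detection_limit = 0.002,
                                     category = "SYN", seed = 1L) {
  stopifnot(true_gm > 0, true_gsd >= 1, n_total >= 1)
  set.seed(seed)
  y <- if (true_gsd == 1) rep(true_gm, n_total) else
    stats::rlnorm(n_total, log(true_gm), log(true_gsd))
  det <- y[y >= detection_limit]
  n_cen <- sum(y < detection_limit)
  if (length(det) == 0L)
    det <- detection_limit  # fully censored draw: seed with one value at DL
  ds <- censored_residue_data(category, det, n_cen, detection_limit)
  attr(ds, "truth") <- list(gm = true_gm, gsd = true_gsd, values = y)
  ds
}

#' Generate synthetic demographic and intake tables
#'
#' Emulates the structure of national demographic registries, body-weight
#' surveys and food-consumption databases: 101 ages x 2 sexes with a smooth
#' age pyramid, a logistic body-weight growth curve (birth ~3.3 kg to adult
#' means of 70 kg for males / 58 kg for females, SD 15% of the mean), and
#' per-category daily intakes for a general-population (LB) and a
#' consumer-only (UB) scenario with UB means always at least the LB means.
#'
#' @param categories category codes (default the 11 surveillance categories).
#' @param seed integer seed.
#' @param intake_base named or unnamed vector of LB mean intakes in g/day; a
#'   default spanning 5--80 g/day is used when omitted.
#' @return list with data.frames `demographics` (age, sex,
#'   population_count, bw_mean, bw_sd) and `intakes` (category, scenario,
#'   intake_mean, intake_sd).
#' @export
generate_population_inputs <- function(categories = fipronil_residue_summary()$category,
                                       seed = 1L, intake_base = NULL) {
  set.seed(seed)
  ages <- 0:100
  # smooth age pyramid: plateau through adulthood, decline in old age
  pyramid <- 1e5 * exp(-pmax(ages - 60, 0)^2 / (2 * 22^2)) *
    (0.75 + 0.25 * exp(-(ages - 40)^2 / (2 * 25^2)))
  adult_bw <- c(male = 70, female = 58)
  demo <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    bw <- 3.3 + (adult_bw[[sx]] - 3.3) / (1 + exp(-(ages - 12) / 3))
    data.frame(age = ages, sex = sx,
               population_count = round(pyramid * if (sx == "male") 0.494 else 0.506),
               bw_mean = bw, bw_sd = 0.15 * bw)
  }))
  k <- length(categories)
  if (is.null(intake_base)) {
    intake_base <- stats::runif(k, 5, 80)
  }
  lb <- data.frame(category = categories, scenario = "LB",
                   intake_mean = intake_base, intake_sd = 0.8 * intake_base)
  ub_mult <- stats::runif(k, 1.5, 4)
  ub <- data.frame(category = categories, scenario = "UB",
                   intake_mean = intake_base * ub_mult,
                   intake_sd = 0.8 * intake_base * ub_mult)
  list(demographics = demographic_strata(demo), intakes = rbind(lb, ub))
}

#' Generate synthetic dichotomous dose-response data
#'
#' Binomial sampling from a model curve, for parameter-recovery testing of the
#' dose-response fitters. The generating truth is attached as attribute
#' `"truth"`.
#'
#' @param spec a [dichotomous_model_spec()] or model name.
#' @param params admissible parameter vector.
#' @param doses dose levels (first must be 0).
#' @param n_per_dose animals per dose group (scalar or vector).
#' @param seed integer seed.
#' @return a [dose_response_data()] object.
#' @export
generate_dose_response <- function(spec, params, doses, n_per_dose, seed = 1L) {
  if (is.character(spec)) spec <- dichotomous_model_spec(spec)
  set.seed(seed)
  n <- rep_len(n_per_dose, length(doses))
  p <- vapply(doses, function(d) model_probability(spec, params, d), 1.0)
  dr <- dose_response_data(doses, n, stats::rbinom(length(doses), n, p))
  attr(dr, "truth") <- list(model = spec$name, params = params, p = p)
  dr
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits the four pipeline inputs as plain-text files: `residues.csv`
#' (long format, one row per sample), `demographics.csv`, `intakes.csv` and
#' `dose_response.csv`, plus `truth.json` recording every generating
#' parameter.
#'
#' @param dir output directory (created if needed).
#' @param residue_specs data.frame like [fipronil_residue_summary()]; each row
#'   is calibrated with [calibrate_gm_gsd_to_spec()] and sampled.
#' @param seed master seed.
#' @return invisibly, the named list of file paths.
#' @export
write_synthetic_bundle <- function(dir,
                                   residue_specs = fipronil_residue_summary(),
                                   seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- split(residue_specs, seq_len(nrow(residue_specs)))
  truth <- list()
  res <- do.call(rbind, lapply(rows, function(r) {
    cal <- calibrate_gm_gsd_to_spec(r)
    ds <- generate_residue_dataset(r$n_total, cal$gm, cal$gsd,
                                   r$detection_limit, r$category,
                                   seed = derive_seed(seed, r$category))
    truth[[r$category]] <<- list(gm = cal$gm, gsd = cal$gsd)
    data.frame(category = r$category,
               value = c(ds$values, rep(NA, ds$n_cen)),
               censored = c(rep(0L, ds$n_obs), rep(1L, ds$n_cen)),
               detection_limit = r$detection_limit)
  }))
  pop <- generate_population_inputs(residue_specs$category,
                                    seed = derive_seed(seed, "population"))
  dr <- fipronil_convulsion_data()
  paths <- list(residues = file.path(dir, "residues.csv"),
                demographics = file.path(dir, "demographics.csv"),
                intakes = file.path(dir, "intakes.csv"),
                dose_response = file.path(dir, "dose_response.csv"),
                truth = file.path(dir, "truth.json"))
  utils::write.csv(res, paths$residues, row.names = FALSE)
  utils::write.csv(pop$demographics, paths$demographics, row.names = FALSE)
  utils::write.csv(pop$intakes, paths$intakes, row.names = FALSE)
  utils::write.csv(data.frame(dose = dr$doses, n = dr$n,
                              incidence = dr$incidence),
                   paths$dose_response, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, residues = truth), paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
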