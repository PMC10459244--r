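#' Assemble a pipeline run configuration
#'
#' @param residues,demographics,intakes,dose_response paths to the four input
#'   tables (CSV; see the schemas in [read_residue_csv()],
#'   [demographic_strata()], [run_exposure_scenario()] and
#'   [dose_response_data()]).
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param scenarios intake scenarios to run.
#' @param n_population simulated population size.
#' @param min_per_stratum minimum individuals per populated stratum.
#' @param residue_mcmc,bmd_mcmc [mcmc_settings()] for the two MCMC stages
#'   (the seeds in these are replaced by stage-derived seeds).
#' @param inter,intra conversion parameter objects.
#' @param noael,safety_factor deterministic reference-dose inputs (mg/kg/day
#'   and unitless).
#' @param n_averaged_draws size of the model-averaged BMD sample.
#' @return an object of class `run_config`.
#' @export
run_config <- function(residues, demographics, intakes, dose_response,
                       out_dir, seed = 1L, scenarios = c("LB", "UB"),
                       n_population = 200000L, min_per_stratum = 10L,
                       residue_mcmc = mcmc_settings(n_chains = 4L, n_iter = 25000L),
                       bmd_mcmc = mcmc_settings(n_chains = 3L, n_iter = 50000L),
                       inter = interspecies_params(),
                       intra = intraspecies_params(),
                       noael = 0.019, safety_factor = 100,
                       n_averaged_draws = 30000L) {
  paths <- c(residues = residues, demographics = demographics,
             intakes = intakes, dose_response = dose_response)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 seed = as.integer(seed), scenarios = scenarios,
                 n_population = as.integer(n_population),
                 min_per_stratum = as.integer(min_per_stratum),
                 residue_mcmc = residue_mcmc, bmd_mcmc = bmd_mcmc,
                 inter = inter, intra = intra, noael = noael,
                 safety_factor = safety_factor,
                 n_averaged_draws = as.integer(n_averaged_draws)),
            class = "run_config")
}

#' Run the full probabilistic risk assessment
#'
#' Executes the five stages in order — censored-residue reconstruction,
#' exposure simulation per scenario, dose-response fitting with model
#' averaging, probabilistic reference dose derivation, and risk
#' characterization against both the deterministic ADI and the pRfD — writing
#' each stage's outputs under `config$out_dir` and returning a manifest.
#'
#' @param config a [run_config()] object.
#' @return an object of class `run_manifest`: per-stage seeds, convergence
#'   flags, key results (pRfD, ADI, percentile table, exposure and risk
#'   summaries) and the output file inventory.
#' @export
run_full_assessment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  seeds <- list()

  # stage 1: residue reconstruction
  datasets <- read_residue_csv(config$paths$residues)
  fits <- lapply(datasets, function(ds) {
    ds <- augment_single_detect(ds)
    ms <- config$residue_mcmc
    ms$seed <- derive_seed(config$seed, paste0("residue-", ds$category))
    fit_censored_lognormal(ds, mcmc = ms)
  })
  seeds$residues <- vapply(fits, function(f) f$mcmc$seed, 1L)
  files$residue_fits <- file.path(config$out_dir, "residue_fits.json")
  write_residue_fits_json(fits, files$residue_fits)

  # stage 2: exposure per scenario
  strata <- demographic_strata(utils::read.csv(config$paths$demographics,
                                               stringsAsFactors = FALSE))
  intakes <- utils::read.csv(config$paths$intakes, stringsAsFactors = FALSE)
  population <- allocate_population(strata, config$n_population,
                                    config$min_per_stratum)
  exposures <- list()
  for (sc in config$scenarios) {
    ex <- run_exposure_scenario(population, strata, fits, intakes, sc,
                                seed = derive_seed(config$seed, paste0("exp-", sc)))
    exposures[[sc]] <- ex
    f <- file.path(config$out_dir, paste0("exposure_", sc, ".csv"))
    utils::write.csv(ex$individuals, f, row.names = FALSE)
    files[[paste0("exposure_", sc)]] <- f
  }

  # stage 3: dose-response + model averaging
  drdf <- utils::read.csv(config$paths$dose_response)
  drdata <- dose_response_data(drdf$dose, drdf$n, drdf$incidence)
  bmd_ms <- config$bmd_mcmc
  bmd_ms$seed <- derive_seed(config$seed, "bmd")
  seeds$bmd <- bmd_ms$seed
  drfits <- fit_dichotomous_models(drdata, mcmc = bmd_ms)
  weights <- compute_model_weights(drfits)
  averaged <- model_average_bmd(drfits, weights,
                                n_draws = config$n_averaged_draws,
                                seed = derive_seed(config$seed, "average"))

  # stage 4: pRfD
  hdmi <- derive_prfd(averaged, config$inter, config$intra,
                      seed = derive_seed(config$seed, "prfd"))
  adi <- derive_adi(config$noael, config$safety_factor)
  files$prfd <- file.path(config$out_dir, "prfd.json")
  jsonlite::write_json(list(
    prfd = hdmi$prfd, adi = adi,
    percentile_table = as.data.frame(hdmi$percentile_table),
    weights = as.list(weights),
    decomposition = as.list(hdmi$decomposition),
    converged = vapply(drfits, `[[`, TRUE, "converged")),
    files$prfd, auto_unbox = TRUE, digits = NA)

  # stage 5: risk characterization
  risk <- list()
  for (sc in config$scenarios) {
    exv <- exposures[[sc]]$individuals$exposure
    grp <- data.frame(sex = exposures[[sc]]$individuals$sex,
                      age_group = age_group(exposures[[sc]]$individuals$age))
    risk[[sc]] <- list(ADI = exceedance_summary(exv, adi, grp),
                       pRfD = exceedance_summary(exv, hdmi$prfd, grp))
  }
  files$risk <- file.path(config$out_dir, "risk.json")
  jsonlite::write_json(lapply(risk, function(r) lapply(r, function(s)
    list(reference = s$reference, count = s$count, fraction = s$fraction))),
    files$risk, auto_unbox = TRUE, digits = NA)

  structure(list(config = config, seeds = seeds,
                 residue_converged = vapply(fits, `[[`, TRUE, "converged"),
                 bmd_converged = vapply(drfits, `[[`, TRUE, "converged"),
                 weights = weights, adi = adi, prfd = hdmi$prfd,
                 percentile_table = hdmi$percentile_table,
                 decomposition = hdmi$decomposition,
                 exposures = exposures, risk = risk, files = files),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Probabilistic risk assessment run\n")
  cat(sprintf("  residue fits converged: %d/%d; dose-response fits converged: %d/%d\n",
              sum(x$residue_converged), length(x$residue_converged),
              sum(x$bmd_converged), length(x$bmd_converged)))
  cat(sprintf("  ADI = %.4g, pRfD = %.4g mg/kg/day\n", x$adi, x$prfd))
  for (sc in names(x$exposures)) {
    e <- x$exposures[[sc]]$individuals$exposure
    cat(sprintf("  %s exposure: mean %.3g mg/kg/day; HQ>1 vs pRfD: %d individuals\n",
                sc, mean(e), x$risk[[sc]]$pRfD$count))
  }
  invisible(x)
}

#' Tabular summaries of a completed run
#'
#' @param manifest a [run_full_assessment()] result.
#' @return list of data.frames: `exposure_by_age_group`, `exposure_by_sex`
#'   (stacked over scenarios), `percentile_table` (protection-direction
#'   BMD/HD50/HDMI percentiles) and `risk` (exceedance counts per scenario and
#'   reference).
#' @export
summarize_results <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  by_age <- do.call(rbind, lapply(names(manifest$exposures), function(sc)
    cbind(scenario = sc, manifest$exposures[[sc]]$by_age_group)))
  by_sex <- do.call(rbind, lapply(names(manifest$exposures), function(sc)
    cbind(scenario = sc, manifest$exposures[[sc]]$by_sex)))
  risk <- do.call(rbind, lapply(names(manifest$risk), function(sc)
    do.call(rbind, lapply(names(manifest$risk[[sc]]), function(ref) {
      s <- manifest$risk[[sc]][[ref]]
      data.frame(scenario = sc, reference = ref, value = s$reference,
                 count = s$count, fraction = s$fraction)
    }))))
  list(exposure_by_age_group = by_age, exposure_by_sex = by_sex,
       percentile_table = as.data.frame(manifest$percentile_table),
       risk = risk)
}
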