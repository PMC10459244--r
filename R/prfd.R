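#' Interspecies extrapolation parameters
#'
#' Parameters for converting an animal benchmark dose to a human-equivalent
#' dose: allometric body-weight scaling with an uncertain exponent
#' `b ~ Normal(allometric_mean, allometric_sd)` and a lognormal interspecies
#' toxicokinetic/toxicodynamic (TK/TD) uncertainty factor with geometric mean
#' `tktd_gm` and geometric standard deviation `tktd_gsd`.
#'
#' @param bw_human human body weight, kg.
#' @param bw_animal test-animal body weight, kg. The adult-rat default of
#'   0.35 kg makes the allometric factor `(0.35/70)^0.3 = 0.204`.
#' @param allometric_mean,allometric_sd mean and SD of the scaling exponent.
#' @param tktd_gm,tktd_gsd lognormal interspecies factor (GM 1, GSD 1.95 are
#'   the WHO/IPCS defaults).
#' @return an object of class `interspecies_params`.
#' @export
interspecies_params <- function(bw_human = 70, bw_animal = 0.35,
                                allometric_mean = 0.7, allometric_sd = 0.0243,
                                tktd_gm = 1, tktd_gsd = 1.95) {
  stopifnot(bw_human > 0, bw_animal > 0, allometric_sd >= 0,
            allometric_mean > 0, allometric_mean < 1.5,
            tktd_gm > 0, tktd_gsd > 1)
  structure(as.list(environment()), class = "interspecies_params")
}

#' Intraspecies (human variability) parameters
#'
#' The human-variability adjustment for protecting all but a fraction
#' `incidence` of the population is sampled as a lognormal value `F` with
#' geometric mean `log10_factor_gm` and geometric SD `log10_factor_gsd`,
#' interpreted as the log10 of the incidence-specific variability factor: the
#' target human dose is `HD50 / 10^F`. With the WHO/IPCS defaults for
#' incidence 1% the median factor is `10^0.746 = 5.57`.
#'
#' @param log10_factor_gm,log10_factor_gsd lognormal parameters of `F`.
#' @param incidence population incidence I the reference dose protects against.
#' @param magnitude benchmark response magnitude M (extra risk).
#' @return an object of class `intraspecies_params`.
#' @export
intraspecies_params <- function(log10_factor_gm = 0.746,
                                log10_factor_gsd = 1.5935,
                                incidence = 0.01, magnitude = 0.10) {
  stopifnot(log10_factor_gm > 0, log10_factor_gsd > 1,
            incidence > 0, incidence < 0.5, magnitude > 0, magnitude < 1)
  structure(as.list(environment()), class = "intraspecies_params")
}

#' Animal-to-human conversion of BMD draws (HD50)
#'
#' Per draw, samples an allometric exponent `b` and an interspecies TK/TD
#' factor `A` and computes
#' `HD50 = BMD * (bw_animal / bw_human)^(1 - b) / A`, the human dose at which
#' half the population experiences at least the benchmark response.
#'
#' @param bmd_draws positive BMD draws, mg/kg/day.
#' @param params an [interspecies_params()] object.
#' @param seed optional integer seed.
#' @return HD50 draws, mg/kg/day.
#' @export
animal_to_human_hd50 <- function(bmd_draws, params = interspecies_params(),
                                 seed = NULL) {
  stopifnot(inherits(params, "interspecies_params"), all(bmd_draws > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(bmd_draws)
  b <- stats::rnorm(n, params$allometric_mean, params$allometric_sd)
  a <- stats::rlnorm(n, log(params$tktd_gm), log(params$tktd_gsd))
  bmd_draws * (params$bw_animal / params$bw_human)^(1 - b) / a
}

#' Human-variability conversion of HD50 draws (HDMI)
#'
#' Divides each HD50 draw by `10^F`, `F ~ lognormal(GM, GSD)` per
#' [intraspecies_params()], yielding the target human dose at which a fraction
#' `incidence` of the population experiences at least the benchmark response.
#'
#' @param hd50_draws positive HD50 draws, mg/kg/day.
#' @param params an [intraspecies_params()] object.
#' @param seed optional integer seed.
#' @return HDMI draws, mg/kg/day.
#' @export
hd50_to_hdmi <- function(hd50_draws, params = intraspecies_params(),
                         seed = NULL) {
  stopifnot(inherits(params, "intraspecies_params"), all(hd50_draws > 0))
  if (!is.null(seed)) set.seed(seed)
  f <- stats::rlnorm(length(hd50_draws), log(params$log10_factor_gm),
                     log(params$log10_factor_gsd))
  hd50_draws / 10^f
}

#' Probabilistic reference dose from HDMI draws
#'
#' The pRfD is the lower tail of the HDMI uncertainty distribution: with the
#' default coverage 0.95 it is the lower 5th percentile (the "95th percentile"
#' in the protection direction).
#'
#' @param hdmi_draws HDMI draws, mg/kg/day.
#' @param coverage one-sided confidence level (default 0.95).
#' @return the pRfD in mg/kg/day.
#' @export
prfd_from_hdmi <- function(hdmi_draws, coverage = 0.95) {
  if (length(hdmi_draws) == 0L) stop("hdmi_draws must be nonempty")
  stopifnot(coverage > 0, coverage < 1)
  unname(stats::quantile(hdmi_draws, 1 - coverage))
}

#' Variance decomposition of log-scale uncertainty components
#'
#' Given independent multiplicative uncertainty components (supplied as draws
#' of their log-scale contributions), returns each component's share of the
#' total log variance.
#'
#' @param component_draws named list of numeric vectors: log-scale
#'   contributions of each component.
#' @return named shares, nonnegative, summing to 1.
#' @export
uncertainty_decomposition <- function(component_draws) {
  stopifnot(is.list(component_draws), length(component_draws) >= 1L)
  v <- vapply(component_draws, stats::var, 1.0)
  if (sum(v) == 0) stop("total log variance is zero")
  v / sum(v)
}

#' Full probabilistic reference dose derivation
#'
#' Chains the animal-to-human and human-variability conversions on a
#' model-averaged BMD posterior, extracts the pRfD, builds the
#' protection-direction percentile table (median, 90th, 95th, 99th — i.e. the
#' lower 50th/10th/5th/1st percentiles of each distribution) and decomposes
#' the log-scale uncertainty into point-of-departure, allometric,
#' interspecies and human-variability shares.
#'
#' @param bmd the model-averaged BMD posterior ([model_average_bmd()] result)
#'   or a numeric vector of BMD draws.
#' @param inter an [interspecies_params()] object.
#' @param intra an [intraspecies_params()] object.
#' @param coverage pRfD one-sided coverage (default 0.95).
#' @param seed integer seed for the conversion sampling.
#' @return an object of class `hdmi_result` with `hd50_draws`, `hdmi_draws`,
#'   `prfd`, `percentile_table` and `decomposition`.
#' @export
derive_prfd <- function(bmd, inter = interspecies_params(),
                        intra = intraspecies_params(), coverage = 0.95,
                        seed = 1L) {
  bmd_draws <- if (inherits(bmd, "bmd_averaged")) bmd$draws else as.numeric(bmd)
  stopifnot(all(bmd_draws > 0))
  n <- length(bmd_draws)
  set.seed(derive_seed(seed, "hd50"))
  b <- stats::rnorm(n, inter$allometric_mean, inter$allometric_sd)
  a <- stats::rlnorm(n, log(inter$tktd_gm), log(inter$tktd_gsd))
  hd50 <- bmd_draws * (inter$bw_animal / inter$bw_human)^(1 - b) / a
  set.seed(derive_seed(seed, "hdmi"))
  f <- stats::rlnorm(n, log(intra$log10_factor_gm), log(intra$log10_factor_gsd))
  hdmi <- hd50 / 10^f
  prfd <- prfd_from_hdmi(hdmi, coverage)
  pr <- c(0.5, 0.10, 0.05, 0.01)
  tab <- cbind(BMD = stats::quantile(bmd_draws, pr),
               HD50 = stats::quantile(hd50, pr),
               HDMI = stats::quantile(hdmi, pr))
  rownames(tab) <- c("Median", "90th percentile", "95th percentile",
                     "99th percentile")
  decomp <- uncertainty_decomposition(list(
    pod = log(bmd_draws),
    allometric = (1 - b) * log(inter$bw_animal / inter$bw_human),
    interspecies = -log(a),
    human_variability = -f * log(10)))
  structure(list(hd50_draws = hd50, hdmi_draws = hdmi, prfd = prfd,
                 percentile_table = tab, decomposition = decomp,
                 coverage = coverage, inter = inter, intra = intra,
                 seed = seed),
            class = "hdmi_result")
}

#' @export
print.hdmi_result <- function(x, ...) {
  cat("Probabilistic reference dose derivation (mg/kg/day)\n")
  cat("Protection-direction percentiles:\n")
  print(signif(x$percentile_table, 4))
  cat(sprintf("pRfD (lower %dth percentile of HDMI): %.4g mg/kg/day\n",
              round(100 * (1 - x$coverage)), x$prfd))
  cat("Uncertainty shares (log-scale variance):\n")
  print(round(x$decomposition, 3))
  invisible(x)
}
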