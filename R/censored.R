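#' Left-censored residue dataset
#'
#' Container for per-category residue measurements where most samples fall
#' below the analytical detection limit: only the detected concentrations are
#' recorded as values, non-detects are represented by their count.
#'
#' @param category food-category code (e.g. "RV" for root and stem
#'   vegetables).
#' @param values detected concentrations in ppm (mg chemical / kg food); all
#'   must be positive. Values below the detection limit are allowed because
#'   the effective reporting limit is inferred during fitting.
#' @param n_cen number of non-detect (censored) samples.
#' @param detection_limit analytical detection limit in ppm.
#' @return an object of class `censored_residue_data`.
#' @export
censored_residue_data <- function(category, values, n_cen,
                                  detection_limit = 0.002) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("at least one detected value is required")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all detected values must be positive and finite")
  if (n_cen < 0) stop("n_cen must be nonnegative")
  if (detection_limit <= 0) stop("detection_limit must be positive")
  structure(list(category = as.character(category), values = values,
                 n_obs = length(values), n_cen = as.integer(n_cen),
                 detection_limit = detection_limit),
            class = "censored_residue_data")
}

#' @export
print.censored_residue_data <- function(x, ...) {
  cat(sprintf("Censored residue data [%s]: %d detects, %d non-detects (%.2f%% censored), DL = %g ppm\n",
              x$category, x$n_obs, x$n_cen,
              100 * x$n_cen / (x$n_obs + x$n_cen), x$detection_limit))
  invisible(x)
}

#' Augment a single-detect dataset
#'
#' Categories with exactly one detected sample cannot inform a scale
#' parameter, so an extra detectable value equal to the detection limit is
#' appended before fitting. Datasets with two or more detects are returned
#' unchanged.
#'
#' @param dataset a [censored_residue_data()] object.
#' @return the (possibly augmented) dataset; `n_cen` is never altered.
#' @export
augment_single_detect <- function(dataset) {
  stopifnot(inherits(dataset, "censored_residue_data"))
  if (dataset$n_obs != 1L) return(dataset)
  censored_residue_data(dataset$category,
                        c(dataset$values, dataset$detection_limit),
                        dataset$n_cen, dataset$detection_limit)
}

#' Priors for the censored lognormal residue model
#'
#' Default data-dependent priors: the geometric mean GM has a Normal prior
#' centred at half the largest detect with scale a quarter of it; the
#' reporting limit RL has a Normal prior centred at the smallest detect with
#' scale one fifth of it (truncated to (0, min detect]); the geometric
#' standard deviation GSD has a lognormal prior with geometric mean 4 and
#' geometric standard deviation 2, i.e. `ln(GSD) ~ Normal(ln 4, ln 2)`.
#'
#' @param dataset optional [censored_residue_data()] used to derive the
#'   defaults; required unless all location/scale arguments are supplied.
#' @param gm_loc,gm_scale Normal prior on GM (ppm).
#' @param rl_loc,rl_scale Normal prior on RL (ppm).
#' @param gsd_gm,gsd_gsd lognormal prior on GSD (unitless).
#' @return an object of class `residue_priors`.
#' @export
residue_priors <- function(dataset = NULL,
                           gm_loc = NULL, gm_scale = NULL,
                           rl_loc = NULL, rl_scale = NULL,
                           gsd_gm = 4, gsd_gsd = 2) {
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "censored_residue_data"))
    ymax <- max(dataset$values)
    ymin <- min(dataset$values)
    if (is.null(gm_loc)) gm_loc <- ymax / 2
    if (is.null(gm_scale)) gm_scale <- ymax / 4
    if (is.null(rl_loc)) rl_loc <- ymin
    if (is.null(rl_scale)) rl_scale <- ymin / 5
  }
  vals <- c(gm_loc, gm_scale, rl_loc, rl_scale, gsd_gm, gsd_gsd)
  if (length(vals) != 6L || any(!is.finite(vals)))
    stop("all prior parameters must be finite (supply a dataset or all values)")
  if (gm_scale <= 0 || rl_scale <= 0 || gsd_gsd <= 1 || gsd_gm <= 0)
    stop("prior scales must be positive (gsd_gsd > 1)")
  structure(list(gm_loc = gm_loc, gm_scale = gm_scale,
                 rl_loc = rl_loc, rl_scale = rl_scale,
                 gsd_gm = gsd_gm, gsd_gsd = gsd_gsd),
            class = "residue_priors")
}

# Unconstrained parameterization used by the sampler:
#   t1 = ln GM                   (GM > 0)
#   t2 = ln ln GSD               (GSD > 1, required for a valid sdlog)
#   t3 = logit(RL / min detect)  (0 < RL <= min detect)
# The GSD lower bound at 1 is the weakest constraint that keeps the lognormal
# scale positive; the prior mass (GM 4, GSD 2) sits far from it.
censored_log_posterior <- function(dataset, priors, latent = FALSE) {
  y <- dataset$values
  ly <- log(y)
  n_cen <- dataset$n_cen
  ymin <- min(y)
  force(priors)
  function(theta) {
    gm <- exp(theta[1L])
    lgsd <- exp(theta[2L])            # ln GSD > 0
    p3 <- stats::plogis(theta[3L])
    rl <- ymin * p3
    mu <- theta[1L]
    # priors (with log-Jacobians of the transforms)
    lp <- stats::dnorm(gm, priors$gm_loc, priors$gm_scale, log = TRUE) + theta[1L] +
      stats::dnorm(lgsd, log(priors$gsd_gm), log(priors$gsd_gsd), log = TRUE) + theta[2L] +
      stats::dnorm(rl, priors$rl_loc, priors$rl_scale, log = TRUE) +
      log(ymin) + log(p3) + log1p(-p3)
    # detects
    lp <- lp + sum(stats::dnorm(ly, mu, lgsd, log = TRUE)) - sum(ly)
    # non-detects
    if (n_cen > 0L) {
      if (latent) {
        z <- theta[-(1:3)]
        pz <- stats::plogis(z)
        ycen <- rl * pz
        lp <- lp + sum(stats::dlnorm(ycen, mu, lgsd, log = TRUE)) +
          n_cen * log(rl) + sum(log(pz) + log1p(-pz))
      } else {
        lp <- lp + n_cen * stats::plnorm(rl, mu, lgsd, log.p = TRUE)
      }
    }
    lp
  }
}

#' Fit a lognormal distribution to left-censored residue data
#'
#' Bayesian reconstruction of the residue concentration distribution from data
#' dominated by non-detects. Detected values contribute lognormal densities;
#' each non-detect contributes the lognormal CDF evaluated at the (inferred)
#' reporting limit RL, either marginally (one CDF term per censored count,
#' the default) or through explicit latent concentrations constrained below RL.
#' Sampling is by multi-chain adaptive Metropolis; the last
#' `1 - warmup_fraction` of each chain is retained and pooled.
#'
#' The fitted object carries posterior draws of GM, GSD and RL together with
#' the derived arithmetic moments `mean = GM * exp(ln(GSD)^2 / 2)` and
#' `sd = mean * sqrt(exp(ln(GSD)^2) - 1)` averaged over retained draws
#' (`mean_est`, `std_est`), which downstream exposure simulation uses to
#' parameterize the residue lognormal.
#'
#' @param dataset a [censored_residue_data()] object (apply
#'   [augment_single_detect()] first when there is a single detect).
#' @param priors a [residue_priors()] object; defaults are derived from the
#'   data.
#' @param mcmc an [mcmc_settings()] object.
#' @param likelihood_mode `"marginalized"` (default) or `"latent"`.
#' @return an object of class `censored_lognormal_fit` with elements
#'   `gm_draws`, `gsd_draws`, `rl_draws`, `mean_est`, `std_est`, `rhat`
#'   (named vector over GM, GSD, RL), `converged`, `accept`, plus the inputs.
#'   Non-convergent fits are returned flagged (`converged = FALSE`), never
#'   silently re-run.
#' @export
fit_censored_lognormal <- function(dataset,
                                   priors = residue_priors(dataset),
                                   mcmc = mcmc_settings(),
                                   likelihood_mode = c("marginalized", "latent")) {
  stopifnot(inherits(dataset, "censored_residue_data"),
            inherits(priors, "residue_priors"),
            inherits(mcmc, "mcmc_settings"))
  likelihood_mode <- match.arg(likelihood_mode)
  latent <- likelihood_mode == "latent" && dataset$n_cen > 0L
  lpost <- censored_log_posterior(dataset, priors, latent = latent)
  k <- 3L + if (latent) dataset$n_cen else 0L
  base_init <- c(log(max(mean(dataset$values), 1e-12)),
                 log(log(priors$gsd_gm)), 0)
  init_fn <- function(chain) {
    set.seed(derive_seed(mcmc$seed, paste0("init", chain)))
    c(base_init + stats::rnorm(3L, 0, 0.3),
      if (latent) stats::rnorm(dataset$n_cen, -1, 0.5))
  }
  scale0 <- c(0.5, 0.3, 0.5, rep(0.5, k - 3L))
  res <- run_metropolis(lpost, init_fn, mcmc, scale0 = scale0)
  pooled <- do.call(rbind, res$chains)
  gm <- exp(pooled[, 1L])
  gsd <- exp(exp(pooled[, 2L]))
  rl <- min(dataset$values) * stats::plogis(pooled[, 3L])
  lgsd <- exp(pooled[, 2L])
  mean_draws <- gm * exp(lgsd^2 / 2)
  sd_draws <- mean_draws * sqrt(expm1(lgsd^2))
  nat <- lapply(res$chains, function(m)
    cbind(GM = exp(m[, 1L]), GSD = exp(exp(m[, 2L])),
          RL = min(dataset$values) * stats::plogis(m[, 3L])))
  rhat <- rhat_by_param(nat)
  ycen <- NULL
  if (latent) {
    ycen <- rl * stats::plogis(pooled[, 4:k, drop = FALSE])
  }
  structure(list(category = dataset$category,
                 gm_draws = gm, gsd_draws = gsd, rl_draws = rl,
                 ycen_draws = ycen,
                 mean_est = mean(mean_draws), std_est = mean(sd_draws),
                 rhat = rhat,
                 converged = max(rhat) < mcmc$rhat_threshold,
                 accept = res$accept,
                 n_obs = dataset$n_obs, n_cen = dataset$n_cen,
                 detection_limit = dataset$detection_limit,
                 likelihood_mode = likelihood_mode,
                 priors = priors, mcmc = mcmc),
            class = "censored_lognormal_fit")
}

#' @export
print.censored_lognormal_fit <- function(x, ...) {
  cat(sprintf("Censored lognormal fit [%s] (%s likelihood)\n",
              x$category, x$likelihood_mode))
  cat(sprintf("  %d detects, %d non-detects; DL = %g ppm\n",
              x$n_obs, x$n_cen, x$detection_limit))
  cat(sprintf("  posterior medians: GM = %.4g ppm, GSD = %.3g, RL = %.4g ppm\n",
              stats::median(x$gm_draws), stats::median(x$gsd_draws),
              stats::median(x$rl_draws)))
  cat(sprintf("  arithmetic moments: mean_est = %.4g, std_est = %.4g ppm\n",
              x$mean_est, x$std_est))
  cat(sprintf("  max R-hat = %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.censored_lognormal_fit <- function(object, ...) {
  c(gm = stats::median(object$gm_draws),
    gsd = stats::median(object$gsd_draws),
    rl = stats::median(object$rl_draws))
}

#' @export
summary.censored_lognormal_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qt <- function(v) stats::quantile(v, probs = probs, names = TRUE)
  out <- rbind(GM = qt(object$gm_draws), GSD = qt(object$gsd_draws),
               RL = qt(object$rl_draws))
  structure(list(quantiles = out, mean_est = object$mean_est,
                 std_est = object$std_est, rhat = object$rhat,
                 converged = object$converged, category = object$category),
            class = "summary.censored_lognormal_fit")
}

#' @export
print.summary.censored_lognormal_fit <- function(x, ...) {
  cat(sprintf("Posterior quantiles for category %s:\n", x$category))
  print(round(x$quantiles, 6))
  cat(sprintf("mean_est = %.4g ppm, std_est = %.4g ppm, max R-hat = %.3f\n",
              x$mean_est, x$std_est, max(x$rhat)))
  invisible(x)
}

#' Sample residue concentrations from a fitted posterior
#'
#' Draws concentrations from the lognormal distribution whose arithmetic
#' moments equal the fitted `mean_est` / `std_est`, the distribution used to
#' impute non-detects and to assign residues in the exposure simulation.
#'
#' @param fit a converged [fit_censored_lognormal()] result.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return `n` positive concentrations in ppm.
#' @export
sample_posterior_residues <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "censored_lognormal_fit"))
  if (!fit$converged) stop("fit has not converged; refusing to sample")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(numeric(0))
  p <- lognormal_params_from_moments(fit$mean_est, fit$std_est)
  if (p$sdlog == 0) return(rep(fit$mean_est, n))
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' @export
simulate.censored_lognormal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sample_posterior_residues(object, nsim, seed)
}

#' Read long-format residue samples from CSV
#'
#' Expects columns `category`, `value`, `censored` (0/1) and
#' `detection_limit`; one row per sample. Censored rows may leave `value`
#' empty. Returns one [censored_residue_data()] per category.
#'
#' @param path CSV file path.
#' @return named list of `censored_residue_data` objects.
#' @export
read_residue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "value", "censored", "detection_limit")
  if (!all(need %in% names(df)))
    stop("residue CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$category), function(g) {
    det <- g$value[g$censored == 0]
    censored_residue_data(g$category[1L], det, sum(g$censored == 1),
                          g$detection_limit[1L])
  })
  out[order(names(out))]
}

#' Serialize residue fits to JSON
#'
#' @param fits named list of [fit_censored_lognormal()] results.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_residue_fits_json <- function(fits, path) {
  obj <- lapply(fits, function(f) list(
    gm = stats::median(f$gm_draws), gsd = stats::median(f$gsd_draws),
    rl = stats::median(f$rl_draws), mean_est = f$mean_est,
    std_est = f$std_est, rhat = as.list(f$rhat), converged = f$converged,
    n_obs = f$n_obs, n_cen = f$n_cen,
    seed = f$mcmc$seed, n_iter = f$mcmc$n_iter))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
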