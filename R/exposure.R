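#' Validate a demographic strata table
#'
#' @param strata data.frame with columns `age` (integer years), `sex`
#'   (`"male"`/`"female"`), `population_count`, `bw_mean` (kg), `bw_sd` (kg).
#' @return the validated data.frame (invisibly classed `demographic_strata`).
#' @export
demographic_strata <- function(strata) {
  need <- c("age", "sex", "population_count", "bw_mean", "bw_sd")
  if (!all(need %in% names(strata)))
    stop("strata must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(strata$population_count >= 0), all(strata$bw_mean > 0),
            all(strata$bw_sd >= 0),
            all(strata$sex %in% c("male", "female")))
  class(strata) <- unique(c("demographic_strata", class(strata)))
  strata
}

#' Allocate simulated individuals across demographic strata
#'
#' Counts are proportional to `population_count` using largest-remainder
#' rounding (ties broken deterministically by stratum order), then every
#' populated stratum is raised to `min_per_stratum`, compensating by reducing
#' the largest strata, so that the total is exactly `n_total`.
#'
#' @param strata a [demographic_strata()] table.
#' @param n_total total simulated individuals (default 200,000).
#' @param min_per_stratum minimum per populated stratum (default 10).
#' @return data.frame of individuals: `id`, `age`, `sex`, `stratum` (row index
#'   into `strata`).
#' @export
allocate_population <- function(strata, n_total = 200000L,
                                min_per_stratum = 10L) {
  strata <- demographic_strata(strata)
  pos <- which(strata$population_count > 0)
  if (length(pos) == 0L) stop("no populated strata")
  if (n_total < min_per_stratum * length(pos))
    stop("n_total too small to give every populated stratum its minimum")
  w <- strata$population_count[pos] / sum(strata$population_count[pos])
  q <- n_total * w
  counts <- floor(q)
  rem <- n_total - sum(counts)
  if (rem > 0) {
    frac <- q - counts
    ord <- order(-frac, seq_along(frac))   # largest remainder, then row order
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  # raise deficient strata to the minimum, taking from the largest strata
  deficit <- pmax(min_per_stratum - counts, 0)
  counts <- counts + deficit
  excess <- sum(deficit)
  while (excess > 0) {
    i <- which.max(counts)
    take <- min(excess, counts[i] - min_per_stratum)
    if (take <= 0) stop("allocation infeasible")
    counts[i] <- counts[i] - take
    excess <- excess - take
  }
  stopifnot(sum(counts) == n_total, all(counts >= min_per_stratum))
  idx <- rep(pos, counts)
  data.frame(id = seq_len(n_total), age = strata$age[idx],
             sex = strata$sex[idx], stratum = idx)
}

#' Aggregate dietary exposure of one or many individuals
#'
#' `sum_i intake_i * residue_i / (bodyweight * 1000)`: intakes in g/day,
#' residues in ppm (mg chemical per kg food), body weight in kg; the factor
#' 1000 converts grams of food to kilograms, giving mg/kg body weight/day.
#'
#' @param intakes numeric vector of per-category intakes (g/day), or a matrix
#'   with one row per individual.
#' @param residues per-category residues (ppm), vector or conforming matrix.
#' @param bodyweight body weight(s) in kg (> 0).
#' @return exposure(s) in mg/kg/day.
#' @export
aggregate_exposure <- function(intakes, residues, bodyweight) {
  if (any(bodyweight <= 0)) stop("bodyweight must be positive")
  if (any(intakes < 0) || any(residues < 0)) stop("negative inputs")
  if (is.matrix(intakes)) {
    rowSums(intakes * residues) / (bodyweight * 1000)
  } else {
    sum(intakes * residues) / (bodyweight * 1000)
  }
}

#' Standard age-group labels
#'
#' Partition of ages 0--100 used in exposure and risk summaries: toddlers
#' (0--2), preschoolers (3--5), children (6--11), pre-teens (12--15), teens
#' (16--18), adults (19--65) and elderly (66+).
#'
#' @param age integer ages.
#' @return factor of group labels.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-1, 2, 5, 11, 15, 18, 65, Inf),
      labels = c("0-2", "3-5", "6-11", "12-15", "16-18", "19-65", "66+"))
}

# accept either a censored_lognormal_fit or a list with mean_est/std_est
residue_moments <- function(fit, category) {
  if (inherits(fit, "censored_lognormal_fit")) {
    if (!fit$converged)
      stop("residue fit for category ", category, " has not converged")
    list(mean = fit$mean_est, sd = fit$std_est)
  } else if (is.list(fit) && all(c("mean_est", "std_est") %in% names(fit))) {
    list(mean = fit$mean_est, sd = fit$std_est)
  } else stop("unusable residue fit for category ", category)
}

#' Simulate population dietary exposure under one intake scenario
#'
#' For every simulated individual: body weight is drawn from the stratum's
#' truncated normal (bounds `[max(0.5, mean - 4 sd), mean + 4 sd]` kg), each
#' category intake from a truncated normal on `[0, mean + 6 sd]` g/day, each
#' residue concentration from the fitted posterior lognormal
#' (via `mean_est`/`std_est`), and the aggregate exposure is computed.
#' Draws are independent across individuals and categories (chronic-average
#' interpretation; no within-person correlation structure).
#'
#' @param population skeleton from [allocate_population()].
#' @param strata the [demographic_strata()] table used for the allocation.
#' @param residue_fits named list (by category) of [fit_censored_lognormal()]
#'   results or `list(mean_est=, std_est=)` stand-ins.
#' @param intake_specs data.frame with columns `category`, `scenario`,
#'   `intake_mean`, `intake_sd` (g/day).
#' @param scenario `"LB"` (general population) or `"UB"` (consumer only).
#' @param seed integer seed.
#' @return an object of class `exposure_result`: `individuals` (data.frame
#'   with body weight, per-category contributions in mg/kg/day and `exposure`),
#'   plus `by_age_group` and `by_sex` summary tables.
#' @export
run_exposure_scenario <- function(population, strata, residue_fits,
                                  intake_specs, scenario = c("LB", "UB"),
                                  seed = 1L) {
  scenario <- match.arg(scenario)
  strata <- demographic_strata(strata)
  spec <- intake_specs[intake_specs$scenario == scenario, , drop = FALSE]
  cats <- sort(unique(spec$category))
  missing_fit <- setdiff(cats, names(residue_fits))
  if (length(missing_fit) > 0)
    stop("missing residue fit for category: ", paste(missing_fit, collapse = ", "))
  n <- nrow(population)
  set.seed(derive_seed(seed, paste0("exposure-", scenario)))
  # body weights per stratum
  bw <- numeric(n)
  for (s in unique(population$stratum)) {
    i <- population$stratum == s
    m <- strata$bw_mean[s]; sd <- strata$bw_sd[s]
    bw[i] <- sample_truncated_normal(sum(i), m, sd,
                                     lower = max(0.5, m - 4 * sd),
                                     upper = m + 4 * sd)
  }
  intakes <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  residues <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  for (j in seq_along(cats)) {
    row <- spec[spec$category == cats[j], , drop = FALSE]
    if (nrow(row) != 1L) stop("need exactly one intake spec per category")
    intakes[, j] <- sample_truncated_normal(n, row$intake_mean, row$intake_sd,
                                            lower = 0,
                                            upper = row$intake_mean + 6 * row$intake_sd)
    mom <- residue_moments(residue_fits[[cats[j]]], cats[j])
    p <- lognormal_params_from_moments(mom$mean, mom$sd)
    residues[, j] <- if (p$sdlog == 0) rep(mom$mean, n) else
      stats::rlnorm(n, p$meanlog, p$sdlog)
  }
  contrib <- intakes * residues / (bw * 1000)
  exposure <- rowSums(contrib)
  ind <- data.frame(population, bodyweight = bw, exposure = exposure)
  colnames(contrib) <- paste0("contrib_", cats)
  ind <- cbind(ind, contrib)
  grp <- age_group(ind$age)
  summarize <- function(f) {
    agg <- tapply(exposure, f, function(e)
      c(n = length(e), mean = mean(e), sd = stats::sd(e),
        median = stats::median(e), p95 = unname(stats::quantile(e, 0.95))))
    data.frame(group = names(agg), do.call(rbind, agg), row.names = NULL)
  }
  all_row <- data.frame(group = "all", n = n, mean = mean(exposure),
                        sd = stats::sd(exposure), median = stats::median(exposure),
                        p95 = unname(stats::quantile(exposure, 0.95)))
  structure(list(individuals = ind, scenario = scenario,
                 by_age_group = rbind(all_row, summarize(grp)),
                 by_sex = summarize(ind$sex), seed = seed),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("Exposure simulation (%s scenario, %d individuals)\n",
              x$scenario, nrow(x$individuals)))
  cat(sprintf("  mean %.3g +/- %.3g mg/kg/day (median %.3g)\n",
              mean(x$individuals$exposure), stats::sd(x$individuals$exposure),
              stats::median(x$individuals$exposure)))
  print(x$by_age_group, digits = 3)
  invisible(x)
}
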