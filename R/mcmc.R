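#' MCMC sampler settings
#'
#' Settings for the multi-chain adaptive random-walk Metropolis sampler used
#' by [fit_censored_lognormal()] and [fit_dichotomous_model()]. Convergence is
#' declared when the Gelman--Rubin potential scale reduction factor of every
#' monitored parameter is below `rhat_threshold` (the conventional 1.1 rule).
#'
#' @param n_chains number of independent chains (>= 2).
#' @param n_iter iterations per chain, including warmup.
#' @param warmup_fraction fraction of each chain discarded as warmup; the
#'   retained draws are the last `(1 - warmup_fraction)` of each chain.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param rhat_threshold convergence threshold for the split-free R-hat.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4L, n_iter = 25000L, warmup_fraction = 0.5,
                          seed = 1L, rhat_threshold = 1.1) {
  stopifnot(n_chains >= 2L, n_iter >= 8L,
            warmup_fraction > 0, warmup_fraction < 1,
            rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 warmup_fraction = warmup_fraction, seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_settings")
}

# Single adaptive random-walk Metropolis chain on an unconstrained scale.
# Proposal scales adapt only during warmup (global log-scale by Robbins-Monro
# toward `target` acceptance; relative per-parameter scales from the empirical
# sd of recent draws), so the retained draws come from a fixed kernel.
mh_chain <- function(log_post, init, n_iter, warmup, scale0 = NULL,
                     target = 0.3) {
  k <- length(init)
  if (is.null(scale0)) scale0 <- rep(0.5, k)
  draws <- matrix(NA_real_, n_iter, k)
  th <- init
  lp <- log_post(th)
  if (!is.finite(lp)) stop("initial value has non-finite log posterior")
  s <- scale0
  lsc <- 0
  acc <- 0L
  win_acc <- 0L
  win <- 50L
  nwin <- 0L
  for (i in seq_len(n_iter)) {
    prop <- th + stats::rnorm(k) * (s * exp(lsc))
    lpp <- log_post(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      th <- prop; lp <- lpp
      acc <- acc + 1L; win_acc <- win_acc + 1L
    }
    draws[i, ] <- th
    if (i <= warmup && i %% win == 0L) {
      nwin <- nwin + 1L
      lsc <- lsc + (win_acc / win - target) / sqrt(nwin)
      win_acc <- 0L
      if (i %% 500L == 0L && i >= 1000L) {
        es <- apply(draws[(i - 999L):i, , drop = FALSE], 2, stats::sd)
        ok <- is.finite(es) & es > 0
        if (any(ok)) s[ok] <- es[ok] * exp(-lsc)
      }
    }
  }
  list(draws = draws, accept = acc / n_iter)
}

# Multi-chain driver. Returns retained draws as a list of [iter x param]
# matrices (one per chain) plus acceptance rates. `init_fn(chain)` supplies
# (jittered) initial values per chain.
run_metropolis <- function(log_post, init_fn, settings, scale0 = NULL,
                           par_names = NULL) {
  warm <- floor(settings$n_iter * settings$warmup_fraction)
  chains <- vector("list", settings$n_chains)
  accept <- numeric(settings$n_chains)
  for (c in seq_len(settings$n_chains)) {
    set.seed(derive_seed(settings$seed, paste0("chain", c)))
    res <- mh_chain(log_post, init_fn(c), settings$n_iter, warm, scale0)
    kept <- res$draws[(warm + 1L):settings$n_iter, , drop = FALSE]
    if (!is.null(par_names)) colnames(kept) <- par_names
    chains[[c]] <- kept
    accept[c] <- res$accept
  }
  list(chains = chains, accept = accept)
}

#' Gelman--Rubin convergence diagnostic
#'
#' Potential scale reduction factor comparing between-chain and within-chain
#' variance for draws of a single scalar parameter.
#'
#' @param chain_draws a numeric matrix with one column per chain, or a list of
#'   equal-length numeric vectors (one per chain).
#' @return the R-hat statistic (>= 1 up to floating point; 1 indicates the
#'   chains are indistinguishable).
#' @export
compute_rhat <- function(chain_draws) {
  if (is.list(chain_draws)) {
    len <- unique(vapply(chain_draws, length, 1L))
    if (length(len) != 1L) stop("all chains must have the same length")
    chain_draws <- do.call(cbind, chain_draws)
  }
  chain_draws <- as.matrix(chain_draws)
  m <- ncol(chain_draws)
  n <- nrow(chain_draws)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 4L) stop("at least 4 draws per chain are required")
  means <- colMeans(chain_draws)
  vars <- apply(chain_draws, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (b == 0) return(1)      # indistinguishable chains
  if (w == 0) return(Inf)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

# R-hat for each column of per-chain draw matrices.
rhat_by_param <- function(chains) {
  k <- ncol(chains[[1L]])
  out <- vapply(seq_len(k), function(j) {
    compute_rhat(lapply(chains, function(m) m[, j]))
  }, 1.0)
  names(out) <- colnames(chains[[1L]])
  out
}

# Deterministic per-stage seed derivation from a master seed. Arithmetic kept
# exact in doubles and reduced below 2^31 so set.seed() accepts the result.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}
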