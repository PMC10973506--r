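#' MCMC sampler settings
#'
#' Settings for the adaptive random-walk Metropolis-within-Gibbs sampler
#' used by [fit_weibull_borrow()] and [fit_binary_borrow()]. The defaults
#' (3 chains of 50,000 iterations, first half discarded as warmup) match
#' the analysis protocol the package implements; tests and exploratory
#' runs typically reduce `n_iter`.
#'
#' @param n_chains Number of independent chains (at least 2, so that the
#'   Gelman-Rubin diagnostic is defined).
#' @param n_iter Total iterations per chain, including warmup.
#' @param warmup_frac Fraction of each chain discarded as warmup, during
#'   which proposal step sizes are adapted; adaptation is frozen afterwards.
#' @param seed Integer seed; chain c uses a seed derived deterministically
#'   from it (`(seed + 104729 * c) mod (2^31 - 2) + 1`).
#' @param target_accept Target per-coordinate acceptance rate for step-size
#'   adaptation.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, warmup_frac = 0.5,
                        seed = 1L, target_accept = 0.3) {
  n_chains <- as.integer(n_chains)
  n_iter <- as.integer(n_iter)
  if (n_chains < 2L) stop("n_chains must be at least 2")
  if (n_iter < 1000L) stop("n_iter must be at least 1000")
  if (warmup_frac <= 0 || warmup_frac >= 1) stop("warmup_frac must be in (0,1)")
  if (target_accept <= 0 || target_accept >= 1) stop("target_accept must be in (0,1)")
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 warmup_frac = warmup_frac, seed = as.integer(seed),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Commensurate-prior borrowing settings
#'
#' Controls how much information the historical control cohort contributes
#' to the concurrent control parameter. The commensurate prior links the
#' current-control parameter to its historical analogue through a Gaussian
#' gap on the linear (logit or log-rate) scale; the gap's standard
#' deviation `sigma_tau` governs borrowing strength: large values decouple
#' the cohorts, values near zero pool them.
#'
#' @param mode `"none"` (historical data ignored), `"fixed"` (gap SD fixed
#'   at `sigma_tau`), or `"adaptive"` (gap SD given a half-normal
#'   hyperprior of scale `hyper_scale`, so the degree of borrowing is
#'   learned from the data - dynamic borrowing).
#' @param sigma_tau Gap standard deviation, required for `mode = "fixed"`.
#' @param hyper_scale Scale of the half-normal hyperprior on the gap SD in
#'   adaptive mode.
#' @return An object of class `borrow_config`.
#' @export
borrow_config <- function(mode = c("adaptive", "fixed", "none"),
                          sigma_tau = NULL, hyper_scale = 1) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(sigma_tau) || !is.finite(sigma_tau) || sigma_tau <= 0)
      stop("mode = 'fixed' requires sigma_tau > 0")
  }
  if (hyper_scale <= 0) stop("hyper_scale must be > 0")
  structure(list(mode = mode, sigma_tau = sigma_tau,
                 hyper_scale = hyper_scale),
            class = "borrow_config")
}

# deterministic per-chain seed, kept below 2^31
.chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) + 104729 * chain) %% 2147483646) + 1L
}

# Adaptive random-walk Metropolis-within-Gibbs.
# log_post(theta) returns the unnormalized log posterior (may be -Inf);
# it may cache expensive pieces internally keyed on coordinates it owns.
# Returns an array [kept iterations, chain, parameter].
.run_mwg <- function(log_post, init, config, param_names,
                     init_jitter = 0.5, step0 = 0.5) {
  n_par <- length(init)
  init_jitter <- rep_len(init_jitter, n_par)
  step0 <- rep_len(step0, n_par)
  n_iter <- config$n_iter
  n_warm <- floor(config$warmup_frac * n_iter)
  n_keep <- n_iter - n_warm
  draws <- array(NA_real_, dim = c(n_keep, config$n_chains, n_par),
                 dimnames = list(NULL, NULL, param_names))
  for (ch in seq_len(config$n_chains)) {
    set.seed(.chain_seed(config$seed, ch))
    theta <- init + stats::rnorm(n_par, 0, init_jitter)
    lp <- log_post(theta)
    tries <- 0L
    while (!is.finite(lp) && tries < 50L) {  # re-jitter off a density cliff
      theta <- init + stats::rnorm(n_par, 0, init_jitter / 4)
      lp <- log_post(theta)
      tries <- tries + 1L
    }
    if (!is.finite(lp)) {
      theta <- init
      lp <- log_post(theta)
    }
    if (!is.finite(lp)) stop("could not find a starting value with finite posterior density")
    step <- step0
    acc <- integer(n_par)
    batch <- 0L
    for (it in seq_len(n_iter)) {
      for (j in seq_len(n_par)) {
        prop <- theta
        prop[j] <- theta[j] + stats::rnorm(1, 0, step[j])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[j] <- acc[j] + 1L
        }
      }
      if (it <= n_warm && it %% 50L == 0L) {
        batch <- batch + 1L
        rate <- acc / 50
        delta <- pmin(0.5, 2 / sqrt(batch))
        step <- step * exp(ifelse(rate > config$target_accept, delta, -delta))
        acc <- integer(n_par)
      }
      if (it > n_warm) draws[it - n_warm, ch, ] <- theta
    }
  }
  draws
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classical (non-split) Gelman-Rubin diagnostic from two or
#' more chains of equal length: with m chains of length n, B is n times
#' the variance of the chain means (m - 1 denominator), W the mean of the
#' within-chain sample variances (n - 1 denominator), and
#' `Rhat = sqrt((((n-1)/n) W + B/n) / W)`. Values close to 1 indicate the
#' chains have mixed; the fitting functions flag any parameter with
#' Rhat > 1.05.
#'
#' @param chains A numeric matrix with one column per chain, or a list of
#'   equal-length numeric vectors.
#' @return The scalar Rhat.
#' @examples
#' gelman_rubin(cbind(c(1, 2, 3, 4), c(3, 4, 5, 6)))  # sqrt(1.95)
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    len <- vapply(chains, length, 1L)
    if (length(unique(len)) != 1L) stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 2L) stop("chains must have length at least 2")
  B <- n * stats::var(colMeans(chains))
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior threshold probabilities for a hazard ratio
#'
#' Fraction of posterior draws strictly below each threshold. The default
#' thresholds are the design effect size (HR 0.76, a 10% absolute gain in
#' 3-year event-free survival), a moderate effect (HR 0.87, a 5% gain),
#' and any benefit (HR 1).
#'
#' @param hr_draws Positive posterior draws of the hazard ratio.
#' @param thresholds Thresholds at which to evaluate the posterior mass.
#' @return Named numeric vector of probabilities, names `"P(HR<x)"`.
#' @export
threshold_probs <- function(hr_draws, thresholds = c(0.76, 0.87, 1.0)) {
  hr_draws <- as.numeric(hr_draws)
  if (length(hr_draws) == 0L) stop("hr_draws must be non-empty")
  if (any(!is.finite(hr_draws)) || any(hr_draws <= 0))
    stop("hr_draws must be positive and finite")
  out <- vapply(thresholds, function(th) mean(hr_draws < th), 1.0)
  names(out) <- sprintf("P(HR<%g)", thresholds)
  out
}

# Build a posterior_summary from a draws array [iter, chain, param].
# `probs` is a named probability vector computed by the caller on the
# pooled draws of the quantity of interest.
.posterior_summary <- function(draws, probs = numeric(0),
                               rhat_threshold = 1.05, mcmc = NULL,
                               model = "") {
  pn <- dimnames(draws)[[3]]
  pooled <- function(j) as.numeric(draws[, , j])
  qs <- t(vapply(seq_along(pn), function(j)
    stats::quantile(pooled(j), c(0.5, 0.025, 0.975), names = FALSE),
    numeric(3)))
  rhat <- vapply(seq_along(pn), function(j) gelman_rubin(draws[, , j]), 1.0)
  summ <- data.frame(parameter = pn, median = qs[, 1],
                     lower95 = qs[, 2], upper95 = qs[, 3], rhat = rhat,
                     row.names = NULL)
  structure(list(draws = draws, summary = summ, probs = probs,
                 converged = all(rhat <= rhat_threshold, na.rm = TRUE),
                 rhat_threshold = rhat_threshold, mcmc = mcmc,
                 model = model),
            class = "posterior_summary")
}

# Pooled draws of one parameter of a posterior_summary.
#' Extract pooled posterior draws of one parameter
#'
#' @param x A `posterior_summary`.
#' @param parameter Parameter name, e.g. `"hr"`, `"delta"`, `"beta"`.
#' @return Numeric vector of all post-warmup draws across chains.
#' @export
posterior_draws <- function(x, parameter) {
  stopifnot(inherits(x, "posterior_summary"))
  pn <- dimnames(x$draws)[[3]]
  if (!parameter %in% pn)
    stop("unknown parameter '", parameter, "'; available: ",
         paste(pn, collapse = ", "))
  as.numeric(x$draws[, , parameter])
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary", if (nzchar(x$model)) paste0("(", x$model, ")"),
      "\n")
  cat(sprintf("  chains: %d  kept draws/chain: %d  converged: %s\n",
              dim(x$draws)[2], dim(x$draws)[1],
              ifelse(x$converged, "yes", sprintf("NO (Rhat > %.2f)",
                                                 x$rhat_threshold))))
  print(x$summary, digits = 4)
  if (length(x$probs)) {
    cat("  threshold probabilities:\n")
    for (i in seq_along(x$probs))
      cat(sprintf("    %s = %.4f\n", names(x$probs)[i], x$probs[i]))
  }
  invisible(x)
}
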