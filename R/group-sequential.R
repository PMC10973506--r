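#' Required number of events (Schoenfeld)
#'
#' Number of events for a two-arm survival comparison with 1:1 allocation:
#' `ceil(4 (z_{1-alpha/2} + z_{power})^2 / (log hr)^2)`.
#'
#' @param hr Target hazard ratio in (0, 1).
#' @param alpha Two-sided significance level.
#' @param power Desired power.
#' @return Integer number of events.
#' @examples
#' schoenfeld_events(0.76, 0.05, 0.82)  # 440
#' @export
schoenfeld_events <- function(hr, alpha = 0.05, power = 0.82) {
  if (!is.finite(hr) || hr <= 0 || hr >= 1)
    stop("hr must lie strictly between 0 and 1 (at hr = 1 the required ",
         "number of events is infinite)")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  ceiling(4 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
            log(hr)^2)
}

#' Lan-DeMets O'Brien-Fleming spending function
#'
#' Cumulative one-sided error spent by information fraction `t`:
#' `2 (1 - Phi(z_{1-alpha/2} / sqrt(t)))`, which equals `alpha` at
#' `t = 1`. Used for both the type-I (efficacy) and, with `alpha` set to
#' the type-II error, the futility spending schedule.
#'
#' @param t Information fraction(s) in (0, 1].
#' @param alpha One-sided error to spend in total.
#' @return Cumulative spend at each `t`.
#' @export
obf_spend <- function(t, alpha = 0.025) {
  if (any(!is.finite(t)) || any(t <= 0) || any(t > 1))
    stop("information fractions must lie in (0, 1]")
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

# --- recursive numerical integration over the Brownian-scale statistic ---
#
# State: grid x of B(t_k) values with trapezoid weights w and subdensity
# g of paths not yet stopped. Under drift theta, B has independent
# increments N(theta * dt, dt); the z statistic at look k is B_k/sqrt(t_k).

.trap_weights <- function(x) {
  n <- length(x)
  h <- x[2] - x[1]
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

# subdensity of B_1 truncated to [lo, up]
.gs_init <- function(t1, theta, lo, up, npts) {
  x <- seq(max(lo, theta * t1 - 8 * sqrt(t1)),
           min(up, theta * t1 + 8 * sqrt(t1)), length.out = npts)
  list(x = x, g = stats::dnorm(x, theta * t1, sqrt(t1)),
       w = .trap_weights(x))
}

# propagate the subdensity over an increment dt and truncate to [lo, up];
# the Gaussian transition kernel is evaluated directly (cheaper than
# dnorm on the npts^2 matrix)
.gs_step <- function(state, dt, theta, lo, up, npts) {
  mid <- theta * dt
  y <- seq(max(lo, min(state$x) + mid - 8 * sqrt(dt)),
           min(up, max(state$x) + mid + 8 * sqrt(dt)), length.out = npts)
  dev <- outer(y, state$x + mid, "-")
  K <- exp(dev * dev / (-2 * dt)) / sqrt(2 * pi * dt)
  g <- as.numeric(K %*% (state$w * state$g))
  list(x = y, g = g, w = .trap_weights(y))
}

# P(B_next > b) for paths that have not stopped, as a function of the
# B-scale bound b (vectorized via the survival of the increment)
.gs_upper_tail <- function(state, dt, theta, b) {
  sum(state$w * state$g *
        stats::pnorm((b - state$x - theta * dt) / sqrt(dt),
                     lower.tail = FALSE))
}

.gs_lower_tail <- function(state, dt, theta, b) {
  sum(state$w * state$g *
        stats::pnorm((b - state$x - theta * dt) / sqrt(dt)))
}

# Solve one-sided efficacy bounds z[k] so the incremental null crossing
# probabilities match the spending increments.
.gs_solve_upper <- function(t, incr, npts) {
  K <- length(t)
  z <- numeric(K)
  z[1] <- stats::qnorm(1 - incr[1])
  state <- .gs_init(t[1], 0, -Inf, z[1] * sqrt(t[1]), npts)
  if (K >= 2) {
    for (k in 2:K) {
      dt <- t[k] - t[k - 1]
      f <- function(c) .gs_upper_tail(state, dt, 0, c * sqrt(t[k])) - incr[k]
      z[k] <- stats::uniroot(f, c(-2, 15), tol = 1e-10)$root
      if (k < K)
        state <- .gs_step(state, dt, 0, -Inf, z[k] * sqrt(t[k]), npts)
    }
  }
  z
}

# Given efficacy bounds, solve futility bounds under drift theta against
# beta-spending increments. Returns the bounds plus a flag marking a
# drift so large that an intermediate beta-spend increment cannot be met
# below the efficacy bound (used to steer the drift calibration).
.gs_solve_lower <- function(t, z_eff, incr_b, theta, npts) {
  K <- length(t)
  zf <- numeric(K)
  capped <- FALSE
  zf[1] <- theta * sqrt(t[1]) + stats::qnorm(incr_b[1])
  if (zf[1] >= z_eff[1]) {
    zf[1] <- z_eff[1]
    if (K > 1) capped <- TRUE
  }
  state <- .gs_init(t[1], theta, zf[1] * sqrt(t[1]), z_eff[1] * sqrt(t[1]),
                    npts)
  if (K >= 2 && !capped) {
    for (k in 2:K) {
      dt <- t[k] - t[k - 1]
      f <- function(c) .gs_lower_tail(state, dt, theta, c * sqrt(t[k])) -
        incr_b[k]
      # intermediate looks: the futility bound must stay below the
      # efficacy bound; at the final look the spend equation is solved
      # unconstrained so the drift calibration sees a monotone mismatch
      hi <- if (k < K) z_eff[k] else z_eff[k] + 8
      if (f(hi) < 0) {
        zf[k] <- hi
        capped <- TRUE
        break
      }
      zf[k] <- stats::uniroot(f, c(-15, hi), tol = 1e-10)$root
      if (k < K)
        state <- .gs_step(state, dt, theta, zf[k] * sqrt(t[k]),
                          z_eff[k] * sqrt(t[k]), npts)
    }
  }
  list(z = zf, capped = capped)
}

#' Solve group-sequential efficacy and futility boundaries
#'
#' Solves the one-sided efficacy z boundaries of a Lan-DeMets
#' O'Brien-Fleming design by recursive numerical integration over the
#' correlated Gaussian increments (trapezoid rule, grid half-width 8 SD,
#' `grid_points` points), so that each incremental null crossing
#' probability equals the alpha-spend increment. With `futility = TRUE`,
#' non-binding futility bounds are solved against a beta-spending
#' function of the same O'Brien-Fleming form under the design
#' alternative: the standardized drift `theta` (the expected final-look z
#' statistic) is calibrated so the futility bound meets the efficacy
#' bound at the final look, and the implied number of events is
#' `ceil((2 theta / |log hr|)^2)` for 1:1 allocation - the
#' interim-monitoring inflation over the fixed-design event count.
#' Without futility, `theta` is calibrated so the efficacy boundary alone
#' achieves power `1 - beta_err`.
#'
#' @param t Strictly increasing information fractions ending at 1
#'   (at most 25 looks).
#' @param alpha One-sided type-I error.
#' @param beta_err Type-II error (1 - power).
#' @param hr Design hazard ratio (< 1) defining the drift; may be `NULL`
#'   when neither futility bounds nor event counts are needed.
#' @param futility Solve non-binding futility bounds as well?
#' @param grid_points Integration grid size (>= 4001 recommended).
#' @return An object of class `gs_design`: information fractions,
#'   spending increments, `z_eff`, `z_fut` (or `NULL`), drift, total and
#'   per-look events, and hazard-ratio-scale bounds.
#' @export
solve_boundaries <- function(t, alpha = 0.025, beta_err = 0.18, hr = NULL,
                             futility = FALSE, grid_points = 4001) {
  t <- as.numeric(t)
  K <- length(t)
  if (K < 1 || K > 25) stop("between 1 and 25 looks are supported")
  if (is.unsorted(t, strictly = TRUE) || t[1] <= 0 ||
      abs(t[K] - 1) > 1e-8)
    stop("information fractions must be strictly increasing and end at 1")
  spend_a <- obf_spend(t, alpha)
  incr_a <- diff(c(0, spend_a))
  z_eff <- .gs_solve_upper(t, incr_a, grid_points)
  z_fut <- NULL
  theta <- NA_real_
  d_total <- NA_real_
  if (futility && is.null(hr))
    stop("futility bounds require a design hazard ratio")
  if (!is.null(hr)) {
    if (hr <= 0 || hr >= 1) stop("hr must lie strictly between 0 and 1")
    if (futility) {
      spend_b <- obf_spend(t, beta_err)
      incr_b <- diff(c(0, spend_b))
      mismatch <- function(th) {
        sol <- .gs_solve_lower(t, z_eff, incr_b, th, grid_points)
        if (sol$capped) return(10)  # drift too large
        sol$z[K] - z_eff[K]
      }
      theta <- stats::uniroot(mismatch, c(0.5, 8), tol = 1e-7)$root
      z_fut <- .gs_solve_lower(t, z_eff, incr_b, theta, grid_points)$z
      z_fut[K] <- z_eff[K]
    } else {
      pow <- function(th) {
        pr <- .gs_cross_upper(t, z_eff, th, grid_points)
        sum(pr) - (1 - beta_err)
      }
      theta <- stats::uniroot(pow, c(0.5, 8), tol = 1e-7)$root
    }
    d_total <- ceiling((2 * theta / abs(log(hr)))^2)
  }
  d_k <- if (is.na(d_total)) rep(NA_real_, K) else t * d_total
  structure(list(K = K, t = t, alpha = alpha, beta_err = beta_err,
                 hr = hr, theta = theta,
                 spend_alpha = spend_a,
                 spend_beta = if (futility) obf_spend(t, beta_err) else NULL,
                 z_eff = z_eff, z_fut = z_fut,
                 d_total = d_total, d_k = d_k,
                 hr_eff = if (!is.na(d_total)) z_to_hr(z_eff, d_k) else NULL,
                 hr_fut = if (!is.null(z_fut) && !is.na(d_total))
                   z_to_hr(z_fut, d_k) else NULL,
                 spending = "Lan-DeMets O'Brien-Fleming",
                 grid_points = grid_points),
            class = "gs_design")
}

# per-look upper-crossing probabilities under drift theta
.gs_cross_upper <- function(t, z, theta, npts) {
  K <- length(t)
  p <- numeric(K)
  p[1] <- stats::pnorm(z[1] - theta * sqrt(t[1]), lower.tail = FALSE)
  if (K >= 2) {
    state <- .gs_init(t[1], theta, -Inf, z[1] * sqrt(t[1]), npts)
    for (k in 2:K) {
      dt <- t[k] - t[k - 1]
      p[k] <- .gs_upper_tail(state, dt, theta, z[k] * sqrt(t[k]))
      if (k < K)
        state <- .gs_step(state, dt, theta, -Inf, z[k] * sqrt(t[k]), npts)
    }
  }
  p
}

#' Boundary crossing probabilities of a group-sequential design
#'
#' First-crossing probabilities of the efficacy boundary at each look,
#' and their cumulative sum, under a given standardized drift
#' (`E[Z_K] = theta` at full information; `theta = 0` is the null, under
#' which the cumulative probability equals the design alpha). Computed by
#' the same recursive numerical integration as the boundary solver;
#' futility bounds are ignored (non-binding).
#'
#' @param design A `gs_design` from [solve_boundaries()].
#' @param drift Standardized drift `theta`.
#' @return Data frame with `look`, `t`, `z`, `p_cross`, `cumulative`.
#' @export
boundary_crossing_probs <- function(design, drift = 0) {
  stopifnot(inherits(design, "gs_design"))
  p <- .gs_cross_upper(design$t, design$z_eff, drift, design$grid_points)
  data.frame(look = seq_len(design$K), t = design$t, z = design$z_eff,
             p_cross = p, cumulative = cumsum(p))
}

#' Convert a z boundary to the hazard-ratio scale
#'
#' For a 1:1 allocation survival comparison with `events` observed
#' events, a z-scale bound corresponds to `exp(-2 z / sqrt(events))`
#' (benefit direction HR < 1).
#'
#' @param z z-scale boundary value(s).
#' @param events Number of events (> 0); recycled against `z`.
#' @return Hazard-ratio-scale bound(s).
#' @export
z_to_hr <- function(z, events) {
  if (any(!is.finite(events)) || any(events <= 0))
    stop("events must be > 0")
  exp(-2 * z / sqrt(events))
}

#' @export
print.gs_design <- function(x, ...) {
  cat(sprintf("Group-sequential design: %d looks, one-sided alpha %.4g, %s spending\n",
              x$K, x$alpha, x$spending))
  df <- data.frame(look = seq_len(x$K), t = x$t,
                   alpha_spent = x$spend_alpha, z_eff = x$z_eff)
  if (!is.null(x$z_fut)) df$z_fut <- x$z_fut
  if (!is.null(x$hr_eff)) df$hr_eff <- x$hr_eff
  if (!is.null(x$hr_fut)) df$hr_fut <- x$hr_fut
  print(df, digits = 4, row.names = FALSE)
  if (!is.na(x$d_total))
    cat(sprintf("  drift %.4f; %d events at the final look (design HR %.2f, type-II error %.2f)\n",
                x$theta, x$d_total, x$hr, x$beta_err))
  invisible(x)
}

#' Simulated operating characteristics of the log-rank test
#'
#' Simulates two-arm exponential trials with 1:1 allocation and a common
#' administrative censoring time calibrated so the expected total number
#' of events equals `total_events`, applies the two-sided log-rank test,
#' and returns the rejection fraction. Under the design alternative this
#' estimates power; under `hr = 1` it estimates the type-I error rate.
#'
#' @param hr True hazard ratio (experimental vs control).
#' @param total_events Expected total number of events per trial.
#' @param alpha Two-sided significance level.
#' @param nsim Number of simulated trials (>= 1000).
#' @param seed Integer seed.
#' @param n_total Total number of patients (1:1); must exceed
#'   `total_events`.
#' @return A list with `rejection`, its binomial Monte-Carlo standard
#'   error `mc_se`, and `nsim`.
#' @export
simulate_logrank_operating_chars <- function(hr, total_events = 441,
                                             alpha = 0.05, nsim = 10000,
                                             seed = 1L, n_total = 800) {
  if (hr <= 0) stop("hr must be > 0")
  if (nsim < 1000) stop("use at least 1000 simulated trials")
  n_arm <- floor(n_total / 2)
  if (total_events >= 2 * n_arm)
    stop("total_events must be below the number of patients")
  # censoring time (control rate 1) giving the target expected events
  expected <- function(tau)
    n_arm * (1 - exp(-tau)) + n_arm * (1 - exp(-hr * tau))
  tau <- stats::uniroot(function(x) expected(x) - total_events,
                        c(1e-6, 1e3), tol = 1e-10)$root
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  grp <- rep(0:1, each = n_arm)
  rej <- logical(nsim)
  for (s in seq_len(nsim)) {
    tt <- c(stats::rexp(n_arm, 1), stats::rexp(n_arm, hr))
    status <- tt <= tau
    tt <- pmin(tt, tau)
    sd <- survival::survdiff(survival::Surv(tt, status) ~ grp)
    rej[s] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE) < alpha
  }
  r <- mean(rej)
  list(rejection = r, mc_se = sqrt(r * (1 - r) / nsim), nsim = nsim)
}
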