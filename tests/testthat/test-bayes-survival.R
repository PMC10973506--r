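test_that("Weibull log likelihood matches hand-evaluated cases", {
  one <- function(t, ev) trial_dataset(make_records(1, efs_time = t,
                                                    efs_event = ev,
                                                    arm = "control"))
  par <- list(nu = 1, mu_c = log(0.5), beta = 0)
  # event at t = 2, unit shape: log(0.5) - 2 * 0.5
  expect_equal(weibull_loglik(par, one(2, TRUE)), log(0.5) - 1,
               tolerance = 1e-12)
  # censored at t = 2: survivor term only
  expect_equal(weibull_loglik(par, one(2, FALSE)), -1, tolerance = 1e-12)
  bad <- make_records(1, efs_time = -1, arm = "control")
  expect_error(weibull_loglik(par, bad), "negative")

  # additivity over subjects
  set.seed(1)
  rec <- make_records(10, arm = rep(c("experimental", "control"), 5),
                      efs_time = rexp(10, 0.3) + 0.02,
                      efs_event = rep(c(TRUE, FALSE), 5))
  par2 <- list(nu = 1.3, mu_c = -2, beta = -0.2)
  total <- weibull_loglik(par2, trial_dataset(rec))
  each <- vapply(seq_len(10), function(i)
    weibull_loglik(par2, trial_dataset(rec[i, ])), 1.0)
  expect_equal(total, sum(each), tolerance = 1e-10)
})

test_that("Gelman-Rubin diagnostic reproduces hand-worked values", {
  expect_equal(gelman_rubin(cbind(c(1, 2, 3, 4), c(3, 4, 5, 6))),
               sqrt(1.95), tolerance = 1e-12)
  # identical chains: B = 0, Rhat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(3 / 4), tolerance = 1e-12)
  set.seed(10)
  expect_equal(gelman_rubin(matrix(rnorm(20000), ncol = 2)), 1,
               tolerance = 0.01)
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal lengths")
})

test_that("threshold probabilities count draws below each cut", {
  expect_equal(unname(threshold_probs(rep(0.5, 10), c(0.76, 1))), c(1, 1))
  expect_equal(unname(threshold_probs(c(0.7, 0.8, 0.9, 1.05))),
               c(0.25, 0.5, 0.75))
  # symmetric log draws put exactly half the mass below HR = 1
  expect_equal(unname(threshold_probs(exp(c(-2, -1, 1, 2)), 1)), 0.5)
  th <- threshold_probs(exp(rnorm(500, 0, 0.5)), c(0.5, 0.76, 1, 1.3))
  expect_true(all(diff(th) >= 0))
  expect_error(threshold_probs(numeric(0)), "non-empty")
})

test_that("a null trial yields a posterior centred on HR = 1", {
  cfg <- trial_config(n_experimental = 2000, n_control = 2000,
                      n_historical = 0, weibull_shape = 1,
                      accrual_rate = 100, milestones = integer(0),
                      p_death60 = c(experimental = 0, control = 0,
                                    historical = 0))
  d <- cut_at_milestone(generate_trial(cfg, seed = 23), 4000)
  f <- fit_weibull_borrow(d, borrow_config("none"), quick_mcmc(seed = 14))
  expect_true(f$converged)
  hr_med <- posterior_median(f, "hr")
  expect_gt(hr_med, 0.9)
  expect_lt(hr_med, 1.1)
  p1 <- unname(f$probs[["P(HR<1)"]])
  expect_gt(p1, 0.3)
  expect_lt(p1, 0.7)
})

test_that("with unit shape the rate posterior matches the gamma conjugate", {
  cfg <- trial_config(n_experimental = 300, n_control = 300,
                      n_historical = 0, weibull_shape = 1,
                      milestones = integer(0))
  d <- cut_at_milestone(generate_trial(cfg, seed = 5), 600)
  f <- fit_weibull_borrow(d, borrow_config("none"),
                          quick_mcmc(seed = 6, n_iter = 20000),
                          fix_shape = 1)
  lam <- exp(posterior_draws(f, "mu_c"))
  ctrl <- d$records[d$records$arm == "control" &
                      d$records$source == "current", ]
  D <- sum(ctrl$efs_event)
  exposure <- sum(pmax(ctrl$efs_time, 0.01))
  expect_equal(mean(lam) / (D / exposure), 1, tolerance = 0.02)
  expect_equal(sd(lam) / (sqrt(D) / exposure), 1, tolerance = 0.02)
})

test_that("commensurate limits reproduce the no-borrow and pooled fits", {
  # mature follow-up keeps the posterior tight enough that the 0.02
  # limit tolerances are dominated by model agreement, not MC error
  cfg <- trial_config(n_experimental = 400, n_control = 400,
                      n_historical = 400, accrual_rate = 10,
                      milestones = c(400))
  d <- cut_at_milestone(generate_trial(cfg, seed = 11), 800)
  qm <- quick_mcmc(seed = 7, n_iter = 12000)
  f_inf <- fit_weibull_borrow(d, borrow_config("fixed", sigma_tau = 100), qm)
  f_none <- fit_weibull_borrow(d, borrow_config("none"), qm)
  expect_lt(abs(posterior_median(f_inf, "beta") -
                  posterior_median(f_none, "beta")), 0.02)
  f_zero <- fit_weibull_borrow(d, borrow_config("fixed", sigma_tau = 1e-4),
                               qm)
  r <- d$records
  r$source[r$source == "historical"] <- "current"
  f_pool <- fit_weibull_borrow(trial_dataset(r), borrow_config("none"), qm)
  expect_lt(abs(posterior_median(f_zero, "mu_c") -
                  posterior_median(f_pool, "mu_c")), 0.02)
  expect_lt(abs(posterior_median(f_zero, "beta") -
                  posterior_median(f_pool, "beta")), 0.02)
})

test_that("credible intervals shrink as the trial grows", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    cfg <- trial_config(n_experimental = n, n_control = n,
                        n_historical = 0, accrual_rate = n / 18,
                        milestones = integer(0))
    d <- cut_at_milestone(generate_trial(cfg, seed = 40 + n), 2 * n)
    f <- suppressWarnings(
      fit_weibull_borrow(d, borrow_config("none"),
                         quick_mcmc(seed = 50 + n, n_iter = 3000)))
    s <- f$summary[f$summary$parameter == "hr", ]
    s$upper95 - s$lower95
  }, 1.0)
  expect_true(all(diff(widths) < 0))
})

test_that("an event-free arm is reported by name", {
  rec <- rbind(make_records(5, arm = "experimental", efs_time = 2,
                            efs_event = FALSE, prefix = "E"),
               make_records(5, arm = "control", efs_time = 2,
                            efs_event = TRUE, prefix = "K"))
  expect_error(fit_weibull_borrow(trial_dataset(rec),
                                  borrow_config("none"), quick_mcmc()),
               "no events in the experimental arm")
})

test_that("the sampler targets the stated posterior on a small dataset", {
  # dense-grid quadrature oracle over (log nu, mu_c, beta) on 20 subjects
  set.seed(99)
  rec <- make_records(20, arm = rep(c("experimental", "control"), each = 10),
                      efs_time = round(rexp(20, 0.08), 2) + 0.05,
                      efs_event = rep(c(TRUE, FALSE), 10))
  d <- trial_dataset(rec)
  st <- bayesinterim:::.weib_stats(d$records)
  lnu_g <- seq(-1.5, 1.5, length.out = 61)
  mu_g <- seq(-7, 0, length.out = 101)
  be_g <- seq(-4, 4, length.out = 121)
  logpost <- array(0, c(61, 101, 121))
  for (i in seq_along(lnu_g)) {
    nu <- exp(lnu_g[i])
    S <- vapply(st$times, function(tt) sum(tt^nu), 1.0)
    for (j in seq_along(mu_g)) {
      ll <- vapply(be_g, function(b)
        bayesinterim:::.weib_ll(nu, c(experimental = mu_g[j] + b,
                                      control = mu_g[j], historical = 0),
                                st, S = S), 1.0)
      logpost[i, j, ] <- ll + dnorm(lnu_g[i], 0, 10, log = TRUE) +
        dnorm(mu_g[j], 0, 10, log = TRUE) + dnorm(be_g, 0, 10, log = TRUE)
    }
  }
  w <- exp(logpost - max(logpost))
  marg <- apply(w, 3, sum)
  cdf_grid <- cumsum(marg / sum(marg))
  f <- fit_weibull_borrow(d, borrow_config("none"),
                          quick_mcmc(seed = 3, n_iter = 20000))
  bd <- sort(posterior_draws(f, "beta"))
  cdf_at <- approx(be_g, cdf_grid, xout = bd, rule = 2)$y
  ks <- max(abs(cdf_at - seq_along(bd) / length(bd)))
  expect_lt(ks, 0.05)
})

test_that("the posterior recovers a simulated benefit and tracks the ML fit", {
  # single mature-follow-up replicate; the 20-replicate coverage
  # experiment lives in the acceptance suite
  hr_true <- 0.76
  mu <- log(-log(0.44) / 48^1.2)
  cfg <- trial_config(n_experimental = 800, n_control = 800,
                      n_historical = 0, weibull_shape = 1.2,
                      accrual_rate = 10, milestones = integer(0),
                      mu_experimental = mu + log(hr_true), mu_control = mu,
                      p_death60 = c(experimental = 0, control = 0,
                                    historical = 0))
  d <- cut_at_milestone(generate_trial(cfg, seed = 1009), 1600)
  f <- fit_weibull_borrow(d, borrow_config("none"),
                          quick_mcmc(seed = 2009, n_iter = 6000))
  s <- f$summary[f$summary$parameter == "hr", ]
  expect_lt(s$lower95, hr_true)
  expect_gt(s$upper95, hr_true)
  r <- d$records
  sr <- survival::survreg(
    survival::Surv(pmax(efs_time, 0.01), efs_event) ~
      I(arm == "experimental"), data = r, dist = "weibull")
  hr_ml <- exp(-coef(sr)[2] / sr$scale)
  expect_equal(s$median, unname(hr_ml), tolerance = 0.03)
})
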