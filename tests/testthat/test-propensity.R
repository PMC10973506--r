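# independently coded IRLS for the logistic propensity model, used as an
# oracle for the fitted coefficients
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    z <- eta + (y - p) / W
    b_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(b_new - b)) < tol) return(as.numeric(b_new))
    b <- as.numeric(b_new)
  }
  as.numeric(b)
}

ctrl_records <- function(age_cur, age_hist, eln_cur = NULL, eln_hist = NULL) {
  nc <- length(age_cur); nh <- length(age_hist)
  rbind(make_records(nc, source = "current", age = age_cur,
                     eln = if (is.null(eln_cur)) "favorable" else eln_cur,
                     prefix = "C"),
        make_records(nh, source = "historical", age = age_hist,
                     eln = if (is.null(eln_hist)) "favorable" else eln_hist,
                     prefix = "H"))
}

test_that("identical covariates give propensity 0.5 everywhere", {
  rec <- ctrl_records(rep(50, 6), rep(50, 6))
  m <- fit_propensity(rec)
  expect_true(all(abs(m$scores - 0.5) < 1e-6))
})

test_that("complete separation is detected and reported", {
  rec <- ctrl_records(c(50, 60), c(20, 30))
  expect_error(fit_propensity(rec), "separation")
  expect_error(fit_propensity(make_records(4, source = "current")),
               "both current and historical")
})

test_that("coefficients match an independent IRLS oracle", {
  set.seed(42)
  rec <- ctrl_records(c(30, 41, 48, 55), c(25, 36, 44, 60),
                      eln_cur = c("favorable", "intermediate", "adverse",
                                  "favorable"),
                      eln_hist = c("intermediate", "favorable", "adverse",
                                   "intermediate"))
  m <- fit_propensity(rec)
  age_z <- (rec$age - mean(rec$age)) / sd(rec$age)
  X <- cbind(1, age_z, as.numeric(rec$eln_risk == "intermediate"),
             as.numeric(rec$eln_risk == "adverse"))
  b_oracle <- irls_logistic(X, as.numeric(rec$source == "current"))
  expect_equal(unname(m$coefficients), b_oracle, tolerance = 1e-6)
})

test_that("greedy matching picks nearest neighbors in score order", {
  m <- structure(list(
    scores = c(C1 = 0.2, C2 = 0.5, C3 = 0.9,
               H1 = 0.1, H2 = 0.45, H3 = 0.8, H4 = 0.95),
    balance_data = data.frame(
      id = c("C1", "C2", "C3", "H1", "H2", "H3", "H4"),
      source = rep(c("current", "historical"), c(3, 4)),
      age = c(30, 40, 50, 29, 41, 49, 51),
      eln_risk = "favorable", stringsAsFactors = FALSE)),
    class = "match_result")
  out <- greedy_match(m, 3)
  got <- setNames(out$pairs$historical_id, out$pairs$current_id)
  expect_identical(got[c("C3", "C2", "C1")], c(C3 = "H4", C2 = "H2",
                                               C1 = "H1"))
  expect_error(greedy_match(m, 4), "exceeds available")
})

test_that("tied scores fall back to the lowest historical id", {
  m <- structure(list(
    scores = c(C1 = 0.5, C2 = 0.5, H9 = 0.5, H2 = 0.5, H5 = 0.5),
    balance_data = data.frame(
      id = c("C1", "C2", "H9", "H2", "H5"),
      source = rep(c("current", "historical"), c(2, 3)),
      age = 40, eln_risk = "favorable", stringsAsFactors = FALSE)),
    class = "match_result")
  out <- greedy_match(m, 2)
  # current processed by id at equal scores; each takes the lowest
  # remaining historical id
  expect_identical(out$pairs$current_id, c("C1", "C2"))
  expect_identical(out$pairs$historical_id, c("H2", "H5"))
})

test_that("matching output is invariant to input row order", {
  d <- generate_trial(small_config(), seed = 9)
  m1 <- greedy_match(fit_propensity(d), 100)
  shuffled <- d$records[sample(nrow(d$records)), ]
  m2 <- greedy_match(fit_propensity(shuffled), 100)
  p1 <- m1$pairs[order(m1$pairs$current_id), ]
  p2 <- m2$pairs[order(m2$pairs$current_id), ]
  expect_equal(p1$historical_id, p2$historical_id)
})

test_that("full-scale matching returns exactly the requested 300 pairs", {
  d <- generate_trial(trial_config(), seed = 4)
  m <- greedy_match(fit_propensity(d), 300)
  expect_equal(nrow(m$pairs), 300L)
  expect_equal(anyDuplicated(m$pairs$historical_id), 0L)
  expect_equal(anyDuplicated(m$pairs$current_id), 0L)
  expect_named(m$pairs, c("current_id", "historical_id", "score_current",
                          "score_historical"))
})

test_that("matching improves age balance under a shifted historical cohort", {
  # historical cohort systematically older: a well-specified score model
  # should not worsen the age standardized mean difference on average
  smds <- t(vapply(1:20, function(s) {
    set.seed(300 + s)
    rec <- ctrl_records(runif(120, 18, 58), runif(200, 28, 65))
    m <- greedy_match(fit_propensity(rec), 100)
    age <- m$balance[m$balance$covariate == "age", ]
    c(before = abs(age$smd_before), after = abs(age$smd_after))
  }, c(before = 1.0, after = 1.0)))
  expect_lt(mean(smds[, "after"]), mean(smds[, "before"]))
})
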