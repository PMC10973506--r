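#' Deterministic per-interim seed
#'
#' Interim k of a schedule run with master seed s uses
#' `(s + 99991 * k) mod (2^31 - 2) + 1`, so a single interim can be
#' re-run in isolation and reproduce the scheduled run exactly.
#'
#' @param master_seed Master integer seed.
#' @param k Interim index (1-based).
#' @return Integer seed below 2^31.
#' @export
interim_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) + 99991 * k) %% 2147483646) + 1L
}

.binary_endpoints <- c("cr", "mrd", "death60", "ae45")

# endpoint counts per cohort from a (cut) record table
.endpoint_counts <- function(records, endpoint) {
  grp <- ifelse(records$source == "historical", "hist",
                ifelse(records$arm == "experimental", "exp", "ctrl"))
  cnt <- function(g) {
    r <- records[grp == g, , drop = FALSE]
    switch(endpoint,
           cr = c(y = sum(r$cr), n = nrow(r)),
           mrd = {
             den <- r$cr & !is.na(r$mrd_negative)
             c(y = sum(r$mrd_negative[den]), n = sum(den))
           },
           death60 = c(y = sum(r$death60), n = nrow(r)),
           ae45 = c(y = sum(r$ae_grade45), n = nrow(r)),
           stop("unknown endpoint ", endpoint))
  }
  e <- cnt("exp"); c0 <- cnt("ctrl"); h <- cnt("hist")
  binary_counts(e["y"], e["n"], c0["y"], c0["n"], h["y"], h["n"])
}

.endpoint_summary <- function(fit, harm = FALSE) {
  s <- fit$summary
  d <- s[s$parameter == "delta", ]
  list(status = "ok",
       delta_median = d$median, delta_ci = c(d$lower95, d$upper95),
       prob_delta_gt_0 = unname(fit$probs[["P(delta>0)"]]),
       harm_direction = harm, converged = fit$converged,
       rhat_max = max(s$rhat, na.rm = TRUE))
}

.efs_summary <- function(fit) {
  s <- fit$summary
  h <- s[s$parameter == "hr", ]
  list(status = "ok",
       hr_median = h$median, hr_ci = c(h$lower95, h$upper95),
       probs = fit$probs, converged = fit$converged,
       rhat_max = max(s$rhat, na.rm = TRUE))
}

.failed_endpoint <- function(e) list(status = "error",
                                     message = conditionMessage(e))

#' Run the scheduled interim benefit-risk assessment
#'
#' For each enrollment milestone: cuts the data at the milestone
#' ([cut_at_milestone()]), restricts the historical cohort to the matched
#' set, fits the Bayesian Weibull EFS model ([fit_weibull_borrow()]) and
#' the four beta-binomial endpoint models ([fit_binary_borrow()]; CR,
#' MRD-negative CR among assessed CR patients, 60-day mortality, grade
#' 4-5 adverse events), and assembles an interim report with posterior
#' medians, 95% credible intervals, hazard-ratio threshold probabilities
#' and benefit/harm probabilities. Matching is performed once on the full
#' dataset and reused at every interim unless `rematch_each = TRUE`. The
#' run is deterministic given the master seed in `mcmc`: interim k uses
#' [interim_seed()] and each endpoint a fixed offset from it. A model
#' failure on one endpoint is recorded in the report (status `"error"`)
#' without aborting the other endpoints; an infeasible milestone aborts.
#'
#' An advisory futility flag fires when the posterior probability of the
#' design benefit, `P(HR < futility_threshold)`, falls below
#' `futility_prob`; no binding stopping rule is imposed.
#'
#' @param data A full [trial_dataset()].
#' @param pairs A `match_result` with pairs filled in (from
#'   [greedy_match()]), or `NULL` to use all historical subjects.
#' @param milestones Strictly increasing enrollment counts.
#' @param borrow A [borrow_config()].
#' @param mcmc An [mcmc_config()]; its seed is the master seed.
#' @param endpoints Endpoints to analyse (subset of
#'   `c("efs", "cr", "mrd", "death60", "ae45")`).
#' @param futility_threshold Hazard-ratio threshold of the advisory flag.
#' @param futility_prob Probability cutoff of the advisory flag.
#' @param rematch_each Recompute propensity matching on each cut dataset
#'   (same pair count as `pairs`) instead of reusing the full-data match.
#' @return A list of `interim_report` objects, one per milestone.
#' @export
run_interim_schedule <- function(data, pairs = NULL,
                                 milestones = data$config$milestones,
                                 borrow = borrow_config("adaptive"),
                                 mcmc = mcmc_config(),
                                 endpoints = c("efs", .binary_endpoints),
                                 futility_threshold = 0.76,
                                 futility_prob = 0.05,
                                 rematch_each = FALSE) {
  stopifnot(inherits(data, "trial_dataset"))
  if (is.unsorted(milestones, strictly = TRUE))
    stop("milestones must be strictly increasing")
  endpoints <- match.arg(endpoints, c("efs", .binary_endpoints),
                         several.ok = TRUE)
  reports <- vector("list", length(milestones))
  for (k in seq_along(milestones)) {
    cut <- cut_at_milestone(data, milestones[k])
    r <- cut$records
    if (borrow$mode == "none") {
      r <- r[r$source != "historical", , drop = FALSE]
    } else if (rematch_each && !is.null(pairs)) {
      m <- greedy_match(fit_propensity(r), nrow(pairs$pairs))
      keep_h <- m$pairs$historical_id
      r <- r[r$source != "historical" | r$id %in% keep_h, , drop = FALSE]
    } else if (!is.null(pairs) && !is.null(pairs$pairs)) {
      keep_h <- pairs$pairs$historical_id
      r <- r[r$source != "historical" | r$id %in% keep_h, , drop = FALSE]
    }
    seed_k <- interim_seed(mcmc$seed, k)
    cutdat <- trial_dataset(r, config = cut$config,
                            calendar_now = cut$calendar_now,
                            median_followup = cut$median_followup)
    efs <- NULL
    if ("efs" %in% endpoints) {
      mk <- mcmc
      mk$seed <- seed_k
      efs <- tryCatch(.efs_summary(
        fit_weibull_borrow(cutdat, borrow = borrow, mcmc = mk,
                           thresholds = sort(unique(c(0.76, 0.87, 1,
                                                      futility_threshold))))),
        error = .failed_endpoint)
    }
    bin <- list()
    for (j in seq_along(.binary_endpoints)) {
      ep <- .binary_endpoints[j]
      if (!ep %in% endpoints) next
      mk <- mcmc
      mk$seed <- interim_seed(seed_k, j)
      bin[[ep]] <- tryCatch({
        cnts <- .endpoint_counts(r, ep)
        .endpoint_summary(fit_binary_borrow(cnts, borrow = borrow,
                                            mcmc = mk),
                          harm = ep %in% c("death60", "ae45"))
      }, error = .failed_endpoint)
    }
    fut <- NA
    if (!is.null(efs) && identical(efs$status, "ok")) {
      pb <- efs$probs[[sprintf("P(HR<%g)", futility_threshold)]]
      fut <- pb < futility_prob
    }
    reports[[k]] <- structure(
      list(interim = k, milestone = milestones[k],
           calendar_cutoff = cut$calendar_now,
           median_followup = cut$median_followup,
           n_current = sum(r$source == "current"),
           n_historical = sum(r$source == "historical"),
           efs_events = sum(r$efs_event[r$source == "current"]),
           efs = efs, binary = bin,
           borrow_mode = borrow$mode,
           futility_flag = fut,
           futility_threshold = futility_threshold,
           futility_prob = futility_prob,
           seed = seed_k),
      class = "interim_report")
  }
  reports
}

#' Interim schedule without external data
#'
#' Runs [run_interim_schedule()] with historical subjects dropped and
#' borrowing disabled - the concurrent-randomization-only Bayesian
#' analysis used to gauge the impact of the external data.
#'
#' @inheritParams run_interim_schedule
#' @return A list of `interim_report` objects.
#' @export
run_without_borrowing <- function(data, milestones = data$config$milestones,
                                  mcmc = mcmc_config(),
                                  endpoints = c("efs", .binary_endpoints),
                                  futility_threshold = 0.76,
                                  futility_prob = 0.05) {
  run_interim_schedule(data, pairs = NULL, milestones = milestones,
                       borrow = borrow_config("none"), mcmc = mcmc,
                       endpoints = endpoints,
                       futility_threshold = futility_threshold,
                       futility_prob = futility_prob)
}

#' Combined interim summary table
#'
#' Flattens a list of interim reports into one row per interim and
#' endpoint: posterior median, 95% credible interval and the probability
#' of benefit (for EFS, `P(HR < 1)`; for binary efficacy endpoints,
#' `P(delta > 0)`; for safety endpoints the reported probability is of
#' excess harm under the same convention).
#'
#' @param reports List of `interim_report` objects.
#' @return Data frame with columns `interim`, `endpoint`, `median`,
#'   `lo95`, `hi95`, `prob_benefit`.
#' @export
interim_summary_table <- function(reports) {
  rows <- list()
  for (rep in reports) {
    if (!is.null(rep$efs) && identical(rep$efs$status, "ok"))
      rows[[length(rows) + 1L]] <-
        data.frame(interim = rep$interim, endpoint = "efs",
                   median = rep$efs$hr_median,
                   lo95 = rep$efs$hr_ci[1], hi95 = rep$efs$hr_ci[2],
                   prob_benefit = unname(rep$efs$probs[["P(HR<1)"]]))
    for (ep in names(rep$binary)) {
      b <- rep$binary[[ep]]
      if (!identical(b$status, "ok")) next
      rows[[length(rows) + 1L]] <-
        data.frame(interim = rep$interim, endpoint = ep,
                   median = b$delta_median,
                   lo95 = b$delta_ci[1], hi95 = b$delta_ci[2],
                   prob_benefit = b$prob_delta_gt_0)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.interim_report <- function(x, ...) {
  cat(sprintf("Interim %d (milestone %d): cutoff %.2f months, median follow-up %.2f months\n",
              x$interim, x$milestone, x$calendar_cutoff, x$median_followup))
  cat(sprintf("  %d current patients (%d EFS events), %d historical controls, borrowing: %s\n",
              x$n_current, x$efs_events, x$n_historical, x$borrow_mode))
  if (!is.null(x$efs)) {
    if (identical(x$efs$status, "ok")) {
      cat(sprintf("  EFS: median HR %.3f (95%% CrI %.3f-%.3f)\n",
                  x$efs$hr_median, x$efs$hr_ci[1], x$efs$hr_ci[2]))
      for (i in seq_along(x$efs$probs))
        cat(sprintf("    %s = %.4f\n", names(x$efs$probs)[i], x$efs$probs[i]))
    } else cat("  EFS: ERROR -", x$efs$message, "\n")
  }
  for (ep in names(x$binary)) {
    b <- x$binary[[ep]]
    if (identical(b$status, "ok")) {
      cat(sprintf("  %s: median delta %+.3f (95%% CrI %+.3f to %+.3f), P(delta>0) = %.4f%s\n",
                  ep, b$delta_median, b$delta_ci[1], b$delta_ci[2],
                  b$prob_delta_gt_0,
                  if (b$harm_direction) " [excess harm]" else ""))
    } else cat(sprintf("  %s: ERROR - %s\n", ep, b$message))
  }
  if (!is.na(x$futility_flag) && x$futility_flag)
    cat(sprintf("  ADVISORY: futility signal (P(HR<%g) < %g)\n",
                x$futility_threshold, x$futility_prob))
  invisible(x)
}
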