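#' Configuration of a synthetic two-arm trial with a historical cohort
#'
#' Describes the statistical structure of a randomized induction trial in
#' adults (18-65 years) with newly diagnosed AML, together with an external
#' historical control cohort from a preceding trial: arm sizes, staggered
#' accrual, Weibull event-free survival (EFS), ELN 2017 genetic risk mix,
#' and binary response/safety endpoint rates. Defaults emulate a trial of
#' 388 experimental vs 392 control patients with a 426-patient historical
#' control cohort, ~22 patients/month accrual, 4-year EFS of 44% in both
#' concurrent arms and 36% historically, and endpoint rates taken from the
#' corresponding patient tables (CR after two cycles ~82/87/85%, 60-day
#' mortality ~6.7/5.4/8.0%, grade 4-5 adverse events ~30/29/28%).
#'
#' Event times follow a Weibull proportional-hazards model with shape
#' `weibull_shape` (nu) and cumulative hazard `t^nu * exp(mu)`; `mu_*` are
#' the per-group log baseline rates. When a `mu` is `NULL` it is derived
#' from the corresponding 4-year EFS value via
#' `mu = log(-log(S(48)) / 48^nu)` (time unit: months).
#'
#' @param n_experimental,n_control,n_historical Cohort sizes (>= 0).
#' @param accrual_rate Concurrent-trial accrual, patients/month (> 0);
#'   enrollment times are i.i.d. uniform over the implied accrual window.
#' @param weibull_shape Weibull shape nu > 0 shared by all groups.
#' @param mu_experimental,mu_control,mu_historical Log baseline event
#'   rates; derived from `efs4y` when `NULL`.
#' @param efs4y Named vector of 4-year EFS probabilities used to derive
#'   the `mu`'s.
#' @param p_cr Probability of complete remission (CR) after two induction
#'   cycles, per group (experimental, control, historical).
#' @param p_mrd_neg_given_cr Probability of MRD negativity among CR
#'   patients with an MRD assessment, per group.
#' @param p_death60 Probability of death within 60 days (2 months) of
#'   treatment start, per group.
#' @param p_ae45 Probability of a grade 4-5 adverse event, per group.
#' @param eln_probs ELN 2017 risk category probabilities
#'   (favorable, intermediate, adverse); must sum to 1.
#' @param mrd_missing Fraction of CR patients with a missing MRD
#'   assessment, for current and historical subjects.
#' @param milestones Increasing enrollment counts at which interim
#'   analyses are scheduled; must not exceed the concurrent sample size.
#' @param hist_horizon Administrative censoring horizon (months) applied
#'   to the fully accrued historical cohort.
#' @param seed Default seed used by [generate_trial()] when none is given.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_experimental = 388, n_control = 392,
                         n_historical = 426, accrual_rate = 22,
                         weibull_shape = 1.2,
                         mu_experimental = NULL, mu_control = NULL,
                         mu_historical = NULL,
                         efs4y = c(experimental = 0.44, control = 0.44,
                                   historical = 0.36),
                         p_cr = c(experimental = 319 / 388,
                                  control = 340 / 392,
                                  historical = 360 / 426),
                         p_mrd_neg_given_cr = c(experimental = 201 / 265,
                                                control = 215 / 269,
                                                historical = 159 / 226),
                         p_death60 = c(experimental = 26 / 388,
                                       control = 21 / 392,
                                       historical = 34 / 426),
                         p_ae45 = c(experimental = 116 / 388,
                                    control = 112 / 392,
                                    historical = 118 / 426),
                         eln_probs = c(favorable = 0.36,
                                       intermediate = 0.30,
                                       adverse = 0.34),
                         mrd_missing = c(current = 0.22, historical = 0.35),
                         milestones = c(150, 300, 450, 600),
                         hist_horizon = 72, seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x))
      stop(nm, " must be a non-negative integer count")
  }
  chk_count(n_experimental, "n_experimental")
  chk_count(n_control, "n_control")
  chk_count(n_historical, "n_historical")
  if (!is.finite(accrual_rate) || accrual_rate <= 0)
    stop("accrual_rate must be > 0")
  if (!is.finite(weibull_shape) || weibull_shape <= 0)
    stop("weibull_shape must be > 0")
  chk_prob <- function(x, nm, len = 3L) {
    if (length(x) != len || any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must be ", len, " probabilities in [0,1]")
  }
  chk_prob(p_cr, "p_cr"); chk_prob(p_mrd_neg_given_cr, "p_mrd_neg_given_cr")
  chk_prob(p_death60, "p_death60"); chk_prob(p_ae45, "p_ae45")
  chk_prob(eln_probs, "eln_probs")
  chk_prob(mrd_missing, "mrd_missing", 2L)
  if (abs(sum(eln_probs) - 1) > 1e-8) stop("eln_probs must sum to 1")
  if (length(milestones)) {
    if (is.unsorted(milestones, strictly = TRUE))
      stop("milestones must be strictly increasing")
    if (max(milestones) > n_experimental + n_control)
      stop("milestones must not exceed the concurrent sample size")
  }
  if (hist_horizon <= 0) stop("hist_horizon must be > 0")
  nu <- weibull_shape
  from_s4 <- function(s) log(-log(s) / 48^nu)
  if (is.null(mu_experimental)) mu_experimental <- from_s4(efs4y[["experimental"]])
  if (is.null(mu_control)) mu_control <- from_s4(efs4y[["control"]])
  if (is.null(mu_historical)) mu_historical <- from_s4(efs4y[["historical"]])
  structure(list(n_experimental = as.integer(n_experimental),
                 n_control = as.integer(n_control),
                 n_historical = as.integer(n_historical),
                 accrual_rate = accrual_rate, weibull_shape = nu,
                 mu_experimental = mu_experimental, mu_control = mu_control,
                 mu_historical = mu_historical,
                 p_cr = p_cr, p_mrd_neg_given_cr = p_mrd_neg_given_cr,
                 p_death60 = p_death60, p_ae45 = p_ae45,
                 eln_probs = eln_probs, mrd_missing = mrd_missing,
                 milestones = as.integer(milestones),
                 hist_horizon = hist_horizon, seed = as.integer(seed)),
            class = "trial_config")
}

.eln_levels <- c("favorable", "intermediate", "adverse")
.record_cols <- c("id", "source", "arm", "age", "eln_risk", "enroll_time",
                  "efs_time", "efs_event", "cr", "mrd_negative", "death60",
                  "ae_grade45")

.empty_records <- function() {
  data.frame(id = character(0), source = character(0), arm = character(0),
             age = numeric(0), eln_risk = character(0),
             enroll_time = numeric(0), efs_time = numeric(0),
             efs_event = logical(0), cr = logical(0),
             mrd_negative = logical(0), death60 = logical(0),
             ae_grade45 = logical(0), stringsAsFactors = FALSE)
}

.validate_records <- function(records) {
  missing_cols <- setdiff(.record_cols, names(records))
  if (length(missing_cols))
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  records <- records[, .record_cols]
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (!all(records$source %in% c("current", "historical")))
    stop("source must be 'current' or 'historical'")
  if (!all(records$arm %in% c("experimental", "control")))
    stop("arm must be 'experimental' or 'control'")
  if (!all(records$eln_risk %in% .eln_levels))
    stop("eln_risk must be one of: ", paste(.eln_levels, collapse = ", "))
  bad <- records$source == "historical" & records$arm != "control"
  if (any(bad)) stop("historical records must be in the control arm")
  if (any(records$efs_time < 0)) stop("efs_time must be >= 0")
  if (any(records$enroll_time < 0)) stop("enroll_time must be >= 0")
  bad <- records$death60 & !(records$efs_event & records$efs_time <= 2)
  if (any(bad))
    stop("death60 implies an observed event within 2 months")
  bad <- !is.na(records$mrd_negative) & !records$cr
  if (any(bad)) stop("mrd_negative may only be defined when cr is TRUE")
  records
}

#' Construct a trial dataset from patient records
#'
#' Wraps a patient-record data frame in a `trial_dataset`, validating the
#' record invariants (unique ids, historical subjects in the control arm,
#' non-negative times, a 60-day death implying an observed event within 2
#' months, MRD defined only in CR).
#'
#' @param records Data frame with columns `id`, `source`, `arm`, `age`,
#'   `eln_risk`, `enroll_time`, `efs_time`, `efs_event`, `cr`,
#'   `mrd_negative` (NA when undefined), `death60`, `ae_grade45`.
#' @param config Optional `trial_config` provenance.
#' @param calendar_now Calendar cutoff in months, `NA` when the dataset
#'   has not been cut at an interim.
#' @param median_followup Median follow-up at the cutoff (months), `NA`
#'   when not cut.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(records, config = NULL, calendar_now = NA_real_,
                          median_followup = NA_real_) {
  records <- .validate_records(records)
  structure(list(records = records, config = config,
                 calendar_now = calendar_now,
                 median_followup = median_followup),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("Trial dataset: %d records (%d experimental, %d control, %d historical)\n",
              nrow(r), sum(r$arm == "experimental"),
              sum(r$source == "current" & r$arm == "control"),
              sum(r$source == "historical")))
  if (!is.na(x$calendar_now))
    cat(sprintf("  cut at calendar month %.2f (median follow-up %.2f months)\n",
                x$calendar_now, x$median_followup))
  cat(sprintf("  EFS events: %d\n", sum(r$efs_event)))
  invisible(x)
}

# Inverse-CDF draw from Weibull with cumulative hazard t^nu * exp(mu),
# optionally truncated to [0, upper].
.rweib_rate <- function(n, nu, mu, upper = Inf) {
  if (n == 0L) return(numeric(0))
  rate <- exp(mu)
  if (is.finite(upper)) {
    pmax_u <- 1 - exp(-upper^nu * rate)
    u <- stats::runif(n, 0, pmax_u)
  } else {
    u <- stats::runif(n)
  }
  (-log(1 - u) / rate)^(1 / nu)
}

.gen_group <- function(n, prefix, source, arms, config, mu, accrual_window) {
  if (n == 0L) return(.empty_records())
  enroll <- if (accrual_window > 0) sort(stats::runif(n, 0, accrual_window))
            else rep(0, n)
  age <- stats::runif(n, 18, 65)
  eln <- sample(.eln_levels, n, replace = TRUE, prob = config$eln_probs)
  grp_idx <- ifelse(source == "historical", "historical",
                    ifelse(arms == "experimental", "experimental", "control"))
  p_at <- function(p) unname(p[grp_idx])
  death60 <- stats::runif(n) < p_at(config$p_death60)
  nu <- config$weibull_shape
  efs <- numeric(n)
  for (g in unique(grp_idx)) {
    sel <- grp_idx == g & !death60
    efs[sel] <- .rweib_rate(sum(sel), nu, mu[which(grp_idx == g)[1]])
    # deaths within 60 days: event time resampled from the Weibull
    # truncated to [0, 2] so death60 => event <= 2 months
    sel <- grp_idx == g & death60
    efs[sel] <- .rweib_rate(sum(sel), nu, mu[which(grp_idx == g)[1]],
                            upper = 2)
  }
  cr <- stats::runif(n) < p_at(config$p_cr)
  mrd_miss_p <- ifelse(source == "historical",
                       config$mrd_missing[["historical"]],
                       config$mrd_missing[["current"]])
  mrd <- rep(NA, n)
  assessed <- cr & (stats::runif(n) >= mrd_miss_p)
  mrd[assessed] <- stats::runif(sum(assessed)) <
    p_at(config$p_mrd_neg_given_cr)[assessed]
  ae <- stats::runif(n) < p_at(config$p_ae45)
  event <- rep(TRUE, n)
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             source = source, arm = arms, age = age, eln_risk = eln,
             enroll_time = enroll, efs_time = efs, efs_event = event,
             cr = cr, mrd_negative = mrd, death60 = death60,
             ae_grade45 = ae, stringsAsFactors = FALSE)
}

#' Generate a synthetic trial dataset
#'
#' Draws a complete patient-level dataset under `config`: concurrent
#' subjects enroll uniformly over the accrual window implied by
#' `accrual_rate`, are randomized 1:1 (exactly `n_experimental` and
#' `n_control`), and receive latent Weibull EFS times; historical control
#' subjects form a fully accrued cohort (enrollment time 0) with
#' administrative censoring at `hist_horizon` months. Binary endpoints are
#' drawn independently at the configured rates except that a 60-day death
#' forces the EFS event into the first 2 months (the event time is
#' resampled from the Weibull truncated to [0, 2]). Concurrent latent
#' event times are uncensored until [cut_at_milestone()] imposes an
#' analysis cutoff.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; the same seed and config reproduce the
#'   dataset exactly.
#' @return A [trial_dataset()].
#' @export
generate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n_cur <- config$n_experimental + config$n_control
  window <- n_cur / config$accrual_rate
  arms <- if (n_cur > 0)
    sample(rep(c("experimental", "control"),
               c(config$n_experimental, config$n_control)))
  else character(0)
  mu_cur <- ifelse(arms == "experimental", config$mu_experimental,
                   config$mu_control)
  cur <- .gen_group(n_cur, "C", rep("current", n_cur), arms, config,
                    mu_cur, window)
  hist <- .gen_group(config$n_historical, "H",
                     rep("historical", config$n_historical),
                     rep("control", config$n_historical), config,
                     rep(config$mu_historical, config$n_historical), 0)
  if (nrow(hist)) {
    cens <- hist$efs_time > config$hist_horizon
    hist$efs_time[cens] <- config$hist_horizon
    hist$efs_event[cens] <- FALSE
    hist$death60[cens] <- FALSE  # horizon >> 2 months, kept for safety
  }
  trial_dataset(rbind(cur, hist), config = config)
}

#' Cut a trial dataset at an enrollment milestone
#'
#' Emulates an interim data cutoff: the calendar cutoff is the enrollment
#' time of the `milestone`-th concurrent patient; concurrent patients
#' enrolled later are excluded, and each retained patient's EFS time is
#' administratively censored at `cutoff - enroll_time` when the latent
#' event lies beyond the cutoff (60-day death indicators of such patients
#' are reset, since the death has not yet been observed). Historical
#' records pass through unchanged. The result records the cutoff and the
#' median follow-up (median of `cutoff - enroll_time` over retained
#' concurrent patients).
#'
#' @param data A [trial_dataset()].
#' @param milestone Enrollment count, at most the number of concurrent
#'   records.
#' @return A [trial_dataset()] with `calendar_now` and `median_followup`
#'   set.
#' @export
cut_at_milestone <- function(data, milestone) {
  stopifnot(inherits(data, "trial_dataset"))
  r <- data$records
  cur <- r[r$source == "current", , drop = FALSE]
  if (milestone < 1 || milestone > nrow(cur))
    stop("infeasible interim: milestone ", milestone,
         " exceeds the ", nrow(cur), " enrolled concurrent patients")
  ord <- order(cur$enroll_time)
  cutoff <- cur$enroll_time[ord[milestone]]
  keep <- cur[cur$enroll_time <= cutoff, , drop = FALSE]
  fup <- cutoff - keep$enroll_time
  cens <- keep$enroll_time + keep$efs_time > cutoff
  keep$efs_time[cens] <- fup[cens]
  keep$efs_event[cens] <- FALSE
  keep$death60[cens] <- FALSE
  hist <- r[r$source == "historical", , drop = FALSE]
  trial_dataset(rbind(keep, hist), config = data$config,
                calendar_now = cutoff,
                median_followup = stats::median(fup))
}
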