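# shared fixtures: short MCMC runs and small trial configurations

quick_mcmc <- function(seed = 1L, n_iter = 4000L, n_chains = 3L) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, seed = seed)
}

# a small balanced trial with a historical cohort
small_config <- function(...) {
  trial_config(n_experimental = 150, n_control = 150, n_historical = 150,
               accrual_rate = 22, milestones = c(80, 160), ...)
}

# hand-built record rows for exact-enumeration tests
make_records <- function(n, source = "current", arm = "control",
                         age = 45, eln = "favorable", enroll = 0,
                         efs_time = 1, efs_event = FALSE,
                         prefix = "X") {
  data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
             source = source, arm = arm, age = age, eln_risk = eln,
             enroll_time = enroll, efs_time = efs_time,
             efs_event = efs_event, cr = FALSE, mrd_negative = NA,
             death60 = FALSE, ae_grade45 = FALSE,
             stringsAsFactors = FALSE)
}

posterior_median <- function(fit, parameter) {
  fit$summary$median[fit$summary$parameter == parameter]
}
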