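#' Fit a propensity-score model for trial membership
#'
#' Logistic regression of current-trial membership (current vs historical)
#' on age and ELN 2017 risk, fitted among control-arm subjects only. Age
#' is standardized internally and ELN risk enters as two indicator
#' contrasts against "favorable". The fitted probabilities of being a
#' current-trial subject are the propensity scores used to match
#' historical controls to concurrent controls.
#'
#' @param records A [trial_dataset()] or a patient-record data frame;
#'   only control-arm subjects are used and both sources must be present.
#' @return An object of class `match_result` with elements `scores`
#'   (named by id), `coefficients` (intercept, standardized-age slope,
#'   two ELN contrasts), `balance_data` (covariates retained for balance
#'   computation), and empty `pairs`/`balance` slots to be filled by
#'   [greedy_match()].
#' @export
fit_propensity <- function(records) {
  if (inherits(records, "trial_dataset")) records <- records$records
  records <- records[records$arm == "control", , drop = FALSE]
  if (!all(c("current", "historical") %in% records$source))
    stop("both current and historical control-arm subjects are required")
  y <- as.integer(records$source == "current")
  age_mean <- mean(records$age)
  age_sd <- stats::sd(records$age)
  if (age_sd == 0) age_sd <- 1
  age_z <- (records$age - age_mean) / age_sd
  eln <- factor(records$eln_risk, levels = .eln_levels)
  X <- cbind(`(Intercept)` = 1, age_z = age_z,
             eln_intermediate = as.numeric(eln == "intermediate"),
             eln_adverse = as.numeric(eln == "adverse"))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 200)))
  coefs <- fit$coefficients
  estimable <- !is.na(coefs)   # aliased columns (e.g. an absent ELN level)
  coefs[!estimable] <- 0
  p <- fit$fitted.values
  eta <- X %*% coefs
  # complete separation: the linear predictor splits the sources exactly
  # and the fitted probabilities have escaped to the boundary
  if ((max(eta[y == 0]) < min(eta[y == 1]) ||
       min(eta[y == 0]) > max(eta[y == 1])) &&
      (min(p[y == 1]) > 1 - 1e-6 || max(p[y == 0]) < 1e-6))
    stop("complete separation detected: all historical linear predictors (max ",
         format(max(eta[y == 0]), digits = 4),
         ") lie below all current ones (min ",
         format(min(eta[y == 1]), digits = 4),
         "); propensity scores are degenerate")
  grad <- crossprod(X[, estimable, drop = FALSE], y - p)
  if (max(abs(grad)) > 1e-8)
    stop("logistic fit did not converge (score gradient norm ",
         format(max(abs(grad)), digits = 3), ")")
  scores <- as.numeric(p)
  names(scores) <- records$id
  structure(list(scores = scores,
                 coefficients = stats::setNames(fit$coefficients,
                                                colnames(X)),
                 age_center = age_mean, age_scale = age_sd,
                 balance_data = records[, c("id", "source", "age",
                                            "eln_risk")],
                 pairs = NULL, balance = NULL),
            class = "match_result")
}

# standardized mean difference between two numeric vectors
.smd <- function(a, b) {
  s <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(a) - mean(b)) / s
}

.balance_table <- function(bd, cur_ids, hist_ids, cur_ids_m, hist_ids_m) {
  covs <- function(d) cbind(age = d$age,
                            eln_favorable = as.numeric(d$eln_risk == "favorable"),
                            eln_intermediate = as.numeric(d$eln_risk == "intermediate"),
                            eln_adverse = as.numeric(d$eln_risk == "adverse"))
  pick <- function(ids) covs(bd[match(ids, bd$id), , drop = FALSE])
  before <- mapply(.smd, as.data.frame(pick(cur_ids)),
                   as.data.frame(pick(hist_ids)))
  after <- mapply(.smd, as.data.frame(pick(cur_ids_m)),
                  as.data.frame(pick(hist_ids_m)))
  data.frame(covariate = names(before), smd_before = unname(before),
             smd_after = unname(after), row.names = NULL)
}

#' Greedy nearest-neighbor matching on propensity scores
#'
#' Matches historical controls 1:1 to concurrent controls without
#' replacement on the absolute propensity-score difference. Concurrent
#' controls are processed in decreasing score order; each takes the
#' closest remaining historical control, ties broken by the lowest
#' historical id, until `n_pairs` pairs are formed. The result is
#' invariant to input row order. A per-covariate standardized mean
#' difference table (before: all concurrent vs all historical controls;
#' after: matched sets) is recomputed on the matched set.
#'
#' @param result A `match_result` from [fit_propensity()].
#' @param n_pairs Number of pairs to form; must not exceed either side.
#' @param seed Accepted for interface stability; the algorithm is fully
#'   deterministic (id tie-break), so the seed is unused.
#' @param caliper Optional maximum score distance for a valid pair
#'   (default `Inf`, i.e. no caliper); an error is raised if the caliper
#'   leaves fewer than `n_pairs` feasible pairs.
#' @return The `match_result` with `pairs` (data frame `current_id`,
#'   `historical_id`, `score_current`, `score_historical`) and `balance`
#'   filled in.
#' @export
greedy_match <- function(result, n_pairs, seed = 1L, caliper = Inf) {
  stopifnot(inherits(result, "match_result"))
  bd <- result$balance_data
  cur_ids <- bd$id[bd$source == "current"]
  hist_ids <- bd$id[bd$source == "historical"]
  if (n_pairs > length(cur_ids) || n_pairs > length(hist_ids))
    stop("n_pairs = ", n_pairs, " exceeds available subjects (",
         length(cur_ids), " current, ", length(hist_ids), " historical)")
  s_cur <- result$scores[cur_ids]
  s_hist <- result$scores[hist_ids]
  ord <- order(-s_cur, cur_ids)
  avail <- rep(TRUE, length(hist_ids))
  hist_rank <- rank(hist_ids)  # for the lowest-id tie break
  pair_cur <- character(n_pairs)
  pair_hist <- character(n_pairs)
  k <- 0L
  for (i in ord) {
    if (k >= n_pairs) break
    d <- abs(s_hist - s_cur[i])
    d[!avail] <- Inf
    d[d > caliper] <- Inf
    if (!any(is.finite(d))) next
    dmin <- min(d)
    cand <- which(d <= dmin)  # exact ties
    j <- cand[which.min(hist_rank[cand])]
    k <- k + 1L
    pair_cur[k] <- cur_ids[i]
    pair_hist[k] <- hist_ids[j]
    avail[j] <- FALSE
  }
  if (k < n_pairs)
    stop("only ", k, " pairs feasible under the caliper; ", n_pairs,
         " requested")
  result$pairs <- data.frame(current_id = pair_cur,
                             historical_id = pair_hist,
                             score_current = unname(result$scores[pair_cur]),
                             score_historical = unname(result$scores[pair_hist]),
                             stringsAsFactors = FALSE)
  result$balance <- .balance_table(bd, cur_ids, hist_ids,
                                   pair_cur, pair_hist)
  result
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Propensity model on %d control-arm subjects\n",
              length(x$scores)))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$pairs)) {
    cat(sprintf("  %d matched pairs\n", nrow(x$pairs)))
    print(x$balance, digits = 3)
  }
  invisible(x)
}

#' Write or read matched pairs as CSV
#'
#' Columns: `current_id, historical_id, score_current, score_historical`.
#'
#' @param result A `match_result` with pairs filled in.
#' @param path File path.
#' @return `write_pairs_csv` returns `path` invisibly; `read_pairs_csv`
#'   returns the pairs data frame.
#' @export
write_pairs_csv <- function(result, path) {
  stopifnot(inherits(result, "match_result"), !is.null(result$pairs))
  utils::write.csv(result$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  out <- utils::read.csv(path, colClasses = c("character", "character",
                                              "numeric", "numeric"))
  need <- c("current_id", "historical_id", "score_current",
            "score_historical")
  if (!identical(names(out), need))
    stop("pairs CSV must have columns: ", paste(need, collapse = ", "))
  out
}
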