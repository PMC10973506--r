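#' Write a trial dataset to CSV
#'
#' One header row with columns exactly `id, source, arm, age, eln_risk,
#' enroll_time, efs_time, efs_event, cr, mrd_negative, death60,
#' ae_grade45`; booleans encoded 0/1; an undefined MRD status is an empty
#' field.
#'
#' @param data A [trial_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  r <- data$records
  out <- data.frame(id = r$id, source = r$source, arm = r$arm,
                    age = r$age, eln_risk = r$eln_risk,
                    enroll_time = r$enroll_time, efs_time = r$efs_time,
                    efs_event = as.integer(r$efs_event),
                    cr = as.integer(r$cr),
                    mrd_negative = ifelse(is.na(r$mrd_negative), NA_integer_,
                                          as.integer(r$mrd_negative)),
                    death60 = as.integer(r$death60),
                    ae_grade45 = as.integer(r$ae_grade45),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.parse_bool <- function(x, allow_na = FALSE) {
  out <- rep(NA, length(x))
  out[x == "0"] <- FALSE
  out[x == "1"] <- TRUE
  bad <- is.na(out) & !(allow_na & (is.na(x) | x == ""))
  list(value = out, bad = bad)
}

#' Read a trial dataset from CSV
#'
#' Reads the format written by [write_trial_csv()], validating every row:
#' numeric fields must parse, enumerations must match their domains,
#' booleans must be 0/1 (an empty `mrd_negative` means undefined), and
#' the record invariants must hold. Malformed rows are reported with
#' their file line numbers (the header is line 1).
#'
#' @param path CSV file path.
#' @param config Optional `trial_config` provenance to attach.
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(path, config = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         check.names = FALSE)
  missing_cols <- setdiff(.record_cols, names(raw))
  if (length(missing_cols))
    stop("malformed header: missing columns ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  errs <- character(0)
  add_err <- function(bad, msg) {
    if (any(bad))
      errs <<- c(errs, sprintf("line %d: %s", line[bad], msg))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    add_err(is.na(v), paste0("non-numeric ", col))
    v
  }
  age <- num("age"); enroll <- num("enroll_time"); efs <- num("efs_time")
  add_err(!is.na(enroll) & enroll < 0, "negative enroll_time")
  add_err(!is.na(efs) & efs < 0, "negative efs_time")
  add_err(!raw$source %in% c("current", "historical"), "invalid source")
  add_err(!raw$arm %in% c("experimental", "control"), "invalid arm")
  add_err(!raw$eln_risk %in% .eln_levels, "invalid eln_risk")
  bools <- list()
  for (col in c("efs_event", "cr", "death60", "ae_grade45")) {
    p <- .parse_bool(raw[[col]])
    add_err(p$bad, paste0(col, " must be 0 or 1"))
    bools[[col]] <- p$value
  }
  mrd <- .parse_bool(raw$mrd_negative, allow_na = TRUE)
  add_err(mrd$bad, "mrd_negative must be 0, 1 or empty")
  add_err(!is.na(mrd$value) & !is.na(bools$cr) & !bools$cr,
          "mrd_negative defined but cr is 0")
  add_err(raw$source == "historical" & raw$arm != "control",
          "historical record not in control arm")
  add_err(!is.na(bools$death60) & bools$death60 &
            !(!is.na(bools$efs_event) & bools$efs_event &
                !is.na(efs) & efs <= 2),
          "death60 set without an observed event within 2 months")
  dup <- duplicated(raw$id) | duplicated(raw$id, fromLast = TRUE)
  add_err(dup & duplicated(raw$id), "duplicate id")
  if (length(errs))
    stop("malformed trial CSV:\n  ",
         paste(utils::head(errs, 10), collapse = "\n  "),
         if (length(errs) > 10) sprintf("\n  ... and %d more", length(errs) - 10))
  records <- data.frame(id = raw$id, source = raw$source, arm = raw$arm,
                        age = age, eln_risk = raw$eln_risk,
                        enroll_time = enroll, efs_time = efs,
                        efs_event = bools$efs_event, cr = bools$cr,
                        mrd_negative = mrd$value, death60 = bools$death60,
                        ae_grade45 = bools$ae_grade45,
                        stringsAsFactors = FALSE)
  trial_dataset(records, config = config)
}

#' Read or write a trial configuration as YAML
#'
#' @param config A [trial_config()].
#' @param path File path (YAML).
#' @return `write_trial_config` returns `path` invisibly;
#'   `read_trial_config` returns a [trial_config()].
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path,
    precision = 17L)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  named <- c("efs4y", "p_cr", "p_mrd_neg_given_cr", "p_death60", "p_ae45",
             "eln_probs", "mrd_missing")
  for (nm in intersect(named, names(raw))) raw[[nm]] <- unlist(raw[[nm]])
  do.call(trial_config, raw)
}
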