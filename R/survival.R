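# Survival analysis: Kaplan-Meier estimation, two-group log-rank testing and
# expression-stratified survival with the 60-month exclusion rule.

validate_survival <- function(records) {
  req <- c("patient_id", "time", "event")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    stop("survival records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$patient_id <- as.character(records$patient_id)
  records$time <- as.numeric(records$time)
  records$event <- as.integer(as.logical(records$event))
  if (any(!is.finite(records$time) | records$time <= 0)) {
    stop("survival times must be finite and positive", call. = FALSE)
  }
  if (anyDuplicated(records$patient_id)) {
    stop("duplicate patient_id in survival records", call. = FALSE)
  }
  records
}

#' Read a clinical survival table from TSV
#'
#' Expected columns: \code{patient_id}, \code{time_months}, \code{event}
#' (0/1).
#'
#' @param path TSV path.
#' @return data.frame with \code{patient_id}, \code{time}, \code{event}.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "time_months", "event"))
  validate_survival(data.frame(patient_id = df$patient_id,
                               time = df$time_months, event = df$event,
                               stringsAsFactors = FALSE))
}

#' Exclude long survival times from a cohort
#'
#' Retains records with survival time at most \code{max_months}; the cohort
#' analyses this package mirrors excluded patients with survival times
#' longer than 60 months ("longer than" read strictly, so a time of exactly
#' 60 months is kept).
#'
#' @param records survival data.frame (\code{patient_id}, \code{time},
#'   \code{event}).
#' @param max_months exclusion threshold in months (default 60).
#' @return Filtered records.
#' @export
filter_survival <- function(records, max_months = 60) {
  stopifnot(max_months > 0)
  records <- validate_survival(records)
  keep <- records$time <= max_months
  if (!any(keep)) {
    stop("no records remain after the ", max_months, "-month filter",
         call. = FALSE)
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " record(s) with time > ", max_months, " months excluded")
  }
  records[keep, , drop = FALSE]
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function. Censored observations
#' reduce the risk set without dropping the curve; at tied times, events are
#' handled before censorings (the standard convention).
#'
#' @param records survival data.frame (\code{patient_id}, \code{time},
#'   \code{event}).
#' @return Object of class \code{km_curve}: list with \code{time} (event
#'   times, increasing), \code{survival}, \code{at_risk}, \code{n_events},
#'   and the underlying \code{survfit} fit.
#' @export
km_estimate <- function(records) {
  records <- validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], n_events = fit$n.event[keep],
                 n = nrow(records), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, final S = %.3f\n",
              x$n, length(x$time),
              if (length(x$survival) > 0) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' Write a Kaplan-Meier curve to TSV
#' @param km a \code{km_curve}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_km <- function(km, path) {
  write_tsv(data.frame(time = km$time, survival = km$survival,
                       at_risk = km$at_risk, events = km$n_events), path)
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic: over the pooled event times, observed
#' minus expected events in one group and the hypergeometric variance are
#' summed; the squared standardized sum is referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param group_a,group_b survival data.frames.
#' @return List with \code{chi2} and \code{p}.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- validate_survival(group_a)
  group_b <- validate_survival(group_b)
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- rbind(
    data.frame(time = group_a$time, event = group_a$event, group = "a"),
    data.frame(time = group_b$time, event = group_b$event, group = "b"))
  if (sum(pooled$event) == 0) {
    stop("no events in the pooled data; log-rank test undefined", call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = pooled)
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Expression-stratified survival analysis
#'
#' Applies the long-survival exclusion, splits the surviving patients into
#' low and high groups by a per-patient stratifier (for example RBM25
#' expression) using either a median split or extreme-quantile groups, and
#' compares the groups' Kaplan-Meier curves with the log-rank test.
#'
#' @param records survival data.frame.
#' @param stratifier named numeric vector over patient ids (must cover all
#'   records surviving the time filter).
#' @param grouping \code{"median"} or a numeric fraction in (0, 0.5] for
#'   extreme-quantile groups.
#' @param max_months exclusion threshold (default 60).
#' @return List with \code{low} and \code{high} (\code{km_curve}s),
#'   \code{chi2}, \code{p}, and the patient id groups.
#' @export
stratified_survival <- function(records, stratifier, grouping = "median",
                                max_months = 60) {
  records <- filter_survival(records, max_months)
  uncovered <- setdiff(records$patient_id, names(stratifier))
  if (length(uncovered) > 0) {
    stop("stratifier missing for patient(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  }
  strat <- stratifier[records$patient_id]
  groups <- if (identical(grouping, "median")) {
    median_split(strat)
  } else if (is.numeric(grouping)) {
    quantile_groups(strat, grouping)
  } else {
    stop("grouping must be \"median\" or a numeric fraction", call. = FALSE)
  }
  if (length(groups$low) == 0 || length(groups$high) == 0) {
    stop("stratification produced an empty group", call. = FALSE)
  }
  low_rec <- records[records$patient_id %in% groups$low, , drop = FALSE]
  high_rec <- records[records$patient_id %in% groups$high, , drop = FALSE]
  lr <- logrank_test(low_rec, high_rec)
  list(low = km_estimate(low_rec), high = km_estimate(high_rec),
       chi2 = lr$chi2, p = lr$p, groups = groups)
}
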