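# Study statistics: 2x2 shift contingency tests, the diabetic/nondiabetic
# test-count comparison from summaries, per-patient rates, docking latency.

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with the Yates continuity correction by default
#' (the correction is floored so a perfectly homogeneous table yields a
#' statistic of exactly zero). One degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows: groups,
#'   columns: outcome / non-outcome).
#' @param continuity apply the Yates correction (default `TRUE`).
#' @return list with `statistic`, `df = 1`, `p.value`.
#' @export
chisq_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined test: a marginal total is zero")
  ct <- stats::chisq.test(table, correct = continuity)
  list(statistic = unname(ct$statistic), df = 1L, p.value = unname(ct$p.value))
}

#' Two-sample t test from group summaries
#'
#' Unequal-variance (Welch) t statistic with Satterthwaite fractional
#' degrees of freedom, computed from per-group mean, SD and n; the pooled
#' (equal-variance) variant is available for sensitivity analysis. The df
#' is also reported rounded to the nearest integer, matching how journals
#' subscript the statistic.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param pooled use the pooled-variance Student t instead of Welch.
#' @return list with `t`, `df`, `df_rounded`, `p.value` (two-sided).
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("sds must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("degenerate test: both sds are zero")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, df_rounded = round(df),
       p.value = 2 * stats::pt(-abs(t), df))
}

#' Per-patient error rate
#'
#' Errors divided by cohort size, with the exact fraction retained
#' alongside the 1-decimal display value.
#'
#' @param error_count number of errors.
#' @param n_patients cohort size (> 0).
#' @return list with `rate` (exact) and `rounded` (1 dp).
#' @export
per_patient_rate <- function(error_count, n_patients) {
  if (n_patients <= 0) stop("n_patients must be positive")
  r <- error_count / n_patients
  list(rate = r, rounded = round(r, 1))
}

#' Summarize meter docking latency
#'
#' Latency is `dock_time - test_time` in fractional hours. Records lacking
#' a dock time are counted separately as undocked; a negative latency is a
#' data-integrity failure and is reported as an error naming the offending
#' records.
#'
#' @param meters meter record `data.frame`.
#' @return list with `n`, `n_undocked`, `mean`, `median`, `q1`, `q3`,
#'   `max` (hours).
#' @export
docking_summary <- function(meters) {
  docked <- !is.na(meters$dock_time)
  lat <- as.numeric(difftime(meters$dock_time[docked],
                             meters$test_time[docked], units = "hours"))
  if (any(lat < 0)) {
    stop("negative docking latency for record(s): ",
         paste(utils::head(meters$record_id[docked][lat < 0], 10), collapse = ", "))
  }
  if (!length(lat)) {
    return(list(n = 0L, n_undocked = sum(!docked), mean = NA_real_,
                median = NA_real_, q1 = NA_real_, q3 = NA_real_, max = NA_real_))
  }
  q <- unname(stats::quantile(lat, c(0.25, 0.75), type = 7))
  list(n = length(lat), n_undocked = sum(!docked), mean = mean(lat),
       median = stats::median(lat), q1 = q[1], q3 = q[2], max = max(lat))
}
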