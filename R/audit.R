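# Error taxonomy and audit tallies.
#
# The reference value is the meter's; any nonzero integer difference in a
# documented value is a transcription error, regardless of magnitude.
# Classification per source is independent; per-source error rates use
# per-source documented denominators (errors are only assessable where a
# value was transcribed).

#' Classify a test against its documented values
#'
#' Vectorized over tests. `NA` in `paper_value` / `flow_value` means the
#' test is undocumented in that source; classification is restricted to
#' documented sources.
#'
#' @param meter_value reference glucose, mg/dL.
#' @param paper_value transcribed paper-log value or `NA`.
#' @param flow_value transcribed flow-sheet value or `NA`.
#' @return `data.frame` with per-source documented flags, signed
#'   discrepancies (`transcribed - meter`), per-source error flags, and a
#'   joint `label` in `no_error` / `paper_log_error` / `flow_sheet_error` /
#'   `both_error`.
#' @export
classify <- function(meter_value, paper_value = NA, flow_value = NA) {
  n <- length(meter_value)
  paper_value <- rep_len(paper_value, n)
  flow_value <- rep_len(flow_value, n)
  pd <- !is.na(paper_value); fd <- !is.na(flow_value)
  pdelta <- ifelse(pd, paper_value - meter_value, NA_integer_)
  fdelta <- ifelse(fd, flow_value - meter_value, NA_integer_)
  perr <- pd & pdelta != 0L
  ferr <- fd & fdelta != 0L
  label <- ifelse(perr & ferr, "both_error",
           ifelse(perr, "paper_log_error",
           ifelse(ferr, "flow_sheet_error", "no_error")))
  data.frame(paper_documented = pd, flow_documented = fd,
             paper_delta = pdelta, flow_delta = fdelta,
             paper_error = perr, flow_error = ferr,
             label = label, stringsAsFactors = FALSE)
}

#' Classify every meter record from a match table
#'
#' @param meters meter record `data.frame`.
#' @param matches output of [match_records()].
#' @return one row per meter record: `record_id`, `vin`, the [classify()]
#'   columns, and per-source matched entry ids.
#' @export
classify_matches <- function(meters, matches) {
  pick <- function(src) {
    m <- matches[matches$source == src & matches$status != "orphan", , drop = FALSE]
    m[match(meters$record_id, m$record_id), c("entry_id", "value_mgdl")]
  }
  p <- pick("paper_log"); f <- pick("flow_sheet")
  cl <- classify(meters$glucose_mgdl, p$value_mgdl, f$value_mgdl)
  cbind(data.frame(record_id = meters$record_id, vin = meters$vin,
                   glucose_mgdl = meters$glucose_mgdl,
                   stringsAsFactors = FALSE),
        cl,
        data.frame(paper_entry_id = p$entry_id, flow_entry_id = f$entry_id,
                   stringsAsFactors = FALSE))
}

#' Tally undocumented tests per source and jointly
#'
#' The joint count is of tests undocumented in both sources simultaneously;
#' all percentages are against the total number of tests. Documented-in-both
#' follows by inclusion-exclusion:
#' `N - miss_paper - miss_flow + miss_both`.
#'
#' @param classified output of [classify_matches()].
#' @return `data.frame` with rows `paper_log`, `flow_sheet`, `both`:
#'   undocumented `n`, `pct`, and the per-source documented count
#'   (`analyzed`) serving as the error-rate denominator.
#' @export
tally_undocumented <- function(classified) {
  n <- nrow(classified)
  miss_p <- sum(!classified$paper_documented)
  miss_f <- sum(!classified$flow_documented)
  miss_b <- sum(!classified$paper_documented & !classified$flow_documented)
  data.frame(
    source = c("paper_log", "flow_sheet", "both"),
    undocumented = c(miss_p, miss_f, miss_b),
    total = n,
    pct = round(100 * c(miss_p, miss_f, miss_b) / n, 2),
    analyzed = c(n - miss_p, n - miss_f, n - miss_p - miss_f + miss_b),
    stringsAsFactors = FALSE)
}

#' Summarize signed error magnitudes
#'
#' Five-number-style summary (min, lower and upper quartile, max) of signed
#' discrepancies in mg/dL, with mmol/L equivalents obtained by converting
#' the absolute magnitude and reattaching the sign. Quartiles use linear
#' interpolation between order statistics (`quantile` type 7).
#'
#' @param discrepancies signed mg/dL differences (`NA` dropped).
#' @return a list with `n`, `min`, `q1`, `q3`, `max` (mg/dL) and
#'   `min_mmol`, `q1_mmol`, `q3_mmol`, `max_mmol`; all statistics `NA` when
#'   the collection is empty (`n = 0` sentinel).
#' @export
magnitude_summary <- function(discrepancies) {
  x <- discrepancies[!is.na(discrepancies)]
  if (length(x) == 0) {
    return(list(n = 0L, min = NA_real_, q1 = NA_real_, q3 = NA_real_,
                max = NA_real_, min_mmol = NA_real_, q1_mmol = NA_real_,
                q3_mmol = NA_real_, max_mmol = NA_real_))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  mg <- c(min = min(x), q1 = q[1], q3 = q[2], max = max(x))
  mmol <- sign(mg) * mgdl_to_mmol(abs(mg))
  c(list(n = length(x)), as.list(mg),
    stats::setNames(as.list(mmol), paste0(names(mg), "_mmol")))
}

#' Count distinct patients affected by each error category
#'
#' A patient is counted once per category however many errors they have;
#' the overall count is the union across categories (a patient with both a
#' paper-log and a flow-sheet error counts once overall).
#'
#' @param classified output of [classify_matches()].
#' @param n_patients cohort size used for percentages.
#' @return `data.frame` with rows `paper_log`, `flow_sheet`, `both`,
#'   `overall`: distinct-VIN counts and percentages of `n_patients`.
#' @export
unique_patients_affected <- function(classified, n_patients) {
  vin_p <- unique(classified$vin[classified$paper_error])
  vin_f <- unique(classified$vin[classified$flow_error])
  vin_b <- unique(classified$vin[classified$paper_error & classified$flow_error])
  vin_all <- union(vin_p, vin_f)
  n <- c(length(vin_p), length(vin_f), length(vin_b), length(vin_all))
  data.frame(category = c("paper_log", "flow_sheet", "both", "overall"),
             patients = n, n_patients = n_patients,
             pct = round(100 * n / n_patients, 1),
             stringsAsFactors = FALSE)
}
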