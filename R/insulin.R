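# Sliding-scale insulin protocol and dose-discrepancy assessment.
#
# An insulin error is a dose decision under the transcribed value that
# differs from what the protocol prescribes for the true (meter) value —
# including withholding a due dose — regardless of the magnitude of the
# dose difference.

#' Define a sliding-scale insulin protocol
#'
#' Ordered, non-overlapping, half-open glucose intervals `[lo, hi)` covering
#' the reportable range, each mapped to a subcutaneous dose in units, with
#' an optional hold-and-notify band below a hypoglycemia threshold. Doses
#' must be non-decreasing in glucose at or above the threshold.
#'
#' @param bands `data.frame` with numeric columns `lo`, `hi`, `dose`.
#' @param hypo_threshold hold-and-notify threshold, mg/dL (`NA` for none).
#' @param range reportable range the bands must cover exactly.
#' @return an object of class `insulin_protocol`.
#' @export
insulin_protocol <- function(bands, hypo_threshold = 70,
                             range = reportable_range()) {
  stopifnot(is.data.frame(bands), all(c("lo", "hi", "dose") %in% names(bands)))
  bands <- bands[order(bands$lo), , drop = FALSE]
  if (any(bands$hi <= bands$lo)) stop("each band needs lo < hi")
  if (bands$lo[1] > range[1] || bands$hi[nrow(bands)] <= range[2])
    stop("bands must cover the reportable range [", range[1], ", ", range[2], "]")
  if (nrow(bands) > 1 && any(bands$lo[-1] != bands$hi[-nrow(bands)]))
    stop("bands must tile without gaps or overlaps")
  if (any(bands$dose < 0)) stop("doses must be non-negative")
  above <- if (is.na(hypo_threshold)) bands else bands[bands$hi > hypo_threshold, ]
  if (is.unsorted(above$dose)) stop("dose must be non-decreasing in glucose above the hold band")
  rownames(bands) <- NULL
  structure(list(bands = bands, hypo_threshold = hypo_threshold, range = range),
            class = "insulin_protocol")
}

#' Default sliding scale
#'
#' A documented synthetic stand-in — the audited unit's own protocol is not
#' public, and any real audit must supply its protocol as configuration:
#' 0 U below 150 mg/dL; 2 U at 150–199; 4 U at 200–249; 6 U at 250–299;
#' 8 U at 300–349; 10 U at 350 and above; hold and notify below 70.
#'
#' @return an `insulin_protocol`.
#' @export
default_protocol <- function() {
  insulin_protocol(data.frame(
    lo = c(10, 150, 200, 250, 300, 350),
    hi = c(150, 200, 250, 300, 350, 601),
    dose = c(0, 2, 4, 6, 8, 10)))
}

#' @export
print.insulin_protocol <- function(x, ...) {
  cat("Sliding-scale insulin protocol\n")
  b <- x$bands
  for (i in seq_len(nrow(b)))
    cat(sprintf("  [%4d, %4d) mg/dL -> %g U\n", b$lo[i], b$hi[i], b$dose[i]))
  if (!is.na(x$hypo_threshold))
    cat(sprintf("  hold and notify below %g mg/dL\n", x$hypo_threshold))
  invisible(x)
}

#' Read / write an insulin protocol as YAML
#'
#' The file lists `bands:` as rows of `lo`, `hi`, `dose` plus an optional
#' `hypo_threshold`; validated on load.
#'
#' @param path YAML file path.
#' @return `read_protocol`: an `insulin_protocol`; `write_protocol`: `path`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$bands)) stop("protocol file lacks 'bands'")
  bands <- do.call(rbind, lapply(y$bands, function(b)
    data.frame(lo = b$lo, hi = b$hi, dose = b$dose)))
  insulin_protocol(bands, hypo_threshold = if (is.null(y$hypo_threshold)) NA
                                           else y$hypo_threshold)
}

#' @rdname read_protocol
#' @param protocol an `insulin_protocol` to serialize.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(list(
    hypo_threshold = protocol$hypo_threshold,
    bands = lapply(seq_len(nrow(protocol$bands)), function(i)
      as.list(protocol$bands[i, c("lo", "hi", "dose")]))), path)
  invisible(path)
}

#' Protocol dose lookup
#'
#' Returns the dose of the unique half-open band containing each glucose
#' value; values below the hypoglycemia threshold dose 0 (hold and notify).
#'
#' @param protocol an [insulin_protocol()].
#' @param glucose mg/dL, within the reportable range.
#' @return dose in units, vectorized.
#' @export
protocol_dose <- function(protocol, glucose) {
  stopifnot(inherits(protocol, "insulin_protocol"))
  b <- protocol$bands
  out_of_range <- glucose < b$lo[1] | glucose >= b$hi[nrow(b)]
  if (any(out_of_range))
    stop("glucose outside protocol domain: ",
         paste(utils::head(glucose[out_of_range], 5), collapse = ", "))
  b$dose[findInterval(glucose, b$lo)]
}

#' Assess the insulin consequence of a transcribed value
#'
#' Computes the protocol dose under the true (meter) value and under the
#' transcribed value independently. An insulin error is a nonzero dose
#' discrepancy, or a due dose withheld because the transcribed value falls
#' in a no-dose band.
#'
#' @param meter_value true glucose, mg/dL.
#' @param transcribed_value documented glucose, mg/dL.
#' @param protocol an [insulin_protocol()].
#' @return `data.frame` with `dose_true`, `dose_transcribed`,
#'   `discrepancy` (units, transcribed - true) and `is_error`; vectorized.
#' @export
assess_insulin <- function(meter_value, transcribed_value,
                           protocol = default_protocol()) {
  dose_true <- protocol_dose(protocol, meter_value)
  dose_tr <- protocol_dose(protocol, transcribed_value)
  disc <- dose_tr - dose_true
  withheld <- dose_true > 0 & dose_tr == 0
  data.frame(dose_true = dose_true, dose_transcribed = dose_tr,
             discrepancy = disc, is_error = disc != 0 | withheld)
}

#' Summarize insulin errors by transcription-error category
#'
#' For each category the assessment uses the transcribed value of the
#' relevant source (the flow-sheet value for the `both` category, being the
#' value that drives dosing). Unique insulin errors count each test once
#' even when it is erroneous in both sources.
#'
#' @param classified output of [classify_matches()].
#' @param protocol an [insulin_protocol()].
#' @param n_patients cohort size for the affected-patient percentage.
#' @return a list: `by_category` (`data.frame` of transcription-error count,
#'   insulin-error count, min/max dose discrepancy, distinct patients) and
#'   `overall` (unique insulin errors, distinct patients affected, pct).
#' @export
summarize_insulin_errors <- function(classified, protocol = default_protocol(),
                                     n_patients) {
  g <- classified$glucose_mgdl
  cats <- list(
    paper_log  = list(sel = classified$paper_error,
                      val = classified$paper_delta + g),
    flow_sheet = list(sel = classified$flow_error,
                      val = classified$flow_delta + g),
    both       = list(sel = classified$paper_error & classified$flow_error,
                      val = classified$flow_delta + g))
  err_record <- stats::setNames(vector("list", 3), names(cats))
  rows <- lapply(names(cats), function(cat) {
    sel <- which(cats[[cat]]$sel)
    if (!length(sel)) {
      err_record[[cat]] <<- character(0)
      return(data.frame(category = cat, transcription_errors = 0L,
                        insulin_errors = 0L, min_discrepancy_u = NA_real_,
                        max_discrepancy_u = NA_real_, patients = 0L,
                        stringsAsFactors = FALSE))
    }
    a <- assess_insulin(g[sel], cats[[cat]]$val[sel], protocol)
    err <- a$is_error
    err_record[[cat]] <<- classified$record_id[sel][err]
    data.frame(category = cat, transcription_errors = length(sel),
               insulin_errors = sum(err),
               min_discrepancy_u = if (any(err)) min(a$discrepancy[err]) else NA_real_,
               max_discrepancy_u = if (any(err)) max(a$discrepancy[err]) else NA_real_,
               patients = length(unique(classified$vin[sel][err])),
               stringsAsFactors = FALSE)
  })
  uniq <- unique(unlist(err_record))
  vins <- unique(classified$vin[classified$record_id %in% uniq])
  list(by_category = do.call(rbind, rows),
       overall = data.frame(unique_insulin_errors = length(uniq),
                            patients = length(vins), n_patients = n_patients,
                            pct = round(100 * length(vins) / n_patients, 1)))
}
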