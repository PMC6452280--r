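#' @importFrom stats quantile rnorm runif rgamma rlnorm qnbinom pnorm qnorm
#' @importFrom stats pchisq pt chisq.test median sd setNames
#' @importFrom utils read.csv write.csv
#' @importFrom graphics hist par
NULL

# Datetime handling: timezone-naive local clock, stored internally as POSIXct
# in UTC so arithmetic never crosses a DST boundary.
.TZ <- "UTC"
.TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

.parse_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = .TZ)
  blank <- is.na(x) | !nzchar(trimws(x))
  if (any(!blank)) {
    v <- trimws(x[!blank])
    p <- as.POSIXct(v, format = .TIME_FMT, tz = .TZ)
    miss <- is.na(p)
    if (any(miss)) p[miss] <- as.POSIXct(v[miss], format = "%Y-%m-%d %H:%M:%S", tz = .TZ)
    miss <- is.na(p)
    if (any(miss)) p[miss] <- as.POSIXct(v[miss], format = "%Y-%m-%d %H:%M", tz = .TZ)
    out[!blank] <- p
  }
  out
}

.format_time <- function(t) {
  out <- format(t, format = .TIME_FMT, tz = .TZ)
  out[is.na(t)] <- ""
  out
}

.schemas <- list(
  meter   = c("record_id", "vin", "test_time", "glucose_mgdl", "operator_id", "dock_time"),
  entry   = c("entry_id", "source", "vin", "entry_time", "value_mgdl"),
  episode = c("vin", "age", "sex", "diabetes", "admit", "discharge")
)

#' Default reportable range of the glucose meter
#'
#' Handheld meters report a bounded range; values outside it print as LO/HI
#' and never enter the numeric stream. Used to validate meter records and to
#' bound the domain of insulin protocols.
#' @return integer vector `c(lo, hi)` in mg/dL.
#' @export
reportable_range <- function() c(10L, 600L)

#' Read a validated record stream from CSV
#'
#' Parses one of the three audit input streams into its domain shape:
#' `"meter"` (reference glucometer records), `"entry"` (hand-transcribed
#' documentation entries), or `"episode"` (patient admission episodes).
#' All invariant violations in the file are collected and reported together;
#' rows are never silently dropped.
#'
#' @param path path to a CSV file with the schema's exact columns.
#' @param schema one of `"meter"`, `"entry"`, `"episode"`.
#' @param range reportable glucose range (mg/dL) used to validate meter values.
#' @return a `data.frame` with parsed columns (datetimes as POSIXct,
#'   glucose as integer).
#' @export
read_stream <- function(path, schema = c("meter", "entry", "episode"),
                        range = reportable_range()) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .validate_stream(raw, schema, range, where = path)
}

#' Write a record stream to CSV
#'
#' Inverse of [read_stream()]; datetimes are serialized as ISO-8601
#' (`YYYY-MM-DDTHH:MM:SS`, local clock), absent `dock_time` as an empty field.
#'
#' @param x a record collection as returned by [read_stream()] or the
#'   synthetic generator.
#' @param path output CSV path.
#' @param schema one of `"meter"`, `"entry"`, `"episode"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path, schema = c("meter", "entry", "episode")) {
  schema <- match.arg(schema)
  cols <- .schemas[[schema]]
  missing <- setdiff(cols, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- x[, cols, drop = FALSE]
  for (cc in names(out)) {
    if (inherits(out[[cc]], "POSIXct")) out[[cc]] <- .format_time(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.validate_stream <- function(raw, schema, range, where = "input") {
  cols <- .schemas[[schema]]
  missing <- setdiff(cols, names(raw))
  extra <- setdiff(names(raw), cols)
  if (length(missing) || length(extra)) {
    stop("schema mismatch for '", schema, "' in ", where,
         if (length(missing)) paste0("; missing column(s): ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ", paste(extra, collapse = ", ")))
  }
  df <- raw[, cols, drop = FALSE]
  n <- nrow(df)
  problems <- character(0)
  bad <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0(msg, " (row", if (length(rows) > 1) "s" else "",
                                      " ", paste(utils::head(rows, 10), collapse = ", "),
                                      if (length(rows) > 10) ", ..." else "", ")"))
    }
  }
  num_int <- function(x) suppressWarnings(as.numeric(x))

  if (schema == "meter") {
    df$test_time <- .parse_time(raw$test_time)
    df$dock_time <- .parse_time(raw$dock_time)
    g <- num_int(raw$glucose_mgdl)
    bad(which(is.na(df$test_time)), "unparseable test_time")
    dock_given <- !is.na(raw$dock_time) & nzchar(trimws(raw$dock_time))
    bad(which(dock_given & is.na(df$dock_time)), "unparseable dock_time")
    bad(which(is.na(g)), "non-numeric glucose_mgdl")
    bad(which(!is.na(g) & (g < range[1] | g > range[2])),
        sprintf("glucose_mgdl outside reportable range [%d, %d]", range[1], range[2]))
    bad(which(!is.na(df$dock_time) & !is.na(df$test_time) & df$dock_time < df$test_time),
        "dock_time earlier than test_time")
    if (anyDuplicated(raw$record_id)) bad(which(duplicated(raw$record_id)), "duplicate record_id")
    df$glucose_mgdl <- as.integer(round(g))
  } else if (schema == "entry") {
    df$entry_time <- .parse_time(raw$entry_time)
    v <- num_int(raw$value_mgdl)
    bad(which(is.na(df$entry_time)), "unparseable entry_time")
    bad(which(is.na(v)), "non-numeric value_mgdl")
    bad(which(!is.na(v) & v <= 0), "non-positive value_mgdl")
    bad(which(!(raw$source %in% c("paper_log", "flow_sheet"))),
        "source must be 'paper_log' or 'flow_sheet'")
    if (anyDuplicated(raw$entry_id)) bad(which(duplicated(raw$entry_id)), "duplicate entry_id")
    df$value_mgdl <- as.integer(round(v))
  } else {
    df$admit <- .parse_time(raw$admit)
    df$discharge <- .parse_time(raw$discharge)
    a <- num_int(raw$age)
    bad(which(is.na(df$admit)), "unparseable admit")
    bad(which(is.na(df$discharge)), "unparseable discharge")
    bad(which(is.na(a)), "non-numeric age")
    bad(which(!is.na(df$admit) & !is.na(df$discharge) & df$admit >= df$discharge),
        "admit not strictly before discharge")
    bad(which(!(raw$sex %in% c("male", "female", "unknown"))), "invalid sex")
    bad(which(!(raw$diabetes %in% c("yes", "no", "unknown"))), "invalid diabetes status")
    if (anyDuplicated(raw$vin)) bad(which(duplicated(raw$vin)), "duplicate vin")
    df$age <- a
  }
  if (length(problems)) {
    stop("validation of '", schema, "' stream ", where, " failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  rownames(df) <- NULL
  df
}

#' Working-shift configuration
#'
#' Two clock times partition the 24-hour day into a day and a night shift,
#' as half-open intervals: the boundary instant belongs to the shift it
#' opens. Defaults are standard 12-hour nursing shifts.
#'
#' @param day_start clock time (`"HH:MM"`) opening the day shift.
#' @param night_start clock time opening the night shift.
#' @return an object of class `shift_config`.
#' @export
shift_config <- function(day_start = "07:00", night_start = "19:00") {
  to_min <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) != 2 || anyNA(p) || p[1] > 23 || p[2] > 59) stop("bad clock time: ", s)
    p[1] * 60L + p[2]
  }
  d <- to_min(day_start); n <- to_min(night_start)
  if (d == n) stop("shift boundaries must be distinct")
  structure(list(day_start = d, night_start = n,
                 day_start_chr = day_start, night_start_chr = night_start),
            class = "shift_config")
}

#' Assign the working shift of a datetime
#'
#' @param t POSIXct vector.
#' @param shift a [shift_config()].
#' @return character vector of `"day"` / `"night"`.
#' @export
assign_shift <- function(t, shift = shift_config()) {
  stopifnot(inherits(shift, "shift_config"))
  lt <- as.POSIXlt(t, tz = .TZ)
  mins <- lt$hour * 60L + lt$min
  d <- shift$day_start; n <- shift$night_start
  if (d < n) {
    ifelse(mins >= d & mins < n, "day", "night")
  } else {
    ifelse(mins >= d | mins < n, "day", "night")
  }
}

#' Convert glucose from mg/dL to mmol/L
#'
#' Uses the molar mass of glucose (18.016 mg/dL per mmol/L) and rounds
#' half-up to one decimal, the convention used in clinical reporting.
#' Display-only: all computation in the package stays in integer mg/dL.
#'
#' @param v glucose in mg/dL, non-negative.
#' @return mmol/L rounded to 1 decimal place.
#' @export
mgdl_to_mmol <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("glucose must be non-negative")
  floor(v / 18.016 * 10 + 0.5) / 10
}
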