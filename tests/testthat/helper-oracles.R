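# Shared fixtures and independent oracles used across the suite.

T0 <- as.POSIXct("2016-07-10 08:00:00", tz = "UTC")

mins <- function(m) m * 60

mk_meters <- function(times, glucose = 150L, vin = "V1",
                      record_id = sprintf("R%03d", seq_along(times))) {
  data.frame(record_id = record_id,
             vin = rep_len(vin, length(times)),
             test_time = times,
             glucose_mgdl = as.integer(rep_len(glucose, length(times))),
             operator_id = "T01",
             dock_time = times + mins(300),
             stringsAsFactors = FALSE)
}

mk_entries <- function(times, value = 150L, vin = "V1", source = "paper_log",
                       entry_id = sprintf("E%03d", seq_along(times))) {
  data.frame(entry_id = entry_id,
             source = rep_len(source, length(times)),
             vin = rep_len(vin, length(times)),
             entry_time = times,
             value_mgdl = as.integer(rep_len(value, length(times))),
             stringsAsFactors = FALSE)
}

mk_episodes <- function(vin, admit, discharge) {
  data.frame(vin = vin, age = 60, sex = "male", diabetes = "no",
             admit = admit, discharge = discharge, stringsAsFactors = FALSE)
}

# Brute-force matching oracle for tiny instances: enumerate all one-to-one
# assignments of meters to window-compatible entries, pick maximum
# cardinality, break ties by minimum total offset.
oracle_match <- function(meter_times, entry_times, window = 60,
                         same_date = TRUE) {
  nm <- length(meter_times); ne <- length(entry_times)
  compat <- matrix(FALSE, nm, ne)
  off <- matrix(NA_real_, nm, ne)
  for (i in seq_len(nm)) for (j in seq_len(ne)) {
    o <- as.numeric(difftime(entry_times[j], meter_times[i], units = "mins"))
    ok <- o >= 0 && o <= window
    if (same_date) ok <- ok && as.Date(entry_times[j], tz = "UTC") ==
                               as.Date(meter_times[i], tz = "UTC")
    compat[i, j] <- ok; off[i, j] <- o
  }
  best <- list(count = -1L, total = Inf, assign = rep(NA_integer_, nm))
  recurse <- function(i, used, assign, count, total) {
    if (i > nm) {
      if (count > best$count ||
          (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total, assign = assign)
      }
      return(invisible())
    }
    recurse(i + 1L, used, assign, count, total)  # leave meter i unmatched
    for (j in seq_len(ne)) {
      if (compat[i, j] && !used[j]) {
        used[j] <- TRUE; assign[i] <- j
        recurse(i + 1L, used, assign, count + 1L, total + off[i, j])
        used[j] <- FALSE; assign[i] <- NA_integer_
      }
    }
  }
  recurse(1L, logical(ne), rep(NA_integer_, nm), 0L, 0)
  best
}

# Sort-and-index quartile oracle (linear interpolation between order stats).
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Closed-form 2x2 chi-square oracle.
oracle_chisq <- function(tab, continuity) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- if (continuity) pmin(0.5, abs(tab - E)) else 0
  sum((abs(tab - E) - adj)^2 / E)
}

# Small generator configuration for quick pipeline runs.
small_config <- function(...) {
  generator_config(n_patients = 50L, post_discharge_count = 5L, ...)
}
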