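# Temporal record linkage between the reference meter stream and each
# transcription stream: same VIN, same calendar date, within the window.

#' Match meter records to transcription entries
#'
#' For each documentation source, candidate pairs share the VIN and the
#' calendar date of the test and lie within the matching window
#' (forward-only by default: a transcription cannot precede its test).
#' Pairs are then claimed greedily by ascending offset (ties broken by
#' entry id), so matching is globally one-to-one per source. Meter records
#' left unmatched are undocumented in that source; entries left unclaimed
#' are orphans.
#'
#' @param meters meter record `data.frame`.
#' @param entries entry `data.frame` covering one or both sources.
#' @param window_minutes matching window (default 60).
#' @param direction `"forward"` (offset in `[0, window]`) or `"symmetric"`
#'   (`|offset| <= window`, for sensitivity analysis).
#' @return a `data.frame` with one row per meter record and source
#'   (`status` `"matched"` or `"undocumented"`, with `entry_id`,
#'   `offset_minutes`, `value_mgdl` when matched) plus one row per orphan
#'   entry (`status == "orphan"`, `record_id` `NA`).
#' @export
match_records <- function(meters, entries, window_minutes = 60,
                          direction = c("forward", "symmetric")) {
  direction <- match.arg(direction)
  if (window_minutes <= 0) stop("window_minutes must be positive")
  if (anyDuplicated(entries$entry_id)) stop("duplicate entry_ids in input")
  if (anyDuplicated(meters$record_id)) stop("duplicate record_ids in input")

  res <- lapply(intersect(c("paper_log", "flow_sheet"), unique(entries$source)),
                function(src) {
    e <- entries[entries$source == src, , drop = FALSE]
    .match_one_source(meters, e, src, window_minutes, direction)
  })
  # sources absent from the entry stream still yield undocumented rows
  for (src in setdiff(c("paper_log", "flow_sheet"), unique(entries$source))) {
    res[[length(res) + 1L]] <- data.frame(
      record_id = meters$record_id, source = src, entry_id = NA_character_,
      offset_minutes = NA_real_, value_mgdl = NA_integer_,
      status = "undocumented", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.match_one_source <- function(meters, e, src, window, direction) {
  m_date <- as.Date(meters$test_time, tz = .TZ)
  e_date <- as.Date(e$entry_time, tz = .TZ)
  md <- data.frame(mi = seq_len(nrow(meters)), vin = meters$vin,
                   date = as.integer(m_date), stringsAsFactors = FALSE)
  ed <- data.frame(ei = seq_len(nrow(e)), vin = e$vin,
                   date = as.integer(e_date), stringsAsFactors = FALSE)
  cand <- merge(md, ed, by = c("vin", "date"))
  if (nrow(cand)) {
    off <- as.numeric(difftime(e$entry_time[cand$ei],
                               meters$test_time[cand$mi], units = "mins"))
    ok <- if (direction == "forward") off >= 0 & off <= window else abs(off) <= window
    cand <- cand[ok, , drop = FALSE]
    off <- off[ok]
  } else off <- numeric(0)

  matched_entry <- rep(NA_integer_, nrow(meters))
  matched_off <- rep(NA_real_, nrow(meters))
  if (nrow(cand)) {
    ord <- order(abs(off), e$entry_id[cand$ei])
    cand <- cand[ord, , drop = FALSE]; off <- off[ord]
    m_taken <- logical(nrow(meters)); e_taken <- logical(nrow(e))
    for (k in seq_len(nrow(cand))) {
      mi <- cand$mi[k]; ei <- cand$ei[k]
      if (!m_taken[mi] && !e_taken[ei]) {
        m_taken[mi] <- TRUE; e_taken[ei] <- TRUE
        matched_entry[mi] <- ei; matched_off[mi] <- off[k]
      }
    }
  }
  matched <- !is.na(matched_entry)
  res <- data.frame(
    record_id = meters$record_id, source = src,
    entry_id = ifelse(matched, e$entry_id[matched_entry], NA_character_),
    offset_minutes = matched_off,
    value_mgdl = ifelse(matched, e$value_mgdl[matched_entry], NA_integer_),
    status = ifelse(matched, "matched", "undocumented"),
    stringsAsFactors = FALSE)
  orphan <- setdiff(seq_len(nrow(e)), matched_entry[matched])
  if (length(orphan)) {
    res <- rbind(res, data.frame(
      record_id = NA_character_, source = src, entry_id = e$entry_id[orphan],
      offset_minutes = NA_real_, value_mgdl = e$value_mgdl[orphan],
      status = "orphan", stringsAsFactors = FALSE))
  }
  res
}

#' Flag documentation entries timestamped after discharge
#'
#' An entry whose `entry_time` is strictly later than the discharge instant
#' of its episode is anomalous (the test cannot have been documented for an
#' admitted patient); entries at the discharge instant are not flagged.
#' Entries whose VIN is unknown to the episode table are flagged separately
#' as orphan VINs.
#'
#' @param entries entry `data.frame`.
#' @param episodes episode `data.frame`.
#' @return `entries` with logical columns `post_discharge` and `orphan_vin`.
#' @export
flag_post_discharge <- function(entries, episodes) {
  i <- match(entries$vin, episodes$vin)
  out <- entries
  out$orphan_vin <- is.na(i)
  disc <- episodes$discharge[i]
  out$post_discharge <- !is.na(i) & entries$entry_time > disc
  out
}
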