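# Synthetic study generator
#
# Emulates the structure of a single-site ICU glucose-documentation audit:
# an admission cohort, a reference glucometer stream, and two independently
# hand-transcribed documentation streams carrying injected missingness and
# transcription errors, with full ground-truth labels.
#
# Two construction guarantees make downstream recovery exact:
#   * consecutive tests within an episode are >= 2 h apart;
#   * every transcription delay is < 120 min (in-window <= 59, late 61-115).
# Under forward-only nearest-offset matching, each entry's smallest-offset
# candidate is then its own test, so the greedy matcher recovers ownership
# exactly (see the methods vignette for the argument).

.nb_size <- function(mu, sd) {
  v <- sd^2
  if (v <= mu) stop("count model needs sd^2 > mean (overdispersion)")
  mu^2 / (v - mu)
}

#' Configuration of the synthetic study generator
#'
#' Defaults are calibrated to the audited study conditions: 234 admission
#' episodes yielding ~5049 tests; per-source undocumented fractions
#' 12.04% (paper log), 40.88% (flow sheet), 4.73% jointly; per-source error
#' fractions 2.21% / 8.11% with 1.64% jointly; docking latency median 5.5 h,
#' mean ~8 h, max 56 h; heavy-tailed per-patient test counts (diabetic mean
#' 60, SD 126; nondiabetic mean 19, SD 40); 40 post-discharge documentation
#' anomalies.
#'
#' @param n_patients number of admission episodes.
#' @param diabetes_mix named proportions for `yes`/`no`/`unknown` status.
#' @param test_count_model per-status negative-binomial `c(mu, sd)` targets.
#' @param los_model lognormal length-of-stay parameters (days) and the
#'   copula correlation `cor` linking stay length to test burden.
#' @param glucose_model lognormal meter-value model (mg/dL), truncated to
#'   the reportable range.
#' @param miss_prob named per-source probability that a result is never
#'   usably documented (no same-date entry within the matching window).
#' @param joint_miss_prob probability both sources miss the same result;
#'   must not exceed either marginal.
#' @param error_prob named per-source probability that a documented value
#'   is wrong.
#' @param joint_error_prob probability both documented values are wrong for
#'   the same test (a copied wrong value); must not exceed either marginal.
#' @param error_magnitude_model mixture of small slips (`slip_weight`,
#'   magnitudes 1..`slip_max` mg/dL) and adjacent-digit transpositions.
#' @param dock_latency_model lognormal docking latency (hours), truncated
#'   at `max_hours`.
#' @param delay_model gamma in-window transcription delay (minutes) and the
#'   fraction `late_frac` of missed results that still receive a late
#'   (out-of-window, 61–115 min) orphan entry.
#' @param gap_model uniform inter-test gap ranges (hours) by shift; minima
#'   must stay >= 2 h.
#' @param post_discharge_count late entries re-timestamped past discharge.
#' @param admit_window study admission window (two dates).
#' @param age_model,male_prob cohort demographics.
#' @param range reportable glucose range, mg/dL.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(
    n_patients = 234L,
    diabetes_mix = c(yes = 44, no = 93, unknown = 97) / 234,
    test_count_model = list(yes = c(mu = 60, sd = 126),
                            no = c(mu = 19, sd = 40),
                            unknown = c(mu = 6.6, sd = 15)),
    los_model = list(mean_days = 24.8, sd_days = 48.3, cor = 0.9),
    glucose_model = list(meanlog = log(140), sdlog = 0.30),
    miss_prob = c(paper_log = 0.1204, flow_sheet = 0.4088),
    joint_miss_prob = 0.0473,
    error_prob = c(paper_log = 0.0221, flow_sheet = 0.0811),
    joint_error_prob = 0.0164,
    error_magnitude_model = list(slip_weight = 0.75, slip_max = 15L),
    dock_latency_model = list(median_hours = 5.5, mean_hours = 8, max_hours = 56),
    delay_model = list(shape = 2, scale = 8, late_frac = 0.15),
    gap_model = list(day = c(2, 5), night = c(3, 8)),
    post_discharge_count = 40L,
    admit_window = c("2016-07-01", "2016-10-31"),
    age_model = c(mean = 57.5, sd = 17.4),
    male_prob = 0.56,
    range = reportable_range()) {

  probs <- c(miss_prob, joint_miss = joint_miss_prob,
             error_prob, joint_error = joint_error_prob,
             male = male_prob, late = delay_model$late_frac)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  need <- c("paper_log", "flow_sheet")
  if (!all(need %in% names(miss_prob)) || !all(need %in% names(error_prob)))
    stop("miss_prob and error_prob need named entries 'paper_log' and 'flow_sheet'")
  if (joint_miss_prob > min(miss_prob))
    stop("joint_miss_prob exceeds a per-source miss probability")
  if (joint_error_prob > min(error_prob))
    stop("joint_error_prob exceeds a per-source error probability")
  if (!all(c("yes", "no", "unknown") %in% names(diabetes_mix)) || sum(diabetes_mix) <= 0)
    stop("degenerate diabetes_mix")
  diabetes_mix <- diabetes_mix / sum(diabetes_mix)
  for (s in names(test_count_model)) .nb_size(test_count_model[[s]]["mu"],
                                              test_count_model[[s]]["sd"])
  if (min(unlist(gap_model)) < 2)
    stop("inter-test gaps must be at least 2 hours")
  if (n_patients < 1) stop("n_patients must be positive")

  structure(list(
    n_patients = as.integer(n_patients), diabetes_mix = diabetes_mix,
    test_count_model = test_count_model, los_model = los_model,
    glucose_model = glucose_model, miss_prob = miss_prob,
    joint_miss_prob = joint_miss_prob, error_prob = error_prob,
    joint_error_prob = joint_error_prob,
    error_magnitude_model = error_magnitude_model,
    dock_latency_model = dock_latency_model, delay_model = delay_model,
    gap_model = gap_model, post_discharge_count = as.integer(post_discharge_count),
    admit_window = admit_window, age_model = age_model, male_prob = male_prob,
    range = as.integer(range)
  ), class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Unknown keys are rejected by name so a typo in a config file fails at
#' startup rather than silently using a default.
#'
#' @param path YAML file whose top-level keys are [generator_config()]
#'   argument names.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in c("diabetes_mix", "miss_prob", "error_prob", "age_model"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  if (!is.null(vals$test_count_model))
    vals$test_count_model <- lapply(vals$test_count_model, unlist)
  if (!is.null(vals$gap_model)) vals$gap_model <- lapply(vals$gap_model, unlist)
  do.call(generator_config, vals)
}

.los_params <- function(los_model) {
  cv <- los_model$sd_days / los_model$mean_days
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(los_model$mean_days) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic admission cohort
#'
#' Draws episodes with demographics, diabetes status and a heavy-tailed
#' (lognormal) length of stay. Admission instants fall uniformly in the
#' configured admission window.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed; the output is reproducible byte-for-byte.
#' @return episode `data.frame` (vin, age, sex, diabetes, admit, discharge).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n_patients
  vin <- sprintf("VIN%05d", seq_len(n))
  age <- round(pmin(100, pmax(18, rnorm(n, config$age_model["mean"], config$age_model["sd"]))))
  sex <- ifelse(runif(n) < config$male_prob, "male", "female")
  diabetes <- sample(names(config$diabetes_mix), n, replace = TRUE,
                     prob = config$diabetes_mix)
  lp <- .los_params(config$los_model)
  los_days <- pmax(0.5, rlnorm(n, lp$meanlog, lp$sdlog))
  w0 <- as.POSIXct(config$admit_window[1], tz = .TZ)
  w1 <- as.POSIXct(config$admit_window[2], tz = .TZ)
  admit <- w0 + round(runif(n, 0, as.numeric(difftime(w1, w0, units = "mins")))) * 60
  discharge <- admit + round(los_days * 24 * 60) * 60
  data.frame(vin = vin, age = age, sex = sex, diabetes = diabetes,
             admit = admit, discharge = discharge, stringsAsFactors = FALSE)
}

#' Generate the reference glucometer stream
#'
#' Per-episode test counts follow a negative binomial whose mean/SD depend
#' on diabetes status; the count quantile is linked to the episode's length
#' of stay through a Gaussian copula (`los_model$cor`) so heavy testers are
#' long stayers, leaving the count marginal exact. Tests are placed from
#' admission with shift-dependent gaps of at least 2 h and end at least 2 h
#' before discharge; glucose values are lognormal truncated to the
#' reportable range; docking latency is lognormal (median/mean per config)
#' truncated at `max_hours`.
#'
#' @param episodes cohort from [generate_cohort()].
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @param shift a [shift_config()] used for the gap model.
#' @return meter `data.frame` (record_id, vin, test_time, glucose_mgdl,
#'   operator_id, dock_time).
#' @export
generate_meter_stream <- function(episodes, config, seed, shift = shift_config()) {
  stopifnot(inherits(config, "generator_config"), nrow(episodes) > 0)
  set.seed(seed + 1L)
  lp <- .los_params(config$los_model)
  rho <- config$los_model$cor
  n <- nrow(episodes)
  stay_h <- as.numeric(difftime(episodes$discharge, episodes$admit, units = "hours"))
  z_los <- (log(stay_h / 24) - lp$meanlog) / lp$sdlog
  z_cnt <- rho * z_los + sqrt(1 - rho^2) * rnorm(n)
  counts <- integer(n)
  for (s in names(config$test_count_model)) {
    idx <- episodes$diabetes == s
    if (!any(idx)) next
    m <- config$test_count_model[[s]]
    counts[idx] <- qnbinom(pnorm(z_cnt[idx]), size = .nb_size(m["mu"], m["sd"]),
                           mu = m["mu"])
  }
  cap <- pmax(0L, floor((stay_h - 4) / 2))   # room for 2 h spacing, 2 h tail margin
  counts <- pmin(counts, cap)

  total <- sum(counts)
  out_vin <- character(total); out_time <- numeric(total)
  k <- 0L
  gaps <- config$gap_model
  for (i in seq_len(n)) {
    N <- counts[i]
    if (N == 0L) next
    t0 <- as.numeric(episodes$admit[i]) + round(runif(1, 0, 120)) * 60
    lim <- as.numeric(episodes$discharge[i]) - 2 * 3600
    times <- numeric(N)
    t <- t0
    for (j in seq_len(N)) {
      if (j > 1L) {
        sh <- assign_shift(as.POSIXct(t, origin = "1970-01-01", tz = .TZ), shift)
        g <- runif(1, gaps[[sh]][1], gaps[[sh]][2])
        # keep room for the remaining tests at the 2 h minimum spacing
        g <- min(g, (lim - t) / 3600 - 2 * (N - j))
        g <- max(g, 2)
        t <- t + round(g * 60) * 60
      }
      times[j] <- t
    }
    out_vin[(k + 1L):(k + N)] <- episodes$vin[i]
    out_time[(k + 1L):(k + N)] <- times
    k <- k + N
  }
  test_time <- as.POSIXct(out_time, origin = "1970-01-01", tz = .TZ)
  glucose <- as.integer(pmin(config$range[2], pmax(config$range[1],
             round(rlnorm(total, config$glucose_model$meanlog,
                          config$glucose_model$sdlog)))))
  dl <- config$dock_latency_model
  sdlog <- sqrt(2 * log(dl$mean_hours / dl$median_hours))
  latency <- pmin(dl$max_hours, rlnorm(total, log(dl$median_hours), sdlog))
  ord <- order(out_vin, out_time)
  data.frame(record_id = sprintf("R%06d", seq_len(total)),
             vin = out_vin[ord],
             test_time = test_time[ord],
             glucose_mgdl = glucose[ord],
             operator_id = sprintf("T%02d", sample(13L, total, replace = TRUE)),
             dock_time = test_time[ord] + round(latency * 60) * 60,
             stringsAsFactors = FALSE)
}

# coupled two-source indicator draw: returns matrix [n x 2] of logicals with
# marginals p1, p2 and joint p12 (drawn as one 4-cell multinomial per row)
.coupled_draw <- function(n, p1, p2, p12) {
  u <- runif(n)
  both <- u < p12
  only1 <- u >= p12 & u < p1
  only2 <- u >= p1 & u < p1 + (p2 - p12)
  cbind(both | only1, both | only2)
}

.draw_delta <- function(glucose, model, range) {
  n <- length(glucose)
  delta <- integer(n)
  transpose_val <- function(g) {
    d <- strsplit(as.character(g), "")[[1]]
    if (length(d) < 2) return(g)
    pos <- if (length(d) == 2) 1L else sample(length(d) - 1L, 1L)
    d[c(pos, pos + 1L)] <- d[c(pos + 1L, pos)]
    as.integer(paste(d, collapse = ""))
  }
  slip <- function(g) {
    for (try in 1:50) {
      s <- sample(c(-1L, 1L), 1L) * sample(model$slip_max, 1L)
      if (g + s >= range[1] && g + s <= range[2]) return(s)
    }
    sample(model$slip_max, 1L) * if (g > mean(range)) -1L else 1L
  }
  use_slip <- runif(n) < model$slip_weight
  for (i in seq_len(n)) {
    if (!use_slip[i]) {
      v <- transpose_val(glucose[i])
      # keep the transposition tail inside the plausible clinical envelope
      if (v != glucose[i] && v >= range[1] && v <= range[2] &&
          abs(v - glucose[i]) <= 110) {
        delta[i] <- v - glucose[i]
        next
      }
    }
    delta[i] <- slip(glucose[i])
  }
  delta
}

#' Generate the two transcription streams with ground truth
#'
#' For every meter record a coupled per-source draw decides whether a usable
#' (same-date, in-window) entry exists in the paper log and/or the flow
#' sheet, honouring the configured joint missingness; a second coupled draw
#' decides per-source transcription errors, with both-source errors sharing
#' one wrong value (a copied transcription). Delivered entries get a gamma
#' delay truncated at 59 min and at the test's midnight (documentation is
#' dated the day of the test); a configurable fraction of missed results
#' still leaves a late orphan entry (61–115 min), from which the configured
#' number of post-discharge anomalies is drawn and re-timestamped past
#' discharge.
#'
#' @param meters meter stream from [generate_meter_stream()].
#' @param episodes the cohort (needed for discharge instants).
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return `list(entries = <entry data.frame>, ground_truth = <label data.frame>)`.
#'   Ground truth has one row per record and source with columns
#'   `transcribed` (an entry exists), `delivered` (usable in-window entry),
#'   `injected_error`, `injected_delta`, `entry_id`, `post_discharge`.
#' @export
generate_transcriptions <- function(meters, episodes, config, seed) {
  stopifnot(inherits(config, "generator_config"), nrow(meters) > 0)
  set.seed(seed + 2L)
  n <- nrow(meters)
  range <- config$range
  mp <- config$miss_prob; ep <- config$error_prob
  delivered <- !.coupled_draw(n, mp["paper_log"], mp["flow_sheet"], config$joint_miss_prob)
  erred <- .coupled_draw(n, ep["paper_log"], ep["flow_sheet"], config$joint_error_prob)
  shared_delta <- .draw_delta(meters$glucose_mgdl, config$error_magnitude_model, range)
  dm <- config$delay_model
  sources <- c("paper_log", "flow_sheet")

  gt <- vector("list", 2L)
  entries <- vector("list", 2L)
  for (si in 1:2) {
    src <- sources[si]
    del <- delivered[, si]
    err <- erred[, si] & del
    delta <- integer(n)
    both_err <- erred[, 1] & erred[, 2] & delivered[, 1] & delivered[, 2]
    delta[err & both_err] <- shared_delta[err & both_err]
    solo <- err & !both_err
    if (any(solo)) delta[solo] <- .draw_delta(meters$glucose_mgdl[solo],
                                              config$error_magnitude_model, range)
    late <- !del & runif(n) < dm$late_frac
    has_entry <- del | late
    lt <- as.POSIXlt(meters$test_time, tz = .TZ)
    mins_to_midnight <- 1439L - (lt$hour * 60L + lt$min)
    d_in <- pmin(59L, pmin(mins_to_midnight, round(rgamma(n, dm$shape, scale = dm$scale))))
    d_late <- 60L + sample(55L, n, replace = TRUE)   # 61..115 min
    delay <- ifelse(del, pmax(0L, d_in), d_late)
    entry_time <- meters$test_time + delay * 60
    value <- meters$glucose_mgdl + delta             # late entries copy the true value
    eid <- rep(NA_character_, n)
    eid[has_entry] <- sprintf("%s%06d", if (src == "paper_log") "P" else "F",
                              seq_len(sum(has_entry)))
    entries[[si]] <- data.frame(
      entry_id = eid[has_entry], source = rep(src, sum(has_entry)),
      vin = meters$vin[has_entry],
      entry_time = entry_time[has_entry], value_mgdl = value[has_entry],
      stringsAsFactors = FALSE)
    gt[[si]] <- data.frame(
      record_id = meters$record_id, vin = meters$vin, source = src,
      transcribed = has_entry, delivered = del,
      injected_error = err, injected_delta = delta,
      entry_id = eid, post_discharge = FALSE, stringsAsFactors = FALSE)
  }
  entries <- rbind(entries[[1]], entries[[2]])
  gt <- rbind(gt[[1]], gt[[2]])

  npd <- config$post_discharge_count
  if (npd > 0) {
    late_ids <- gt$entry_id[gt$transcribed & !gt$delivered]
    if (length(late_ids) < npd)
      stop("late-entry pool (", length(late_ids),
           ") smaller than post_discharge_count (", npd, ")")
    pick <- sample(late_ids, npd)
    idx <- match(pick, entries$entry_id)
    disc <- episodes$discharge[match(entries$vin[idx], episodes$vin)]
    entries$entry_time[idx] <- disc + round(runif(npd, 1, 48) * 60) * 60
    gt$post_discharge[match(pick, gt$entry_id)] <- TRUE
  }
  ord <- order(entries$source, entries$vin, entries$entry_time, entries$entry_id)
  entries <- entries[ord, ]
  rownames(entries) <- NULL
  rownames(gt) <- NULL
  list(entries = entries, ground_truth = gt)
}

#' Generate insulin administrations from flow-sheet entries
#'
#' Models the nurse dosing off the (possibly erroneous) flow-sheet value:
#' one administration record per flow-sheet entry, dose from the protocol
#' lookup on the transcribed value. Values outside the protocol domain are
#' flagged rather than dosed.
#'
#' @param entries entry `data.frame`; only `source == "flow_sheet"` rows are
#'   used.
#' @param protocol an [insulin_protocol()].
#' @return `data.frame` with entry_id, vin, admin_time, value_mgdl,
#'   dose_units, held, out_of_protocol.
#' @export
generate_insulin_administrations <- function(entries, protocol = default_protocol()) {
  stopifnot(inherits(protocol, "insulin_protocol"))
  fs <- entries[entries$source == "flow_sheet", , drop = FALSE]
  v <- fs$value_mgdl
  in_dom <- v >= protocol$bands$lo[1] & v < protocol$bands$hi[nrow(protocol$bands)]
  dose <- rep(NA_real_, length(v))
  if (any(in_dom)) dose[in_dom] <- protocol_dose(protocol, v[in_dom])
  data.frame(entry_id = fs$entry_id, vin = fs$vin, admin_time = fs$entry_time,
             value_mgdl = v, dose_units = dose,
             held = in_dom & v < protocol$hypo_threshold,
             out_of_protocol = !in_dom,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_meter_stream()] and [generate_transcriptions()] with one seed.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @param shift a [shift_config()].
#' @return `list(episodes, meters, entries, ground_truth)`.
#' @export
simulate_study <- function(config = generator_config(), seed, shift = shift_config()) {
  episodes <- generate_cohort(config, seed)
  meters <- generate_meter_stream(episodes, config, seed, shift)
  tr <- generate_transcriptions(meters, episodes, config, seed)
  list(episodes = episodes, meters = meters,
       entries = tr$entries, ground_truth = tr$ground_truth)
}
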