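test_that("windowed matching follows the same-VIN, same-date, one-hour rule", {
  m <- mk_meters(T0)                        # test at 08:00
  e <- mk_entries(T0 + mins(30))            # entry at 08:30
  res <- match_records(m, e)
  row <- res[res$source == "paper_log" & res$record_id == "R001", ]
  expect_identical(row$status, "matched")
  expect_equal(row$offset_minutes, 30)

  # only an entry outside the window -> undocumented, entry orphaned
  res2 <- match_records(m, mk_entries(T0 + mins(90)))
  expect_identical(res2$status[res2$record_id %in% "R001" &
                               res2$source == "paper_log"], "undocumented")
  expect_identical(res2$status[res2$status == "orphan"], "orphan")

  # nearest in-window candidate wins
  res3 <- match_records(m, mk_entries(T0 + mins(c(10, 50))))
  row3 <- res3[res3$source == "paper_log" & res3$record_id %in% "R001", ]
  expect_identical(row3$entry_id, "E001")
  expect_equal(row3$offset_minutes, 10)

  # forward-only: a transcription cannot precede its test
  res4 <- match_records(m, mk_entries(T0 - mins(10)))
  expect_identical(res4$status[res4$record_id %in% "R001" &
                               res4$source == "paper_log"], "undocumented")
  res5 <- match_records(m, mk_entries(T0 - mins(10)), direction = "symmetric")
  expect_identical(res5$status[res5$record_id %in% "R001" &
                               res5$source == "paper_log"], "matched")

  # the same-date clause: a 23:30 test never matches a 00:10 next-day entry
  late <- as.POSIXct("2016-07-10 23:30:00", tz = "UTC")
  res6 <- match_records(mk_meters(late), mk_entries(late + mins(40)))
  expect_identical(res6$status[res6$record_id %in% "R001" &
                               res6$source == "paper_log"], "undocumented")
})

test_that("duplicate ids are rejected and VINs never cross-match", {
  m <- mk_meters(T0)
  e <- mk_entries(rep(T0 + mins(5), 2), entry_id = c("E1", "E1"))
  expect_error(match_records(m, e), "duplicate entry_id")
  e2 <- mk_entries(T0 + mins(5), vin = "OTHER")
  res <- match_records(m, e2)
  expect_identical(res$status[res$record_id %in% "R001" &
                              res$source == "paper_log"], "undocumented")
})

test_that("greedy matching equals the brute-force assignment oracle when delays are below spacing", {
  # rich overlap regime: window wider than the inter-test spacing, delays
  # below the spacing, so several entries are candidates for several tests
  set.seed(31)
  for (rep in 1:60) {
    nm <- sample(1:3, 1)
    gap <- sample(61:119, nm, replace = TRUE)
    mt <- T0 + mins(cumsum(gap))
    owned <- which(runif(nm) < 0.7)
    delays <- sample(0:59, length(owned), replace = TRUE)
    et <- mt[owned] + mins(delays)
    if (!length(owned)) next
    res <- match_records(mk_meters(mt), mk_entries(et), window_minutes = 240)
    got <- res[res$status == "matched", ]
    orc <- oracle_match(mt, et, window = 240)
    expect_identical(nrow(got), orc$count)
    # oracle assignment is the ownership assignment; greedy must agree
    exp_pairs <- data.frame(record_id = sprintf("R%03d", owned),
                            entry_id = sprintf("E%03d", seq_along(owned)))
    expect_identical(got[order(got$record_id), c("record_id", "entry_id")],
                     exp_pairs, ignore_attr = TRUE)
  }
})

test_that("matching conserves counts and is one-to-one on arbitrary instances", {
  set.seed(32)
  for (rep in 1:40) {
    nm <- sample(1:6, 1); ne <- sample(0:6, 1)
    mt <- T0 + mins(sort(sample(0:600, nm)))
    et <- T0 + mins(sample(0:700, ne))
    res <- match_records(mk_meters(mt), mk_entries(et))
    mrows <- res[res$status != "orphan" & res$source == "paper_log", ]
    expect_identical(nrow(mrows), nm)  # matched + undocumented = all meters
    matched_e <- mrows$entry_id[!is.na(mrows$entry_id)]
    expect_false(anyDuplicated(matched_e) > 0)
    # orphans are exactly the unconsumed entries
    orph <- res$entry_id[res$status == "orphan"]
    expect_setequal(c(matched_e, orph), sprintf("E%03d", seq_len(ne)))
    # greedy never beats the brute-force maximum cardinality
    orc <- oracle_match(mt, et)
    expect_lte(length(matched_e), orc$count)
    # every match satisfies the window
    expect_true(all(mrows$offset_minutes[!is.na(mrows$offset_minutes)] >= 0 &
                    mrows$offset_minutes[!is.na(mrows$offset_minutes)] <= 60))
  }
})

test_that("post-discharge flagging uses a strict boundary and reports orphan VINs", {
  ep <- mk_episodes("V1", T0, T0 + 86400)
  e <- mk_entries(c(T0 + 86400 + 3600, T0 + 86400, T0 + 3600), vin = "V1")
  out <- flag_post_discharge(e, ep)
  expect_identical(out$post_discharge, c(TRUE, FALSE, FALSE))
  e2 <- mk_entries(T0, vin = "GHOST")
  out2 <- flag_post_discharge(e2, ep)
  expect_true(out2$orphan_vin)
  expect_false(out2$post_discharge)
})

test_that("the synthetic study carries exactly the configured number of post-discharge entries", {
  s <- simulate_study(generator_config(), seed = 33)
  flagged <- flag_post_discharge(s$entries, s$episodes)
  expect_identical(sum(flagged$post_discharge), 40L)
  expect_identical(sum(s$ground_truth$post_discharge), 40L)
})
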