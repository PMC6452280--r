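test_that("generation is deterministic under a fixed seed", {
  a <- simulate_study(small_config(), seed = 3)
  b <- simulate_study(small_config(), seed = 3)
  expect_identical(a, b)
  c <- simulate_study(small_config(), seed = 4)
  expect_false(identical(a$meters, c$meters))
})

test_that("cohort generation honours size, uniqueness and the diabetes mix", {
  cfg <- generator_config()
  ep <- generate_cohort(cfg, seed = 5)
  expect_identical(nrow(ep), 234L)
  expect_false(anyDuplicated(ep$vin) > 0)
  expect_true(all(ep$admit < ep$discharge))

  one <- generate_cohort(generator_config(n_patients = 1), seed = 5)
  expect_identical(nrow(one), 1L)

  # empirical proportions within 3 binomial SEs of the configured mix
  big <- generate_cohort(generator_config(n_patients = 10000L), seed = 6)
  for (s in c("yes", "no", "unknown")) {
    p <- cfg$diabetes_mix[[s]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(big$diabetes == s) - p), 3 * se)
  }
  expect_error(generator_config(diabetes_mix = c(yes = 0, no = 0, unknown = 0)),
               "degenerate")
})

test_that("per-patient test counts hit the heavy-tailed calibration targets", {
  cfg <- generator_config(n_patients = 1000L,
                          diabetes_mix = c(yes = 1, no = 0, unknown = 0))
  ep <- generate_cohort(cfg, seed = 8)
  m <- generate_meter_stream(ep, cfg, seed = 8)
  counts <- table(factor(m$vin, levels = ep$vin))
  expect_lt(abs(mean(counts) - 60) / 60, 0.10)
  # an episode drawing zero tests simply contributes no records
  expect_true(any(counts == 0))
})

test_that("meter stream construction invariants hold", {
  s <- simulate_study(small_config(), seed = 9)
  m <- s$meters
  expect_true(all(m$dock_time >= m$test_time))
  expect_true(all(m$glucose_mgdl >= 10 & m$glucose_mgdl <= 600))
  # tests stay inside the episode, ending at least 2 h before discharge
  ep <- s$episodes[match(m$vin, s$episodes$vin), ]
  expect_true(all(m$test_time >= ep$admit))
  expect_true(all(m$test_time <= ep$discharge - 2 * 3600))
  # consecutive tests within an episode are at least 2 h apart
  gaps <- unlist(tapply(as.numeric(m$test_time), m$vin,
                        function(x) diff(sort(x))))
  expect_true(all(gaps >= 2 * 3600))
  # docking latency is truncated at the configured maximum
  lat <- as.numeric(difftime(m$dock_time, m$test_time, units = "hours"))
  expect_lte(max(lat), 56)
})

test_that("no-error and all-miss limits behave as configured", {
  cfg <- generator_config(n_patients = 30L,
                          error_prob = c(paper_log = 0, flow_sheet = 0),
                          joint_error_prob = 0, post_discharge_count = 0L)
  s <- simulate_study(cfg, seed = 10)
  delivered <- s$ground_truth[s$ground_truth$delivered, ]
  v <- s$entries$value_mgdl[match(delivered$entry_id, s$entries$entry_id)]
  g <- s$meters$glucose_mgdl[match(delivered$record_id, s$meters$record_id)]
  expect_identical(v, g)

  cfg2 <- generator_config(n_patients = 10L,
                           miss_prob = c(paper_log = 1, flow_sheet = 1),
                           joint_miss_prob = 1, post_discharge_count = 0L,
                           delay_model = list(shape = 2, scale = 8, late_frac = 0))
  s2 <- simulate_study(cfg2, seed = 10)
  expect_identical(nrow(s2$entries), 0L)
  expect_false(any(s2$ground_truth$transcribed))
})

test_that("coupled missingness honours the joint probability and inclusion-exclusion", {
  expect_error(generator_config(joint_miss_prob = 0.5), "exceeds")
  expect_error(generator_config(joint_error_prob = 0.5), "exceeds")
  s <- simulate_study(generator_config(), seed = 12)
  gt <- s$ground_truth
  del <- matrix(gt$delivered, ncol = 2,
                dimnames = list(NULL, NULL))  # paper block then flow block
  miss_p <- sum(!del[, 1]); miss_f <- sum(!del[, 2])
  miss_b <- sum(!del[, 1] & !del[, 2])
  expect_lte(miss_b, min(miss_p, miss_f))
  n <- nrow(del)
  expect_identical(sum(del[, 1] & del[, 2]), n - miss_p - miss_f + miss_b)
})

test_that("ground-truth labels are internally consistent", {
  s <- simulate_study(generator_config(), seed = 13)
  gt <- s$ground_truth
  expect_true(all(gt$transcribed[gt$injected_error]))
  expect_identical(gt$injected_delta != 0L, gt$injected_error)
  expect_true(all(gt$delivered[gt$injected_error]))
  # injected deltas never push a value outside the reportable range
  g <- s$meters$glucose_mgdl[match(gt$record_id, s$meters$record_id)]
  v <- g + gt$injected_delta
  expect_true(all(v >= 10 & v <= 600))
  # every delivered or late row points at a real entry, others at none
  expect_identical(is.na(gt$entry_id), !gt$transcribed)
})

test_that("error magnitudes stay inside the audited clinical envelope", {
  s <- simulate_study(generator_config(), seed = 14)
  d <- s$ground_truth$injected_delta
  d <- d[d != 0]
  expect_gt(length(d), 100)
  expect_true(all(abs(d) <= 110))
  expect_true(any(abs(d) > 15))  # transposition tail present
})

test_that("insulin administrations dose off the transcribed flow-sheet value", {
  e <- mk_entries(T0 + mins(c(10, 20, 30)), value = c(85L, 210L, 5L),
                  source = "flow_sheet")
  adm <- generate_insulin_administrations(e)
  expect_equal(adm$dose_units, c(0, 4, NA))
  expect_identical(adm$out_of_protocol, c(FALSE, FALSE, TRUE))
  expect_identical(adm$held, c(FALSE, FALSE, FALSE))
  # monotone protocol: higher transcribed glucose never yields a lower dose
  set.seed(15)
  v <- sort(sample(10:600, 200, replace = TRUE))
  dd <- generate_insulin_administrations(
    mk_entries(T0 + mins(seq_along(v)), value = v, source = "flow_sheet"))
  expect_true(!is.unsorted(dd$dose_units))
})
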