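test_that("protocol validation enforces coverage, tiling and monotone doses", {
  expect_error(insulin_protocol(data.frame(lo = c(10, 200), hi = c(150, 601),
                                           dose = c(0, 4))), "tile")
  expect_error(insulin_protocol(data.frame(lo = 50, hi = 601, dose = 0)),
               "cover")
  expect_error(insulin_protocol(data.frame(lo = c(10, 150), hi = c(150, 601),
                                           dose = c(0, -2))), "non-negative")
  expect_error(insulin_protocol(data.frame(lo = c(10, 150, 300),
                                           hi = c(150, 300, 601),
                                           dose = c(0, 6, 2))),
               "non-decreasing")
  # a hold band below the hypoglycemia threshold may sit under dosed bands
  p <- default_protocol()
  expect_s3_class(p, "insulin_protocol")
  expect_identical(p$hypo_threshold, 70)
})

test_that("dose lookup uses half-open bands and matches a linear scan over the full range", {
  p <- default_protocol()
  expect_equal(protocol_dose(p, 120), 0)
  expect_equal(protocol_dose(p, c(150, 200, 250, 300, 350)), c(2, 4, 6, 8, 10))
  expect_equal(protocol_dose(p, c(149, 199, 349, 600)), c(0, 2, 8, 10))
  expect_error(protocol_dose(p, 601), "outside")
  expect_error(protocol_dose(p, 5), "outside")
  scan <- vapply(10:600, function(g) {
    b <- p$bands
    b$dose[which(g >= b$lo & g < b$hi)]
  }, numeric(1))
  expect_equal(protocol_dose(p, 10:600), scan)
})

test_that("insulin assessment flags exactly the dose-changing transcription errors", {
  a <- assess_insulin(210, 180)
  expect_equal(a$discrepancy, -2)
  expect_true(a$is_error)

  same <- assess_insulin(180, 180)
  expect_equal(same$discrepancy, 0)
  expect_false(same$is_error)

  within_band <- assess_insulin(160, 190)   # both in the 150-199 band
  expect_equal(within_band$discrepancy, 0)
  expect_false(within_band$is_error)

  # withholding a due dose is an error by definition
  withheld <- assess_insulin(220, 140)
  expect_true(withheld$is_error)
  expect_equal(withheld$discrepancy, -4)
})

test_that("insulin errors are a subset of transcription errors with protocol-consistent signs", {
  set.seed(51)
  m <- sample(80:400, 400, replace = TRUE)
  t <- sample(80:400, 400, replace = TRUE)
  a <- assess_insulin(m, t)
  expect_true(all(t[a$is_error] != m[a$is_error]))
  nz <- a$discrepancy != 0
  expect_identical(sign(a$discrepancy[nz]), sign(t[nz] - m[nz]))
  # band robustness: slips of < 10 mg/dL around mid-band values never
  # change the dose, hence never count as insulin errors
  g <- sample(c(170, 220, 270, 320), 100, replace = TRUE)
  slips <- assess_insulin(g, g + sample(-9:9, 100, replace = TRUE))
  expect_false(any(slips$is_error))
})

test_that("a constructed flow-sheet error set yields exactly its band-crossing insulin errors", {
  # 242 flow-sheet transcription errors of which 24 cross a dosing band:
  # 20 under-doses (meter 210 transcribed 180) and 4 over-doses (180 -> 210)
  n <- 242
  meter <- c(rep(210L, 20), rep(180L, 4), rep(160L, n - 24))
  trans <- c(rep(180L, 20), rep(210L, 4), rep(170L, n - 24))
  cl <- data.frame(record_id = sprintf("R%03d", 1:n),
                   vin = sprintf("V%02d", rep(1:30, length.out = n)),
                   glucose_mgdl = meter,
                   paper_error = FALSE, flow_error = TRUE,
                   paper_delta = NA_integer_, flow_delta = trans - meter)
  s <- summarize_insulin_errors(cl, n_patients = 234)
  fl <- s$by_category[s$by_category$category == "flow_sheet", ]
  expect_identical(fl$transcription_errors, 242L)
  expect_identical(fl$insulin_errors, 24L)
  # discrepancy range equals the brute-force min/max over the fixture
  disc <- assess_insulin(meter, trans)$discrepancy
  err <- disc != 0
  expect_equal(fl$min_discrepancy_u, min(disc[err]))
  expect_equal(fl$max_discrepancy_u, max(disc[err]))
  expect_equal(c(fl$min_discrepancy_u, fl$max_discrepancy_u), c(-2, 2))
  expect_identical(s$overall$unique_insulin_errors, 24L)
})

test_that("zero transcription errors yield zero insulin errors", {
  cl <- data.frame(record_id = "R1", vin = "V1", glucose_mgdl = 200L,
                   paper_error = FALSE, flow_error = FALSE,
                   paper_delta = 0L, flow_delta = 0L)
  s <- summarize_insulin_errors(cl, n_patients = 10)
  expect_identical(sum(s$by_category$insulin_errors), 0L)
  expect_identical(s$overall$unique_insulin_errors, 0L)
})

test_that("protocols round-trip through their YAML form", {
  p <- default_protocol()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(p, f)
  q <- read_protocol(f)
  expect_equal(q$bands, p$bands)
  expect_equal(q$hypo_threshold, p$hypo_threshold)
  expect_error(read_protocol(withr::local_tempfile()), "not found")
})
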