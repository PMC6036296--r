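hypoxia_chamber <- function(...) {
  microchamber_model(ambient_o2_kpa = percent_to_kpa(0.8), ...)
}

test_that("percent suppression arithmetic and bounds", {
  expect_equal(round(percent_suppression(389.7, 17.8), 1), 95.4)
  expect_equal(percent_suppression(50, 50), 0)
  expect_equal(percent_suppression(50, 0), 100)
  expect_lt(percent_suppression(50, 80), 0)  # enhancement is negative
  expect_error(percent_suppression(0, 10), "positive")
})

test_that("sulfite wells calibrate the zero-oxygen reference", {
  p <- preset_library("eos_fccp_hypoxia")
  # non-trivial sensor mapping: signal = 2*kPa + 1
  lv <- simulate_level_plate(p, chamber = hypoxia_chamber(),
                             noise = noise_model(seed = 5), n_wells = 3,
                             signal_gain = 2, signal_offset = 1)
  cal <- calibrate_zero(lv, percent_to_kpa(0.8))
  expect_equal(cal$zero_signal, 1, tolerance = 0.05)       # offset = true floor
  expect_equal(cal$ambient_signal, 2 * percent_to_kpa(0.8) + 1,
               tolerance = 0.05)
  # mapping recovers kPa from signal
  expect_equal(apply_calibration(cal$ambient_signal, cal),
               percent_to_kpa(0.8), tolerance = 1e-9)
  # pooled median over two sulfite wells, last 3 post-sulfite cycles
  sulf <- lv$levels[lv$levels$group == "SULFITE" & lv$levels$cycle >= 10, ]
  expect_equal(cal$zero_signal, median(sulf$signal))
  # constant-signal (no sulfite drop) plate fails calibration
  flat <- lv
  flat$levels$signal <- 5
  expect_error(calibrate_zero(flat, percent_to_kpa(0.8)), "not below")
})

test_that("calibration is idempotent on already-calibrated data", {
  ident <- structure(list(ambient_o2_kpa = 3, ambient_signal = 3,
                          zero_signal = 0), class = "oxygen_calibration")
  x <- c(0, 0.4, 1.7, 3)
  expect_equal(apply_calibration(x, ident), x, tolerance = 1e-15)
})

test_that("rate estimator recovers known consumption within 10%", {
  sched <- injection_schedule("MEDIA", 3)
  p <- rate_preset("const50", sched, n_cycles = 8,
                   ocr = list(baseline = 50,
                              responses = list(no_response())))
  lv <- simulate_level_plate(p, chamber = microchamber_model(),
                             noise = noise_model(seed = 2), n_wells = 4)
  cal <- calibrate_zero(lv, 20.2)
  est <- estimate_rates_from_levels(lv, cal)
  expect_equal(mean(est$traces$ocr), 50, tolerance = 0.10)
  # zero-consumption well reads ~0
  p0 <- rate_preset("null", sched, n_cycles = 8,
                    ocr = list(baseline = 0,
                               responses = list(no_response())))
  lv0 <- simulate_level_plate(p0, chamber = microchamber_model(),
                              noise = noise_model(seed = 3), n_wells = 2)
  est0 <- estimate_rates_from_levels(lv0, calibrate_zero(lv0, 20.2))
  expect_lt(max(abs(est0$traces$ocr)), 2)
})

test_that("estimator is linear in the true rate over a dilution series", {
  sched <- injection_schedule("MEDIA", 3)
  means <- sapply(c(0.5, 1, 2), function(f) {
    p <- rate_preset("dil", sched, n_cycles = 6,
                     ocr = list(baseline = 30 * f,
                                responses = list(no_response())))
    lv <- simulate_level_plate(p, chamber = microchamber_model(),
                               noise = noise_off(), n_wells = 1)
    est <- estimate_rates_from_levels(lv, calibrate_zero(lv, 20.2))
    mean(est$traces$ocr)
  })
  expect_equal(means[3] / means[2], 2, tolerance = 0.02)
  expect_equal(means[1] / means[2], 0.5, tolerance = 0.02)
})

test_that("hypoxic data need the hypoxic ambient anchor", {
  p <- preset_library("eos_fccp_hypoxia")
  lv <- simulate_level_plate(p, chamber = hypoxia_chamber(),
                             noise = noise_model(seed = 7), n_wells = 4)
  cal <- calibrate_zero(lv, percent_to_kpa(0.8))
  est <- estimate_rates_from_levels(lv, cal)
  fccp <- post_glucose_peak(est, glucose_event = "FCCP", channel = "ocr")
  expect_equal(mean(fccp$peak), 9.4, tolerance = 0.10)
  # analyzing the same plate against a normoxic ambient anchor biases the
  # back-diffusion correction by V*alpha*kd*(20.2 - 0.81) ~ +23 pmol/min
  cal_bad <- cal
  cal_bad$ambient_o2_kpa <- 20.2
  est_bad <- estimate_rates_from_levels(lv, cal_bad)
  fccp_bad <- post_glucose_peak(est_bad, glucose_event = "FCCP",
                                channel = "ocr")
  expect_gt(abs(mean(fccp_bad$peak) - 9.4), 5)
})

test_that("short fit windows yield missing rates with a warning", {
  p <- rate_preset("const", injection_schedule("MEDIA", 2), n_cycles = 4,
                   ocr = list(baseline = 20,
                              responses = list(no_response())))
  lv <- simulate_level_plate(p, chamber = microchamber_model(
    samples_per_measure = 4), noise = noise_off(), n_wells = 2)
  cal <- calibrate_zero(lv, 20.2)
  expect_warning(expect_error(estimate_rates_from_levels(lv, cal),
                              "enough samples"),
                 "fewer than 3")
})

test_that("level tables round-trip", {
  p <- preset_library("eos_fccp_hypoxia")
  lv <- simulate_level_plate(p, chamber = hypoxia_chamber(
    samples_per_measure = 5), noise = noise_model(seed = 9), n_wells = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_level_table(lv, f)
  back <- read_level_table(f)
  expect_equal(back$levels$signal, lv$levels$signal, tolerance = 1e-10)
  expect_equal(back$chamber$ambient_o2_kpa, lv$chamber$ambient_o2_kpa)
  expect_equal(as.data.frame(back$schedule), as.data.frame(lv$schedule))
})
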