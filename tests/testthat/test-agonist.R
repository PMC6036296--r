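test_that("peak height reports absolute peak and baseline-subtracted delta", {
  # baseline 24.5, post-stimulus max 572.8
  tr <- toy_trace(c(24.0, 24.5, 100, 572.8, 400, 300), channel = "ocr")
  sch <- injection_schedule("PMA", 2)
  res <- peak_height(tr, sch, stimulus = "PMA")
  expect_equal(res$baseline, 24.5)
  expect_equal(res$peak, 572.8)
  expect_equal(res$delta, 548.3)
  expect_equal(res$time_to_peak_min, 12)  # two cycles at 6 min
  # flat trace: no response
  flat <- toy_trace(rep(20, 6), channel = "ocr")
  res_flat <- peak_height(flat, sch, stimulus = "PMA")
  expect_equal(res_flat$delta, 0)
  expect_identical(res_flat$kinetic_class, "none")
  # stimulus after the final measurement
  expect_error(peak_height(toy_trace(c(1, 2), channel = "ocr"),
                           injection_schedule("PMA", 2), stimulus = "PMA"),
               "final measurement|beyond trace length")
})

test_that("primed schedules take the baseline before the primer", {
  tr <- toy_trace(c(38.5, 38.5, 38.5, 39.0, 38.8, 150.9, 120, 90),
                  channel = "ocr")
  sch <- injection_schedule(c("IL-5", "PAF"), c(3, 5))
  res <- peak_height(tr, sch, stimulus = "PAF")
  expect_equal(res$baseline, 38.5)  # before IL-5, not before PAF
  expect_equal(res$peak, 150.9)
  # explicit override: baseline just before the stimulus itself
  res2 <- peak_height(tr, sch, stimulus = "PAF", baseline_event = "PAF")
  expect_equal(res2$baseline, 38.8)
})

test_that("AUC above baseline matches hand trapezoid quadrature", {
  # post-stimulus points (6,30), (12,50), (18,20) above baseline 10:
  # trapezoids: 6*(20+40)/2 + 6*(40+10)/2 = 180 + 150 = 330
  tr <- toy_trace(c(10, 30, 50, 20), channel = "ocr")
  res <- peak_height(tr, injection_schedule("PMA", 1), stimulus = "PMA")
  expect_equal(res$auc_above_baseline, 330)
})

test_that("kinetic classes match the simulated preset kinetics", {
  neut <- simulate_rate_plate(preset_library("neut_pma"), n_wells = 2,
                              noise = noise_off())
  expect_identical(unname(classify_kinetics(neut, stimulus = "PMA")),
                   rep("transient", 2))
  # the transient preset is near baseline at the end of the long assay
  res <- peak_height(neut, stimulus = "PMA")
  expect_lt(res$persistence[1], 0.1)
  eos <- simulate_rate_plate(preset_library("eos_pma"), n_wells = 2,
                             noise = noise_off())
  expect_identical(unname(classify_kinetics(eos, stimulus = "PMA")),
                   rep("biphasic", 2))
  # monotone plateau: sustained by rule
  plateau <- toy_trace(c(10, 10, rep(100, 18)), channel = "ocr")
  expect_identical(unname(classify_kinetics(plateau,
                                            injection_schedule("PMA", 2),
                                            stimulus = "PMA")),
                   "sustained")
})

test_that("classification is invariant to uniform rescaling", {
  for (preset in c("neut_pma", "eos_pma")) {
    a <- simulate_rate_plate(preset_library(preset), n_wells = 1,
                             noise = noise_off())
    k1 <- classify_kinetics(a, stimulus = "PMA")
    a$traces$ocr <- a$traces$ocr * 7.3
    expect_identical(classify_kinetics(a, stimulus = "PMA"), k1)
  }
})

test_that("glucose-oxidation index quantifies the oligomycin-suppressible rise", {
  tr <- toy_trace(c(22.0, 22.9, 60.0, 62.1, 58.0, 30.0, 28.0),
                  channel = "ocr")
  sch <- injection_schedule(c("GLUC", "OLIGO"), c(2, 5))
  gi <- glucose_oxidation_index(tr, sch)
  expect_equal(gi$delta_ocr_glucose, 62.1 - 22.9)  # 39.2
  expect_equal(gi$oligo_suppression_fraction, (62.1 - 28) / 62.1)
  # suppression 0 when post-oligomycin min equals the post-glucose max
  tr2 <- toy_trace(c(20, 20, 50, 50, 50), channel = "ocr")
  gi2 <- glucose_oxidation_index(tr2, injection_schedule(c("GLUC", "OLIGO"),
                                                         c(2, 4)))
  expect_equal(gi2$oligo_suppression_fraction, 0)
  # neutrophil preset: OCR unresponsive to glucose
  flatp <- simulate_rate_plate(preset_library("neut_glucose_flat"),
                               n_wells = 2, noise = noise_off())
  expect_equal(glucose_oxidation_index(flatp)$delta_ocr_glucose, c(0, 0))
  expect_error(glucose_oxidation_index(tr, injection_schedule(
    c("OLIGO", "GLUC"), c(2, 5))), "precede")
})

test_that("measured peak never exceeds the continuous-model peak (noiseless)", {
  for (nm in c("eos_pma", "neut_pma", "eos_il5_paf", "neut_gmcsf_fmlp")) {
    p <- preset_library(nm)
    a <- simulate_rate_plate(p, n_wells = 1, noise = noise_off())
    stim <- p$schedule$name[nrow(p$schedule)]
    meas <- peak_height(a, stimulus = stim)$peak
    truth <- preset_truth(p)$ocr$events[[stim]][["peak"]]
    expect_lte(meas, truth + 1e-9)
    expect_gt(meas, 0.95 * truth)  # within one sampling interval's change
    # and the measured peak equals the brute-force post-stimulus maximum
    tr <- well_trace(a, "W01")
    post <- tr$ocr[tr$index > p$schedule$after_index[nrow(p$schedule)]]
    expect_equal(meas, max(post))
  }
})
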