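test_that("rate tables round-trip losslessly through the text dialect", {
  assay <- simulate_rate_plate(preset_library("eos_glyco_10mM"),
                               n_wells = 3, noise = noise_model(seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(assay, f)
  back <- read_rate_table(f)
  expect_equal(back$traces, assay$traces, tolerance = 1e-12)
  expect_equal(as.data.frame(back$schedule), as.data.frame(assay$schedule))
  expect_equal(back$cells_per_well, assay$cells_per_well)
  expect_equal(back$glucose_mM, assay$glucose_mM)
  # writing the re-read assay reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("trace validation rejects malformed plates", {
  tr <- toy_trace(c(1, 2, 3, 4))
  sched <- injection_schedule("GLUC", 2)
  expect_s3_class(plate_assay(tr, sched), "plate_assay")
  # duplicated (well, index)
  dup <- rbind(tr, tr[3, ])
  expect_error(plate_assay(dup, sched), "duplicated")
  # non-monotone time
  bad_t <- tr; bad_t$time_min[3] <- bad_t$time_min[2]
  expect_error(plate_assay(bad_t, sched), "time")
  # schedule event at/beyond trace end
  expect_error(plate_assay(tr, injection_schedule("GLUC", 4)),
               "beyond trace length")
  # missing mandatory column
  expect_error(plate_assay(tr[, setdiff(names(tr), "index")], sched),
               "missing column")
  # both channels absent in a row
  both_na <- tr; both_na$ecar[2] <- NA
  expect_error(plate_assay(both_na, sched), "at least one")
  # fewer than 2 measurements
  expect_error(plate_assay(tr[1, ], injection_schedule()), "fewer than 2")
})

test_that("windows partition the cycle range and empty windows are errors", {
  w <- segment_windows(injection_schedule(c("A", "B", "C"), c(3, 6, 9)), 12)
  expect_equal(w$label, c("baseline", "A", "B", "C"))
  expect_equal(w$start, c(1, 4, 7, 10))
  expect_equal(w$end, c(3, 6, 9, 12))
  w1 <- segment_windows(injection_schedule("A", 3), 6)
  expect_equal(w1$start, c(1, 4))
  expect_equal(w1$end, c(3, 6))
  # coincident injections leave an empty window
  sch <- injection_schedule("A", 3)
  sch2 <- rbind(as.data.frame(sch), data.frame(name = "B", after_index = 3,
                                               compound_conc = NA))
  class(sch2) <- class(sch)
  expect_error(segment_windows(sch2, 6), "empty window")
  # property: random schedules always partition [1, n] disjointly
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    k <- sample(1:4, 1)
    after <- sort(sample(seq_len(n - 1), k))
    w <- segment_windows(injection_schedule(paste0("E", seq_len(k)), after), n)
    covered <- unlist(Map(seq, w$start, w$end))
    expect_identical(sort(covered), seq_len(n))
    expect_false(anyDuplicated(covered) > 0)
  }
})

test_that("group aggregation matches brute-force mean/SEM", {
  rows <- do.call(rbind, lapply(1:3, function(w)
    toy_trace(c(10, 12, 14, 13)[c(w, w, w, w)] + 0:3, channel = "ocr",
              well = paste0("W", w), group = "g")))
  # index 1 holds OCR {10, 12, 14} across the three wells
  assay <- plate_assay(rows, injection_schedule("GLUC", 2))
  agg <- aggregate_group(assay, "g")
  at1 <- agg[agg$channel == "ocr" & agg$index == 1, ]
  expect_equal(at1$mean, 12)
  expect_equal(at1$sem, 2 / sqrt(3), tolerance = 1e-12)  # 1.1547
  expect_equal(at1$n, 3)
  # single well: SEM absent
  a1 <- plate_assay(toy_trace(c(5, 6), channel = "ocr"),
                    injection_schedule())
  agg1 <- aggregate_group(a1, "g")
  expect_equal(agg1$mean, c(5, 6))
  expect_true(all(is.na(agg1$sem)))
  # brute force on a random plate
  assay <- random_assay(n_wells = 6, seed = 3)
  agg <- aggregate_group(assay, "g1")
  tr <- assay$traces[assay$traces$group == "g1", ]
  for (i in unique(tr$index)) for (ch in c("ecar", "ocr")) {
    v <- tr[[ch]][tr$index == i]
    row <- agg[agg$index == i & agg$channel == ch, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sem, sd(v) / sqrt(length(v)))
  }
  expect_error(aggregate_group(assay, "nonesuch"), "unknown group")
})

test_that("MAD outlier rule flags but excludes only when enabled", {
  rows <- do.call(rbind, lapply(1:6, function(w)
    toy_trace(rep(10, 4) + 0.01 * w, channel = "ocr",
              well = paste0("W", w), group = "g")))
  rows$ocr[rows$well == "W6"] <- 500  # grossly deviant well
  assay <- plate_assay(rows, injection_schedule())
  agg <- aggregate_group(assay, "g")
  expect_identical(attr(agg, "flagged"), "W6")
  expect_equal(unique(agg$n), 6)  # flagged but retained by default
  agg_mad <- aggregate_group(assay, "g", outlier_rule = "mad")
  expect_equal(unique(agg_mad$n), 5)
  expect_true(all(abs(agg_mad$mean - 10.035) < 0.1))
})

test_that("density normalization is linear and undoes 2x seeding", {
  expect_equal(scale_to_reference_density(40, 150e3, 150e3), 40)
  expect_equal(scale_to_reference_density(40, 300e3, 150e3), 20)
  expect_error(scale_to_reference_density(40, 0, 150e3), "positive")
  p <- preset_library("eos_glyco_10mM")
  a2 <- simulate_rate_plate(p, n_wells = 2, noise = noise_off(),
                            cells_per_well = 300e3)
  a1 <- simulate_rate_plate(p, n_wells = 2, noise = noise_off())
  expect_equal(scale_to_reference_density(a2$traces$ecar, 300e3, 150e3),
               a1$traces$ecar, tolerance = 1e-12)
})
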