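# Zero-oxygen calibration from sulfite reference wells and level-to-rate
# estimation valid under hypoxia. The vendor's hypoxia rate calculator is
# proprietary; this module implements a transparent two-anchor affine
# calibration plus a diffusion-corrected least-squares slope estimator
# derived from the transient-microchamber model.

#' Zero-oxygen calibration from sulfite wells
#'
#' Sodium-sulfite injections chemically scavenge oxygen, so sulfite wells
#' provide a true zero-oxygen sensor reading. The calibration is affine with
#' two anchors: `zero_signal`, the pooled median sensor signal over the last
#' three post-sulfite measure phases of all sulfite wells, and the ambient
#' anchor `(ambient_o2_kpa, ambient_signal)`. By default the ambient signal
#' is the pre-consumption plateau: the median of the first sample of every
#' measure phase of the non-sulfite wells (each mix phase re-equilibrates
#' the chamber to ambient).
#'
#' @param levels a `level_traces` object ([simulate_level_plate()] or
#'   [read_level_table()]).
#' @param ambient_o2_kpa the chamber's true ambient oxygen tension, kPa
#'   (e.g. `percent_to_kpa(0.8)` for the hypoxic workstation).
#' @param ambient_signal optional explicit ambient anchor signal.
#' @param sulfite_group group label of the zero-reference wells.
#' @param n_reference_cycles post-sulfite cycles pooled for the zero anchor
#'   (default 3, taken from the end of the assay).
#' @return object of class `"oxygen_calibration"`: list with
#'   `ambient_o2_kpa`, `ambient_signal`, `zero_signal`.
#' @export
calibrate_zero <- function(levels, ambient_o2_kpa,
                           ambient_signal = NULL,
                           sulfite_group = "SULFITE",
                           n_reference_cycles = 3L) {
  stopifnot(inherits(levels, "level_traces"))
  lv <- levels$levels
  sulf <- lv[lv$group == sulfite_group, , drop = FALSE]
  if (!nrow(sulf)) stop("no sulfite reference wells in group '",
                        sulfite_group, "'")
  post <- sulf[sulf$cycle > levels$sulfite_after, , drop = FALSE]
  if (length(unique(post$cycle)) < n_reference_cycles)
    stop("need at least ", n_reference_cycles, " post-sulfite cycles")
  last_cycles <- sort(unique(post$cycle), decreasing = TRUE)
  last_cycles <- last_cycles[seq_len(n_reference_cycles)]
  zero_signal <- median(post$signal[post$cycle %in% last_cycles])
  if (is.null(ambient_signal)) {
    amb <- lv[lv$group != sulfite_group & lv$sample == 1L, , drop = FALSE]
    if (!nrow(amb))
      stop("no non-sulfite wells to anchor the ambient signal; supply ",
           "'ambient_signal'")
    ambient_signal <- median(amb$signal)
  }
  if (zero_signal >= ambient_signal)
    stop("sulfite signal (", signif(zero_signal, 4),
         ") is not below the ambient plateau (",
         signif(ambient_signal, 4), "); calibration failed")
  structure(list(ambient_o2_kpa = ambient_o2_kpa,
                 ambient_signal = ambient_signal,
                 zero_signal = zero_signal),
            class = "oxygen_calibration")
}

#' @export
print.oxygen_calibration <- function(x, ...) {
  cat("oxygen_calibration: zero signal ", signif(x$zero_signal, 4),
      ", ambient signal ", signif(x$ambient_signal, 4), " = ",
      x$ambient_o2_kpa, " kPa\n", sep = "")
  invisible(x)
}

#' Map sensor signal to oxygen tension
#'
#' Applies the affine two-anchor calibration:
#' `kPa = ambient_o2_kpa * (signal - zero) / (ambient_signal - zero)`.
#' Applying a calibration to data already in kPa with anchors `(zero = 0,
#' ambient_signal = ambient_o2_kpa)` is the identity, so calibration is
#' idempotent.
#'
#' @param signal numeric sensor readings.
#' @param calibration an [calibrate_zero()] result.
#' @return oxygen tension, kPa.
#' @export
apply_calibration <- function(signal, calibration) {
  stopifnot(inherits(calibration, "oxygen_calibration"))
  calibration$ambient_o2_kpa * (signal - calibration$zero_signal) /
    (calibration$ambient_signal - calibration$zero_signal)
}

#' Estimate consumption rates from oxygen-level traces
#'
#' Converts raw per-sample oxygen levels to per-cycle OCR using the
#' transient-microchamber balance `dC/dt = kd (C_amb - C) - OCR/(V alpha)`:
#' for each measure phase, an ordinary least-squares line is fitted to the
#' calibrated levels over the first half of the phase (where back-diffusion
#' curvature is smallest), and
#' `OCR = V alpha (kd (C_amb - C_bar) - slope)` with `C_bar` the fitted
#' window's mean level. Because the back-diffusion term is evaluated at the
#' actual chamber level, the estimator remains valid when the ambient
#' tension is hypoxic — provided the calibration's ambient anchor is the
#' true one; a normoxic anchor applied to hypoxic data biases the rate by
#' `V alpha kd` times the ambient error.
#'
#' @param levels a `level_traces` object.
#' @param calibration an [calibrate_zero()] result; its `ambient_o2_kpa` is
#'   used as `C_amb` in the back-diffusion correction.
#' @param chamber a [microchamber_model()] supplying `V`, `alpha`, `kd`;
#'   defaults to the one stored in `levels`.
#' @param fit_fraction fraction of each measure phase used in the fit
#'   (default 0.5).
#' @param include_sulfite keep the zero-reference wells in the output
#'   (default `FALSE`).
#' @return a [plate_assay()] whose traces carry the estimated OCR per cycle
#'   (`ecar` is `NA`); `time_min` is the midpoint of each fit window.
#'   Measure phases with fewer than 3 samples in the fit window yield `NA`
#'   with a warning.
#' @export
estimate_rates_from_levels <- function(levels, calibration,
                                       chamber = levels$chamber,
                                       fit_fraction = 0.5,
                                       include_sulfite = FALSE,
                                       sulfite_group = "SULFITE") {
  stopifnot(inherits(levels, "level_traces"),
            inherits(calibration, "oxygen_calibration"))
  va <- chamber$volume_ul * chamber$alpha_pmol_per_ul_kpa
  kd <- chamber$kd_per_min
  camb <- calibration$ambient_o2_kpa
  lv <- levels$levels
  if (!include_sulfite)
    lv <- lv[lv$group != sulfite_group, , drop = FALSE]
  short_window <- FALSE
  rows <- lapply(split(lv, list(lv$well, lv$cycle), drop = TRUE),
                 function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    t_rel <- d$time_min - d$time_min[1L]
    keep <- t_rel <= fit_fraction * chamber$measure_min + 1e-9
    ocr <- NA_real_
    tmid <- mean(d$time_min[keep])
    if (sum(keep) < 3L) {
      short_window <<- TRUE
    } else {
      kpa <- apply_calibration(d$signal[keep], calibration)
      tt <- d$time_min[keep]
      fit <- stats::lm.fit(cbind(1, tt), kpa)
      slope <- fit$coefficients[2L]
      ocr <- va * (kd * (camb - mean(kpa)) - slope)
    }
    data.frame(well = d$well[1L], group = d$group[1L],
               index = d$cycle[1L], time_min = tmid,
               ecar = NA_real_, ocr = ocr, stringsAsFactors = FALSE)
  })
  if (short_window)
    warning("fit windows with fewer than 3 samples yielded missing rates")
  traces <- do.call(rbind, rows)
  traces <- traces[!is.na(traces$ocr), , drop = FALSE]
  if (!nrow(traces)) stop("no measure phase had enough samples to fit")
  traces <- traces[order(traces$well, traces$index), , drop = FALSE]
  plate_assay(traces, levels$schedule,
              ambient_o2_percent = camb / 101.325 * 100)
}

#' Percent suppression of a rate under hypoxia
#'
#' `100 * (1 - hypoxic / normoxic)`: the percentage by which a rate measured
#' under hypoxia falls short of its normoxic counterpart. Ranges over
#' `(-Inf, 100]`; 0 at equality, 100 when the hypoxic rate is zero.
#'
#' @param normoxic normoxic rate (> 0).
#' @param hypoxic matching hypoxic rate.
#' @return percent suppression.
#' @examples
#' percent_suppression(389.7, 17.8) # ~95
#' @export
percent_suppression <- function(normoxic, hypoxic) {
  if (any(normoxic <= 0)) stop("'normoxic' must be positive")
  100 * (1 - hypoxic / normoxic)
}

#' Read / write oxygen-level traces
#'
#' Plain-text serialization of level traces: a `#`-metadata header
#' describing the microchamber, a long-format sample table (`well`, `group`,
#' `cycle`, `phase`, `sample`, `time_min`, `signal`), and a `# schedule`
#' block, mirroring the rate-table dialect.
#'
#' @param levels a `level_traces` object.
#' @param file path or connection.
#' @return `read_level_table()`: a `level_traces` object;
#'   `write_level_table()`: `file`, invisibly.
#' @export
write_level_table <- function(levels, file) {
  stopifnot(inherits(levels, "level_traces"))
  ch <- levels$chamber
  con <- textConnection("out", "w", local = TRUE)
  writeLines(c("# granuloflux level table v1",
               paste0("# volume_ul: ", ch$volume_ul),
               paste0("# kd_per_min: ", ch$kd_per_min),
               paste0("# ambient_o2_kpa: ", ch$ambient_o2_kpa),
               paste0("# measure_min: ", ch$measure_min),
               paste0("# mix_min: ", ch$mix_min),
               paste0("# samples_per_measure: ", ch$samples_per_measure),
               paste0("# alpha_pmol_per_ul_kpa: ", ch$alpha_pmol_per_ul_kpa),
               paste0("# sulfite_after: ", levels$sulfite_after)), con)
  utils::write.csv(levels$levels, con, row.names = FALSE, quote = FALSE)
  writeLines("# schedule", con)
  utils::write.csv(as.data.frame(levels$schedule)[, c("name", "after_index",
                                                      "compound_conc")],
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(out, file)
  invisible(file)
}

#' @rdname write_level_table
#' @export
read_level_table <- function(file) {
  lines <- readLines(file)
  meta <- list()
  for (ln in lines[grepl("^#\\s*\\w+\\s*:", lines)]) {
    key <- sub("^#\\s*(\\w+)\\s*:.*$", "\\1", ln)
    meta[[key]] <- as.numeric(sub("^#\\s*\\w+\\s*:\\s*", "", ln))
  }
  sched_at <- grep("^#\\s*schedule\\s*$", lines)
  if (!length(sched_at)) stop("no schedule block in ", file)
  body <- lines[seq_len(sched_at[1L] - 1L)]
  body <- body[!grepl("^#", body) & nzchar(body)]
  sched_lines <- lines[seq(sched_at[1L] + 1L, length(lines))]
  sched_lines <- sched_lines[!grepl("^#", sched_lines) & nzchar(sched_lines)]
  lv <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  sch <- if (length(sched_lines) > 1L) {
    s <- utils::read.csv(text = sched_lines, stringsAsFactors = FALSE)
    injection_schedule(s$name, s$after_index, s$compound_conc)
  } else injection_schedule()
  chamber <- microchamber_model(meta$volume_ul, meta$kd_per_min,
                                meta$ambient_o2_kpa, meta$measure_min,
                                meta$mix_min, meta$samples_per_measure,
                                meta$alpha_pmol_per_ul_kpa)
  structure(list(levels = lv, schedule = sch, chamber = chamber,
                 n_cycles = max(lv$cycle),
                 sulfite_after = as.integer(meta$sulfite_after)),
            class = "level_traces")
}
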