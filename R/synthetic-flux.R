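# Ground-truth plate simulator: continuous-time per-well rate kinetics,
# measure/mix microchamber oxygen-level traces, and presets anchored to
# published granulocyte group means.

#' Noise model for simulated plates
#'
#' Measured rates are `well_factor * r(t) + eps`: a per-well multiplicative
#' lognormal effect (unit mean, coefficient of variation `well_effect_cv`)
#' times the true rate, plus additive Gaussian measurement noise with
#' standard deviation `measurement_sd_prop * |signal| + measurement_sd_abs`.
#' Oxygen-level samples in level-mode simulations get additive Gaussian
#' noise of SD `level_sd_kpa`. An identical seed reproduces an identical
#' plate. Defaults are calibrated so that simulated SEMs at about 6 wells
#' are of the order of published kinetic-trace SEMs; they are a documented
#' calibration, not a claim about any instrument.
#'
#' @param well_effect_cv per-well multiplicative CV (default 0.05).
#' @param measurement_sd_prop proportional additive SD (default 0.02).
#' @param measurement_sd_abs absolute additive SD in rate units (default 0.5).
#' @param level_sd_kpa additive SD of level samples, kPa (default 0.02).
#' @param seed integer seed, or `NULL` to inherit the session RNG state.
#' @return list of class `"noise_model"`.
#' @export
noise_model <- function(well_effect_cv = 0.05, measurement_sd_prop = 0.02,
                        measurement_sd_abs = 0.5, level_sd_kpa = 0.02,
                        seed = NULL) {
  stopifnot(well_effect_cv >= 0, measurement_sd_prop >= 0,
            measurement_sd_abs >= 0, level_sd_kpa >= 0)
  structure(list(well_effect_cv = well_effect_cv,
                 measurement_sd_prop = measurement_sd_prop,
                 measurement_sd_abs = measurement_sd_abs,
                 level_sd_kpa = level_sd_kpa, seed = seed),
            class = "noise_model")
}

#' Noise-free noise model
#' @param seed optional seed (irrelevant to the output, kept for symmetry).
#' @return a [noise_model()] with all variances zero.
#' @export
noise_off <- function(seed = NULL)
  noise_model(0, 0, 0, 0, seed = seed)

#' Transient-microchamber model
#'
#' Physical stand-in for the small measurement volume formed when the sensor
#' cartridge lowers over the cell monolayer. During a measure phase the
#' chamber oxygen tension obeys
#' `dC/dt = kd (C_amb - C) - r(t) / (V alpha)` with `C` in kPa, `kd` the
#' back-diffusion constant, `V` the chamber volume and `alpha` the oxygen
#' solubility scaling (pmol O2 per microlitre per kPa); each mix phase
#' re-equilibrates the chamber to ambient. Defaults are documented,
#' configurable package choices.
#'
#' @param volume_ul chamber volume, microlitres (default 2.28).
#' @param kd_per_min back-diffusion constant, 1/min (default 0.05).
#' @param ambient_o2_kpa ambient oxygen tension, kPa (default 20.2, air-
#'   equilibrated medium; hypoxic workstation runs use about 0.81,
#'   see [percent_to_kpa()]).
#' @param measure_min,mix_min measure / mix phase durations, minutes.
#' @param samples_per_measure level samples recorded per measure phase.
#' @param alpha_pmol_per_ul_kpa O2 solubility scaling (default 10.5,
#'   aqueous medium at 37 C).
#' @return list of class `"microchamber_model"`.
#' @export
microchamber_model <- function(volume_ul = 2.28, kd_per_min = 0.05,
                               ambient_o2_kpa = 20.2, measure_min = 2,
                               mix_min = 1, samples_per_measure = 10,
                               alpha_pmol_per_ul_kpa = 10.5) {
  vals <- c(volume_ul, kd_per_min, ambient_o2_kpa, measure_min, mix_min,
            samples_per_measure, alpha_pmol_per_ul_kpa)
  if (any(vals[-2] <= 0) || kd_per_min < 0)
    stop("microchamber parameters must be positive (kd may be 0)")
  structure(list(volume_ul = volume_ul, kd_per_min = kd_per_min,
                 ambient_o2_kpa = ambient_o2_kpa, measure_min = measure_min,
                 mix_min = mix_min,
                 samples_per_measure = as.integer(samples_per_measure),
                 alpha_pmol_per_ul_kpa = alpha_pmol_per_ul_kpa),
            class = "microchamber_model")
}

#' Convert % O2 to partial pressure
#' @param percent oxygen fraction in percent.
#' @param barometric_kpa barometric pressure, kPa (default 101.325).
#' @return oxygen tension in kPa.
#' @export
percent_to_kpa <- function(percent, barometric_kpa = 101.325)
  percent / 100 * barometric_kpa

# ---- injection response kinetics ------------------------------------------

#' Injection response kinetics for rate presets
#'
#' Three kinetic families describe how a well's true rate `r(t)` reacts to
#' an injection at time `t_i`:
#' \describe{
#'   \item{`step_response(target, tau_min)`}{first-order approach to a new
#'     plateau: `r(t) = target + (r(t_i) - target) exp(-(t - t_i)/tau)`;
#'     `tau_min = 0` switches instantly.}
#'   \item{`transient_response(peak_delta, tau_rise, tau_decay)`}{a
#'     rise-decay burst riding on the rate at injection:
#'     `r(t) = r(t_i) + A (1 - exp(-(t-t_i)/tau_rise)) exp(-(t-t_i)/tau_decay)`.
#'     The amplitude `A` is solved so that the continuous-time peak of the
#'     burst equals `peak_delta`, i.e. presets are parameterized by the
#'     measured peak excursion they should produce.}
#'   \item{`biphasic_response(...)`}{the sum of two rise-decay terms with
#'     distinct time constants (relative weight `weight2` on the slower
#'     one), again scaled so the continuous-time maximum of the sum equals
#'     `peak_delta`.}
#'   \item{`no_response()`}{the injection leaves the rate law unchanged
#'     (vehicle/primer injections).}
#' }
#'
#' @param target new plateau rate (rate units of the channel).
#' @param tau_min approach time constant, minutes (>= 0).
#' @param peak_delta peak excursion above the rate at injection time.
#' @param tau_rise,tau_decay rise and decay time constants, minutes (> 0).
#' @param tau_rise1,tau_decay1,tau_rise2,tau_decay2 component time constants
#'   of a biphasic response.
#' @param weight2 relative amplitude of the second (slower) component.
#' @return a response descriptor for [rate_preset()].
#' @name injection_responses
NULL

#' @rdname injection_responses
#' @export
step_response <- function(target, tau_min = 1.5) {
  stopifnot(tau_min >= 0)
  list(type = "step", target = target, tau = tau_min)
}

# Internal: rise-decay shape and its continuous-time maximum.
.rd_shape <- function(u, tau_r, tau_d)
  (1 - exp(-u / tau_r)) * exp(-u / tau_d)

.rd_shape_max <- function(tau_r, tau_d)
  .rd_shape(tau_r * log(1 + tau_d / tau_r), tau_r, tau_d)

#' @rdname injection_responses
#' @export
transient_response <- function(peak_delta, tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > 0)
  list(type = "transient", tau_r = tau_rise, tau_d = tau_decay,
       peak_delta = peak_delta,
       A = peak_delta / .rd_shape_max(tau_rise, tau_decay))
}

#' @rdname injection_responses
#' @export
biphasic_response <- function(peak_delta, tau_rise1, tau_decay1,
                              tau_rise2, tau_decay2, weight2 = 0.8) {
  stopifnot(tau_rise1 > 0, tau_decay1 > 0, tau_rise2 > 0, tau_decay2 > 0,
            weight2 > 0)
  shape <- function(u)
    .rd_shape(u, tau_rise1, tau_decay1) +
      weight2 * .rd_shape(u, tau_rise2, tau_decay2)
  grid <- seq(0, 20 * (tau_rise2 + tau_decay2), by = 0.05)
  smax <- max(shape(grid))
  list(type = "biphasic", peak_delta = peak_delta,
       tau_r = c(tau_rise1, tau_rise2), tau_d = c(tau_decay1, tau_decay2),
       A = peak_delta / smax * c(1, weight2))
}

#' @rdname injection_responses
#' @export
no_response <- function() list(type = "none")

# ---- preset ----------------------------------------------------------------

#' Define a ground-truth kinetic preset
#'
#' A preset is the complete ground truth for one simulated assay condition:
#' the injection schedule, the measurement cadence, and for each channel a
#' baseline rate plus one injection response (see [injection_responses]) per
#' scheduled event. Presets for published conditions are available from
#' [preset_library()].
#'
#' @param name preset (and simulated group) name.
#' @param schedule an [injection_schedule()].
#' @param n_cycles total measurement cycles; must exceed the last event's
#'   `after_index`.
#' @param interval_min minutes between successive rate measurements
#'   (default 6, i.e. three measurements per ~18 min condition segment).
#' @param ecar,ocr `NULL`, or `list(baseline =, responses = list(...))` with
#'   one response (possibly `no_response()`) per scheduled event.
#' @param reference_cells cell count the baselines refer to (rates scale
#'   linearly with seeding density around this reference).
#' @param ambient_o2_percent ambient oxygen of the condition, % (20.9
#'   normoxia, 0.8 hypoxic workstation).
#' @param glucose_mM assay-medium glucose.
#' @return list of class `"rate_preset"`.
#' @export
rate_preset <- function(name, schedule, n_cycles, interval_min = 6,
                        ecar = NULL, ocr = NULL, reference_cells = 150e3,
                        ambient_o2_percent = 20.9, glucose_mM = 10) {
  if (is.null(ecar) && is.null(ocr))
    stop("preset needs at least one channel")
  n_cycles <- as.integer(n_cycles)
  if (nrow(schedule) && max(schedule$after_index) >= n_cycles)
    stop("'n_cycles' must exceed the last event's after_index")
  for (ch in list(ecar, ocr)) {
    if (is.null(ch)) next
    if (is.null(ch$baseline) || ch$baseline < 0)
      stop("channel baseline must be >= 0")
    if (length(ch$responses) != nrow(schedule))
      stop("each channel needs exactly one response per scheduled event ",
           "(use no_response() for inert injections)")
  }
  structure(list(name = name, schedule = schedule, n_cycles = n_cycles,
                 interval_min = interval_min, ecar = ecar, ocr = ocr,
                 reference_cells = reference_cells,
                 ambient_o2_percent = ambient_o2_percent,
                 glucose_mM = glucose_mM),
            class = "rate_preset")
}

#' @export
print.rate_preset <- function(x, ...) {
  cat("rate_preset '", x$name, "': ", x$n_cycles, " cycles @ ",
      x$interval_min, " min, injections: ",
      paste(x$schedule$name, collapse = ", "), "\n", sep = "")
  for (ch in c("ecar", "ocr")) if (!is.null(x[[ch]]))
    cat("  ", toupper(ch), " baseline ", x[[ch]]$baseline, "\n", sep = "")
  invisible(x)
}

# Internal: build the piecewise continuous-time rate law for one channel.
# Returns function(t) vectorized over absolute assay time (minutes).
# `event_times` are the clock times at which each scheduled injection takes
# effect. Step events restart the law from the total rate at injection;
# transient events ride on (and freeze) the rate at injection.
.rate_law <- function(channel, event_times) {
  starts <- -Inf
  funs <- list(local({
    b <- channel$baseline
    function(t) rep.int(b, length(t))
  }))
  for (k in seq_along(channel$responses)) {
    resp <- channel$responses[[k]]
    if (is.null(resp) || resp$type == "none") next
    t0 <- event_times[k]
    cur <- funs[[length(funs)]]
    r0 <- cur(t0)
    f <- switch(resp$type,
      step = local({
        t0 <- t0; tg <- resp$target; tau <- resp$tau; r0 <- r0
        if (tau == 0) function(t) rep.int(tg, length(t))
        else function(t) tg + (r0 - tg) * exp(-(t - t0) / tau)
      }),
      transient = ,
      biphasic = local({
        t0 <- t0; A <- resp$A; tau_r <- resp$tau_r; tau_d <- resp$tau_d
        r0 <- r0
        function(t) {
          u <- t - t0
          out <- rep.int(r0, length(t))
          for (j in seq_along(A))
            out <- out + A[j] * .rd_shape(u, tau_r[j], tau_d[j])
          out
        }
      }),
      stop("unknown response type: ", resp$type))
    starts <- c(starts, t0)
    funs[[length(funs) + 1L]] <- f
  }
  function(t) {
    seg <- findInterval(t, starts, left.open = TRUE)
    seg[seg < 1L] <- 1L
    out <- numeric(length(t))
    for (s in unique(seg)) {
      sel <- seg == s
      out[sel] <- funs[[s]](t[sel])
    }
    out
  }
}

# Internal: measurement clock times and injection clock times of a preset.
.preset_times <- function(preset) {
  times <- preset$interval_min * seq_len(preset$n_cycles)
  list(times = times,
       event_times = times[preset$schedule$after_index])
}

#' True measurement-grid rates and design anchors of a preset
#'
#' `preset_truth()` reports, per channel, the baseline and the designed
#' anchor of every non-inert injection response: the plateau `target` of a
#' step, or the absolute continuous-time peak (`rate at injection +
#' peak_delta`) of a transient/biphasic burst. `preset_rates()` evaluates
#' the continuous-time true rate on the preset's measurement grid.
#'
#' @param preset a [rate_preset()].
#' @return `preset_truth()`: nested list `channel -> (baseline, events)`;
#'   `preset_rates()`: data.frame `index`, `time_min`, plus one column per
#'   channel.
#' @export
preset_truth <- function(preset) {
  pt <- .preset_times(preset)
  out <- list()
  for (ch in c("ecar", "ocr")) {
    channel <- preset[[ch]]
    if (is.null(channel)) next
    law <- .rate_law(channel, pt$event_times)
    ev <- list()
    for (k in seq_len(nrow(preset$schedule))) {
      resp <- channel$responses[[k]]
      if (is.null(resp) || resp$type == "none") next
      nm <- preset$schedule$name[k]
      ev[[nm]] <- switch(resp$type,
        step = c(target = resp$target),
        c(peak = law(pt$event_times[k]) + resp$peak_delta))
    }
    out[[ch]] <- list(baseline = channel$baseline, events = ev)
  }
  out
}

#' @rdname preset_truth
#' @export
preset_rates <- function(preset) {
  pt <- .preset_times(preset)
  out <- data.frame(index = seq_len(preset$n_cycles), time_min = pt$times)
  for (ch in c("ecar", "ocr")) {
    if (is.null(preset[[ch]])) next
    out[[ch]] <- .rate_law(preset[[ch]], pt$event_times)(pt$times)
  }
  out
}

# ---- rate-mode simulation --------------------------------------------------

# Internal: draw unit-mean lognormal well factors with CV cv.
.well_factors <- function(n, cv) {
  if (cv == 0) return(rep.int(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a rate-mode flux plate
#'
#' Evaluates the preset's continuous-time rate laws at the measurement grid,
#' applies linear cell-density scaling, the per-well effect and measurement
#' noise of the [noise_model()], and packages the result as a
#' [plate_assay()] carrying the preset's schedule. With [noise_off()] the
#' measured rates equal the true grid rates exactly.
#'
#' @param preset a [rate_preset()].
#' @param schedule schedule to simulate under; defaults to the preset's own
#'   and must have the same number of events as the preset defines
#'   responses for.
#' @param n_wells wells to simulate (default 6).
#' @param noise a [noise_model()].
#' @param cells_per_well seeded cells; true rates scale by
#'   `cells_per_well / reference_cells`.
#' @param group group label for the simulated wells (default: preset name).
#' @param well_prefix prefix for generated well ids.
#' @return a [plate_assay()].
#' @examples
#' assay <- simulate_rate_plate(preset_library("eos_glyco_10mM"),
#'                              n_wells = 6, noise = noise_model(seed = 7))
#' glyco_params(assay)
#' @export
simulate_rate_plate <- function(preset, schedule = preset$schedule,
                                n_wells = 6, noise = noise_model(),
                                cells_per_well = preset$reference_cells,
                                group = preset$name, well_prefix = "W") {
  stopifnot(inherits(preset, "rate_preset"))
  if (nrow(schedule) != nrow(preset$schedule))
    stop("schedule has ", nrow(schedule), " events but the preset defines ",
         nrow(preset$schedule), " responses")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  pt <- list(times = preset$interval_min * seq_len(preset$n_cycles))
  pt$event_times <- pt$times[schedule$after_index]
  density <- cells_per_well / preset$reference_cells
  truth <- list()
  for (ch in c("ecar", "ocr"))
    if (!is.null(preset[[ch]]))
      truth[[ch]] <- .rate_law(preset[[ch]], pt$event_times)(pt$times) *
        density
  wf <- .well_factors(n_wells, noise$well_effect_cv)
  n_cyc <- preset$n_cycles
  rows <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    d <- data.frame(well = sprintf("%s%02d", well_prefix, w), group = group,
                    index = seq_len(n_cyc), time_min = pt$times,
                    ecar = NA_real_, ocr = NA_real_,
                    stringsAsFactors = FALSE)
    for (ch in names(truth)) {
      sig <- wf[w] * truth[[ch]]
      sd_i <- noise$measurement_sd_prop * abs(sig) + noise$measurement_sd_abs
      eps <- if (all(sd_i == 0)) 0 else stats::rnorm(n_cyc, 0, sd_i)
      d[[ch]] <- sig + eps
    }
    rows[[w]] <- d
  }
  plate_assay(do.call(rbind, rows), schedule,
              cells_per_well = cells_per_well,
              ambient_o2_percent = preset$ambient_o2_percent,
              glucose_mM = preset$glucose_mM)
}

# ---- level-mode simulation -------------------------------------------------

# Internal: RK4 integration of the measure-phase chamber ODE
#   dC/dt = kd (C_amb - C) - r(t)/(V alpha),
# clamped at C >= 0, fixed step (default 0.01 min). Returns C at `t_out`
# (absolute times within [t0, t0 + duration]).
.integrate_chamber <- function(rate_fun, c0, t0, duration, chamber,
                               t_out, dt = 0.01) {
  kd <- chamber$kd_per_min
  va <- chamber$volume_ul * chamber$alpha_pmol_per_ul_kpa
  camb <- chamber$ambient_o2_kpa
  deriv <- function(t, c) kd * (camb - c) - rate_fun(t) / va
  n_steps <- ceiling(duration / dt)
  tt <- t0
  cc <- c0
  out <- numeric(length(t_out))
  oi <- 1L
  grid_t <- numeric(n_steps + 1L)
  grid_c <- numeric(n_steps + 1L)
  grid_t[1L] <- tt; grid_c[1L] <- cc
  for (s in seq_len(n_steps)) {
    h <- min(dt, t0 + duration - tt)
    k1 <- deriv(tt, cc)
    k2 <- deriv(tt + h / 2, cc + h / 2 * k1)
    k3 <- deriv(tt + h / 2, cc + h / 2 * k2)
    k4 <- deriv(tt + h, cc + h * k3)
    cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (cc < 0) cc <- 0
    tt <- tt + h
    grid_t[s + 1L] <- tt
    grid_c[s + 1L] <- cc
  }
  stats::approx(grid_t, grid_c, xout = t_out, rule = 2)$y
}

#' Simulate a level-mode flux plate (raw oxygen traces)
#'
#' Generates raw per-sample oxygen-level traces as the instrument sensor
#' would record them: within each measure phase the transient-microchamber
#' oxygen tension follows `dC/dt = kd (C_amb - C) - r(t)/(V alpha)`
#' (integrated by fixed-step 4th-order Runge-Kutta at 0.01 min), each mix
#' phase re-equilibrates the chamber to ambient, and levels are reported as
#' sensor signal `gain * kPa + offset` plus Gaussian sample noise. In
#' addition to `n_wells` measurement wells, `sulfite_wells` cell-free
#' reference wells receive a sodium-sulfite injection (event `"SULFITE"`
#' after cycle `sulfite_after`) that chemically scavenges oxygen, driving
#' their level to the true zero with first-order kinetics and no mix-phase
#' recovery; these wells provide the zero-oxygen calibration anchor for
#' [calibrate_zero()].
#'
#' @inheritParams simulate_rate_plate
#' @param chamber a [microchamber_model()]; its `ambient_o2_kpa` should
#'   match the preset's ambient condition.
#' @param sulfite_wells number of zero-reference wells (default 2).
#' @param sulfite_after cycle after which sulfite is injected (default 1).
#' @param sulfite_k_per_min first-order O2 scavenging constant (default 3).
#' @param signal_gain,signal_offset affine map from kPa to recorded sensor
#'   signal (defaults 1 and 0: signal in kPa).
#' @return object of class `"level_traces"`: list with `levels` (data.frame
#'   `well`, `group`, `cycle`, `phase`, `sample`, `time_min`, `signal`),
#'   `schedule`, `chamber`, `n_cycles`, `sulfite_after`.
#' @export
simulate_level_plate <- function(preset, schedule = preset$schedule,
                                 chamber = microchamber_model(),
                                 noise = noise_model(), n_wells = 6,
                                 cells_per_well = preset$reference_cells,
                                 sulfite_wells = 2, sulfite_after = 1,
                                 sulfite_k_per_min = 3,
                                 signal_gain = 1, signal_offset = 0,
                                 group = preset$name, well_prefix = "W") {
  stopifnot(inherits(preset, "rate_preset"),
            inherits(chamber, "microchamber_model"))
  if (is.null(preset$ocr))
    stop("level-mode simulation needs an OCR channel in the preset")
  if (nrow(schedule) != nrow(preset$schedule))
    stop("schedule has ", nrow(schedule), " events but the preset defines ",
         nrow(preset$schedule), " responses")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  period <- chamber$measure_min + chamber$mix_min
  n_cyc <- preset$n_cycles
  # injections take effect during the mix after their anchor cycle
  event_times <- schedule$after_index * period - chamber$mix_min
  density <- cells_per_well / preset$reference_cells
  law <- .rate_law(preset$ocr, event_times)
  wf <- .well_factors(n_wells, noise$well_effect_cv)
  samp_rel <- seq(0, chamber$measure_min,
                  length.out = chamber$samples_per_measure)
  rows <- list()
  emit <- function(well, grp, cyc, t_abs, c_kpa) {
    sig <- signal_gain * c_kpa + signal_offset
    if (noise$level_sd_kpa > 0)
      sig <- sig + stats::rnorm(length(sig), 0,
                                signal_gain * noise$level_sd_kpa)
    data.frame(well = well, group = grp, cycle = cyc, phase = "measure",
               sample = seq_along(t_abs), time_min = t_abs, signal = sig,
               stringsAsFactors = FALSE)
  }
  for (w in seq_len(n_wells)) {
    rate_fun <- local({
      f <- wf[w] * density
      function(t) f * law(t)
    })
    for (cyc in seq_len(n_cyc)) {
      t0 <- (cyc - 1L) * period
      c_kpa <- .integrate_chamber(rate_fun, chamber$ambient_o2_kpa, t0,
                                  chamber$measure_min, chamber,
                                  t0 + samp_rel)
      rows[[length(rows) + 1L]] <-
        emit(sprintf("%s%02d", well_prefix, w), group, cyc, t0 + samp_rel,
             c_kpa)
    }
  }
  # sulfite zero-reference wells: ambient until injection, then first-order
  # decay to zero across measure and mix phases alike
  t_sulf <- sulfite_after * period - chamber$mix_min
  for (w in seq_len(sulfite_wells)) {
    for (cyc in seq_len(n_cyc)) {
      t0 <- (cyc - 1L) * period
      t_abs <- t0 + samp_rel
      c_kpa <- ifelse(t_abs <= t_sulf, chamber$ambient_o2_kpa,
                      chamber$ambient_o2_kpa *
                        exp(-sulfite_k_per_min * (t_abs - t_sulf)))
      rows[[length(rows) + 1L]] <-
        emit(sprintf("SULF%02d", w), "SULFITE", cyc, t_abs, c_kpa)
    }
  }
  sched <- schedule
  structure(list(levels = do.call(rbind, rows), schedule = sched,
                 chamber = chamber, n_cycles = n_cyc,
                 sulfite_after = as.integer(sulfite_after)),
            class = "level_traces")
}

#' @export
print.level_traces <- function(x, ...) {
  cat("level_traces:", length(unique(x$levels$well)), "wells,",
      x$n_cycles, "cycles,", x$chamber$samples_per_measure,
      "samples/measure phase\n")
  invisible(x)
}

# ---- preset library --------------------------------------------------------

# Internal: standard glycolysis stress-test preset (ECAR channel).
# Unprinted levels (baselines, oligomycin plateaus, residual post-2-DG
# acidification) are documented package choices.
.glyco_preset <- function(name, nga, gluc_peak, gc_level, dg_level,
                          glucose_mM) {
  rate_preset(
    name,
    injection_schedule(c("GLUC", "OLIGO", "2-DG"), c(3L, 6L, 9L),
                       c(paste(glucose_mM, "mM"), "2.5 uM", "100 mM")),
    n_cycles = 12L,
    ecar = list(baseline = nga,
                responses = list(step_response(gluc_peak),
                                 step_response(gc_level),
                                 step_response(dg_level))),
    glucose_mM = glucose_mM)
}

# Internal: mito stress-test preset (OCR channel).
.mito_preset <- function(name, basal, oligo_level, fccp_level, rotaa_level,
                         ambient_o2_percent = 20.9) {
  rate_preset(
    name,
    injection_schedule(c("OLIGO", "FCCP", "ROT/AA"), c(3L, 6L, 9L),
                       c("2.5 uM", "1.5 uM", "1/1 uM")),
    n_cycles = 12L,
    ocr = list(baseline = basal,
               responses = list(step_response(oligo_level),
                                step_response(fccp_level),
                                step_response(rotaa_level))),
    ambient_o2_percent = ambient_o2_percent)
}

# Internal: single-stimulus (PMA) preset with a long post-stimulus window.
.pma_preset <- function(name, baseline, peak, kinetics,
                        ambient_o2_percent = 20.9) {
  resp <- switch(kinetics,
    biphasic = biphasic_response(peak - baseline,
                                 tau_rise1 = 4, tau_decay1 = 15,
                                 tau_rise2 = 60, tau_decay2 = 400,
                                 weight2 = 0.8),
    transient = transient_response(peak - baseline,
                                   tau_rise = 8, tau_decay = 35))
  rate_preset(
    name,
    injection_schedule("PMA", 3L, "200 nM"),
    n_cycles = 27L,
    ocr = list(baseline = baseline, responses = list(resp)),
    ambient_o2_percent = ambient_o2_percent)
}

# Internal: primer + stimulus preset; the primer alone leaves OCR unchanged.
.primed_preset <- function(name, primer, stimulus, baseline, peak) {
  rate_preset(
    name,
    injection_schedule(c(primer, stimulus), c(3L, 5L),
                       c("10 ng/ml", "100 nM")),
    n_cycles = 18L,
    ocr = list(baseline = baseline,
               responses = list(no_response(),
                                transient_response(peak - baseline,
                                                   tau_rise = 6,
                                                   tau_decay = 45))))
}

#' Library of published-condition presets
#'
#' Returns ground-truth presets whose true trace levels are anchored to
#' published granulocyte group means (eosinophil/neutrophil extracellular
#' flux assays): glycolysis stress tests at 1 and 10 mM glucose, the
#' glucose-oxidation test with early oligomycin, PMA stimulation with the
#' cell-type-specific kinetics (eosinophil biphasic/sustained, neutrophil
#' transient), cytokine-primed agonist responses, and mitochondrial stress
#' tests under normoxia and hypoxia. Anchored values (post-glucose peaks,
#' stimulated OCR peaks, post-FCCP rates) are the published group means;
#' levels the source experiments did not print (baselines of unprinted
#' channels, oligomycin plateaus, hypoxic basal rates) are realistic,
#' documented package choices.
#'
#' @param name optional preset name; omit to get the full named list.
#' @return a [rate_preset()] (if `name` is given) or a named list of all
#'   presets.
#' @examples
#' names(preset_library())
#' preset_library("eos_pma")
#' @export
preset_library <- function(name = NULL) {
  lib <- list(
    # glycolysis stress tests; printed anchors: post-glucose ECAR peaks
    eos_glyco_1mM   = .glyco_preset("eos_glyco_1mM", 8, 31.2, 36, 9, 1),
    eos_glyco_10mM  = .glyco_preset("eos_glyco_10mM", 8, 41.6, 48, 9, 10),
    neut_glyco_1mM  = .glyco_preset("neut_glyco_1mM", 10, 48.4, 56, 11, 1),
    neut_glyco_10mM = .glyco_preset("neut_glyco_10mM", 10, 73.1, 84, 11, 10),
    # glucose-oxidation test: OCR 22.9 -> 62.1, suppressed by early OLIGO
    eos_glucose_oxidation = rate_preset(
      "eos_glucose_oxidation",
      injection_schedule(c("GLUC", "OLIGO"), c(3L, 6L),
                         c("10 mM", "2.5 uM")),
      n_cycles = 10L,
      ocr = list(baseline = 22.9,
                 responses = list(step_response(62.1),
                                  step_response(28))),
      ecar = list(baseline = 8,
                  responses = list(step_response(30),
                                   step_response(33)))),
    # neutrophil control: OCR unchanged by glucose
    neut_glucose_flat = rate_preset(
      "neut_glucose_flat",
      injection_schedule(c("GLUC", "OLIGO"), c(3L, 6L),
                         c("10 mM", "2.5 uM")),
      n_cycles = 10L,
      ocr = list(baseline = 10,
                 responses = list(no_response(), no_response())),
      ecar = list(baseline = 10,
                  responses = list(step_response(60),
                                   step_response(66)))),
    # PMA respiratory burst
    eos_pma  = .pma_preset("eos_pma", 24.5, 572.8, "biphasic"),
    neut_pma = .pma_preset("neut_pma", 13.9, 513, "transient"),
    neut_pma_normoxia = .pma_preset("neut_pma_normoxia", 13.9, 389.7,
                                    "transient"),
    neut_pma_hypoxia  = .pma_preset("neut_pma_hypoxia", 4, 17.8,
                                    "transient", ambient_o2_percent = 0.8),
    # cytokine priming + agonist
    eos_il5_paf     = .primed_preset("eos_il5_paf", "IL-5", "PAF",
                                     38.5, 150.9),
    eos_il5_fmlp    = .primed_preset("eos_il5_fmlp", "IL-5", "fMLP",
                                     38.6, 112.1),
    neut_gmcsf_fmlp = .primed_preset("neut_gmcsf_fmlp", "GM-CSF", "fMLP",
                                     12.5, 84.3),
    # mitochondrial stress tests, normoxia vs hypoxia (post-FCCP anchors)
    eos_fccp_normoxia = .mito_preset("eos_fccp_normoxia", 30, 12, 63.8, 8),
    eos_fccp_hypoxia  = .mito_preset("eos_fccp_hypoxia", 8, 3, 9.4, 2,
                                     ambient_o2_percent = 0.8))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stop("unknown preset '", name, "'; see names(preset_library())")
  lib[[name]]
}
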