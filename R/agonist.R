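# Agonist-stimulated respiratory responses: peak height, kinetic class,
# glucose-oxidation index. Peak height is reported as the absolute peak rate
# (responses are conventionally quoted "from X to Y"), with the
# baseline-subtracted delta always alongside.

# Internal: baseline cycle index for a (possibly primed) stimulus. Priming
# injections (IL-5, GM-CSF) do not reset the baseline: unless overridden,
# the baseline is the last measurement before the FIRST injection of the
# schedule, i.e. before the primer of a priming+stimulus pair.
.baseline_index <- function(schedule, baseline_event) {
  if (is.null(baseline_event)) return(schedule$after_index[1L])
  i <- match(baseline_event, schedule$name)
  if (is.na(i)) stop("baseline event '", baseline_event, "' not in schedule")
  schedule$after_index[i]
}

#' Peak-height response to an injected agonist
#'
#' Quantifies the oxygen-consumption (or acidification) response to a
#' stimulus injection: baseline rate, absolute peak over all post-stimulus
#' measurements to assay end, their difference (`delta`), time to peak,
#' trapezoid area under the curve above baseline, the persistence fraction
#' `(final - baseline)/delta`, and a kinetic class from
#' [classify_kinetics()].
#'
#' For primed schedules (e.g. IL-5 followed by PAF) the baseline is taken
#' before the first injection of the pair — priming agents alone do not
#' change the baseline rate — unless `baseline_event` names another anchor.
#'
#' @inheritParams glyco_params
#' @param stimulus schedule name of the stimulus injection (e.g. `"PMA"`,
#'   `"fMLP"`, `"PAF"`).
#' @param channel `"ocr"` (default) or `"ecar"`.
#' @param baseline_event optional schedule event before which the baseline
#'   is read; default: the first scheduled injection.
#' @param ... thresholds passed to [classify_kinetics()].
#' @return data.frame with one row per well: `well`, `group`, `baseline`,
#'   `peak`, `delta`, `time_to_peak_min`, `auc_above_baseline`,
#'   `persistence`, `kinetic_class`.
#' @examples
#' assay <- simulate_rate_plate(preset_library("eos_pma"), n_wells = 3,
#'                              noise = noise_model(seed = 1))
#' peak_height(assay, stimulus = "PMA")
#' @export
peak_height <- function(x, schedule = NULL, stimulus, channel = c("ocr", "ecar"),
                        baseline_event = NULL, ...) {
  channel <- match.arg(channel)
  rs <- .resolve_traces(x, schedule)
  sch <- rs$schedule
  si <- match(stimulus, sch$name)
  if (is.na(si)) stop("stimulus '", stimulus, "' not in schedule")
  stim_after <- sch$after_index[si]
  out <- lapply(rs$traces, function(tr) {
    n <- max(tr$index)
    if (stim_after >= n)
      stop("stimulus occurs after the final measurement")
    b_idx <- .baseline_index(sch, baseline_event)
    if (b_idx < 1L || b_idx >= n)
      stop("no pre-stimulus baseline measurement")
    baseline <- .window_values(tr, b_idx, channel)
    post_idx <- seq.int(stim_after + 1L, n)
    v <- .window_values(tr, post_idx, channel)
    t_post <- tr$time_min[match(post_idx, tr$index)]
    t_stim <- tr$time_min[match(stim_after, tr$index)]
    peak <- max(v)
    delta <- peak - baseline
    ttp <- t_post[which.max(v)] - t_stim
    auc <- if (length(v) > 1L)
      sum(diff(t_post) * (utils::head(v - baseline, -1L) +
                          utils::tail(v - baseline, -1L)) / 2)
    else 0
    persistence <- if (delta > 0) (v[length(v)] - baseline) / delta
                   else NA_real_
    kin <- .classify_kinetics_core(v, t_post - t_stim, baseline, ...)
    data.frame(well = tr$well[1L], group = tr$group[1L],
               baseline = baseline, peak = peak, delta = delta,
               time_to_peak_min = ttp, auc_above_baseline = auc,
               persistence = persistence, kinetic_class = kin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Internal classifier on post-stimulus values v at times t (min after
# stimulus) against a baseline. All thresholds are relative to the response
# delta, so the class is invariant to uniform rescaling of rates.
.classify_kinetics_core <- function(v, t, baseline,
                                    rel_height = 0.6, min_separation = 3L,
                                    persistence_threshold = 0.5,
                                    persistence_time_min = 90) {
  if (length(v) < 3L) {
    warning("post-stimulus window too short to classify kinetics")
    return("none")
  }
  delta <- max(v) - baseline
  if (delta <= 0) return("none")
  n <- length(v)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || v[i] > v[i - 1L]
    right_ok <- i == n || v[i] >= v[i + 1L]
    is_max[i] <- left_ok && right_ok
  }
  qual <- which(is_max & (v - baseline) >= rel_height * delta)
  if (length(qual) >= 2L &&
      max(qual) - min(qual) >= min_separation)
    return("biphasic")
  late <- which(t >= persistence_time_min)
  if (length(late)) {
    pers_late <- (v[late[1L]] - baseline) / delta
    if (pers_late >= persistence_threshold) return("sustained")
  }
  "transient"
}

#' Classify the kinetic shape of an agonist response
#'
#' Labels the post-stimulus trace as one of:
#' \describe{
#'   \item{biphasic}{at least two local maxima, each reaching at least
#'     `rel_height` (default 60%) of the response delta above baseline, and
#'     separated by at least `min_separation` cycles.}
#'   \item{sustained}{not biphasic, but still at or above
#'     `persistence_threshold` (default 0.5) of the delta at
#'     `persistence_time_min` (default 90) minutes post-stimulus.}
#'   \item{transient}{otherwise: the rate returns toward baseline.}
#'   \item{none}{no positive response, or too few post-stimulus
#'     measurements to judge (with a warning).}
#' }
#' Thresholds are relative to the response delta, so the classification is
#' invariant to uniform rescaling of the rates. The defaults are pragmatic
#' package choices, not instrument constants, and should be tuned to the
#' assay cadence.
#'
#' @inheritParams peak_height
#' @param rel_height fraction of the response delta a local maximum must
#'   reach to count as a phase.
#' @param min_separation minimum cycle separation between biphasic maxima.
#' @param persistence_threshold persistence fraction defining "sustained".
#' @param persistence_time_min minutes post-stimulus at which persistence is
#'   judged.
#' @return character vector, one class per well.
#' @export
classify_kinetics <- function(x, schedule = NULL, stimulus,
                              channel = c("ocr", "ecar"),
                              baseline_event = NULL,
                              rel_height = 0.6, min_separation = 3L,
                              persistence_threshold = 0.5,
                              persistence_time_min = 90) {
  res <- peak_height(x, schedule, stimulus, channel, baseline_event,
                     rel_height = rel_height,
                     min_separation = min_separation,
                     persistence_threshold = persistence_threshold,
                     persistence_time_min = persistence_time_min)
  stats::setNames(res$kinetic_class, res$well)
}

#' Glucose-oxidation index
#'
#' Detects mitochondrial oxidation of glucose-derived pyruvate as an
#' oligomycin-suppressible OCR rise after glucose: `delta_ocr_glucose` is
#' the maximal post-glucose OCR minus the last pre-glucose OCR, and
#' `oligo_suppression_fraction` is the fraction of the post-glucose maximum
#' lost after (early) oligomycin injection,
#' `(max post-glucose - min post-oligomycin) / max post-glucose`.
#'
#' @inheritParams glyco_params
#' @param glucose_event,oligo_event schedule names of the glucose and
#'   oligomycin injections (glucose must come first).
#' @return data.frame with one row per well: `well`, `group`,
#'   `delta_ocr_glucose` (pmol O2/min), `oligo_suppression_fraction`.
#' @export
glucose_oxidation_index <- function(x, schedule = NULL,
                                    glucose_event = "GLUC",
                                    oligo_event = "OLIGO") {
  rs <- .resolve_traces(x, schedule)
  sch <- rs$schedule
  gi <- match(glucose_event, sch$name)
  oi <- match(oligo_event, sch$name)
  if (is.na(gi) || is.na(oi))
    stop("schedule must contain '", glucose_event, "' and '",
         oligo_event, "'")
  if (sch$after_index[gi] >= sch$after_index[oi])
    stop("'", glucose_event, "' must precede '", oligo_event, "'")
  out <- lapply(rs$traces, function(tr) {
    n <- max(tr$index)
    pre <- .window_values(tr, sch$after_index[gi], "ocr")
    post_gluc_max <- max(.window_values(tr, .event_window(sch, n,
                                                          glucose_event),
                                        "ocr"))
    post_oligo_min <- min(.window_values(tr, .event_window(sch, n,
                                                           oligo_event),
                                         "ocr"))
    data.frame(well = tr$well[1L], group = tr$group[1L],
               delta_ocr_glucose = post_gluc_max - pre,
               oligo_suppression_fraction =
                 (post_gluc_max - post_oligo_min) / post_gluc_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
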