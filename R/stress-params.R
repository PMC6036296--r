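# Glycolysis and mitochondrial stress-test parameters from segmented traces.
# All parameters are computed per well and only then aggregated; group-mean
# traces are never parameterized directly.

# Internal: accept either a plate_assay or a single-well trace + schedule,
# returning list(traces = named list of per-well data.frames, schedule).
.resolve_traces <- function(x, schedule) {
  if (inherits(x, "plate_assay")) {
    if (is.null(schedule)) schedule <- x$schedule
    tr <- split(x$traces, x$traces$well)
  } else if (is.data.frame(x)) {
    if (is.null(schedule))
      stop("a schedule is required when passing a bare trace")
    if (length(unique(x$well)) > 1L)
      stop("bare trace must contain a single well; pass a plate_assay ",
           "for multi-well input")
    x <- x[order(x$index), , drop = FALSE]
    tr <- stats::setNames(list(x), x$well[1L])
  } else stop("'x' must be a plate_assay or a trace data.frame")
  list(traces = tr, schedule = schedule)
}

# Internal: channel values of a trace over a cycle-index window; errors on
# empty/missing data so parameter extrema are never taken over nothing.
.window_values <- function(trace, idx, channel) {
  v <- trace[[channel]][match(idx, trace$index)]
  if (!length(v) || all(is.na(v)))
    stop("no ", toupper(channel), " measurements in window [",
         min(idx), ",", max(idx), "]")
  v[!is.na(v)]
}

#' Glycolysis stress-test parameters
#'
#' Extracts the four glycolytic parameters from an ECAR trace segmented by a
#' glucose / oligomycin / 2-DG injection schedule:
#' \describe{
#'   \item{nga}{non-glycolytic acidification: the ECAR measurement prior to
#'     glucose injection.}
#'   \item{g}{glycolysis: maximal ECAR after glucose injection through the
#'     measurement prior to oligomycin injection, minus `nga`.}
#'   \item{gc}{glycolytic capacity: maximal ECAR after oligomycin injection
#'     through the measurement prior to 2-DG injection, minus `nga`.}
#'   \item{gr}{glycolytic reserve: `gc - g` (exactly).}
#' }
#' "Measurement prior to glucose injection" is read as the single last
#' baseline measurement (`baseline = "last"`, the default); a baseline-mean
#' variant is provided for robustness comparisons. No parameter is floored
#' at zero: negative reserves are legitimate outputs of the formulas.
#'
#' @param x a [plate_assay()] (computed for every well) or a single-well
#'   trace data.frame.
#' @param schedule an [injection_schedule()]; defaults to the assay's. Must
#'   contain the three events, in order.
#' @param baseline `"last"` (single pre-glucose measurement) or `"mean"`
#'   (mean of the baseline window).
#' @param events named character vector mapping roles `glucose`, `oligo`,
#'   `dg` to event names in the schedule.
#' @return data.frame with one row per well: `well`, `group`, `nga`, `g`,
#'   `gc`, `gr` (all mpH/min).
#' @examples
#' sched <- injection_schedule(c("GLUC", "OLIGO", "2-DG"), c(3, 6, 9))
#' assay <- simulate_rate_plate(preset_library("eos_glyco_10mM"),
#'                              n_wells = 3, noise = noise_model(seed = 1))
#' glyco_params(assay)
#' @export
glyco_params <- function(x, schedule = NULL,
                         baseline = c("last", "mean"),
                         events = c(glucose = "GLUC", oligo = "OLIGO",
                                    dg = "2-DG")) {
  baseline <- match.arg(baseline)
  rs <- .resolve_traces(x, schedule)
  sch <- rs$schedule
  for (role in c("glucose", "oligo", "dg"))
    if (!events[[role]] %in% sch$name)
      stop("schedule lacks the ", role, " event '", events[[role]], "'")
  out <- lapply(rs$traces, function(tr) {
    n <- max(tr$index)
    w <- segment_windows(sch, n)
    pre_idx <- seq.int(1L, w$end[which(w$label == "baseline")])
    nga <- if (baseline == "last") {
      .window_values(tr, max(pre_idx), "ecar")
    } else mean(.window_values(tr, pre_idx, "ecar"))
    post_gluc <- .event_window(sch, n, events[["glucose"]])
    post_oligo <- .event_window(sch, n, events[["oligo"]])
    g <- max(.window_values(tr, post_gluc, "ecar")) - nga
    gc <- max(.window_values(tr, post_oligo, "ecar")) - nga
    data.frame(well = tr$well[1L], group = tr$group[1L],
               nga = nga, g = g, gc = gc, gr = gc - g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mitochondrial stress-test parameters
#'
#' Extracts the six oxidative parameters from an OCR trace segmented by an
#' oligomycin / FCCP / rotenone+antimycin A schedule:
#' \describe{
#'   \item{non_mito}{non-mitochondrial OCR: minimum rate after rotenone/
#'     antimycin A addition through the end of the assay.}
#'   \item{br}{basal respiration: last pre-oligomycin OCR minus `non_mito`.}
#'   \item{pl}{proton leak: minimum OCR after oligomycin (through the
#'     measurement prior to FCCP) minus `non_mito`.}
#'   \item{atp_link}{ATP-linked respiration: `br - pl` (exactly).}
#'   \item{max_cap}{maximum respiratory capacity: maximal OCR after FCCP
#'     (through the measurement prior to rotenone/antimycin A) minus
#'     `non_mito`.}
#'   \item{spa_cap}{spare respiratory capacity: `max_cap - br` (exactly).}
#' }
#' Under hypoxia the FCCP response can fall below basal respiration; the
#' resulting negative spare capacity is returned as computed.
#'
#' @inheritParams glyco_params
#' @param events named character vector mapping roles `oligo`, `fccp`,
#'   `rotaa` to schedule event names.
#' @return data.frame with one row per well: `well`, `group`, `non_mito`,
#'   `br`, `pl`, `atp_link`, `max_cap`, `spa_cap` (all pmol O2/min).
#' @export
mito_params <- function(x, schedule = NULL,
                        events = c(oligo = "OLIGO", fccp = "FCCP",
                                   rotaa = "ROT/AA")) {
  rs <- .resolve_traces(x, schedule)
  sch <- rs$schedule
  for (role in c("oligo", "fccp", "rotaa"))
    if (!events[[role]] %in% sch$name)
      stop("schedule lacks the ", role, " event '", events[[role]], "'")
  out <- lapply(rs$traces, function(tr) {
    n <- max(tr$index)
    w <- segment_windows(sch, n)
    oligo_at <- sch$after_index[match(events[["oligo"]], sch$name)]
    non_mito <- min(.window_values(tr, .event_window(sch, n,
                                                     events[["rotaa"]]),
                                   "ocr"))
    br <- .window_values(tr, oligo_at, "ocr") - non_mito
    pl <- min(.window_values(tr, .event_window(sch, n, events[["oligo"]]),
                             "ocr")) - non_mito
    max_cap <- max(.window_values(tr, .event_window(sch, n,
                                                    events[["fccp"]]),
                                  "ocr")) - non_mito
    data.frame(well = tr$well[1L], group = tr$group[1L],
               non_mito = non_mito, br = br, pl = pl,
               atp_link = br - pl, max_cap = max_cap,
               spa_cap = max_cap - br, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Post-glucose peak rate
#'
#' The absolute (not baseline-subtracted) maximal rate in the window from
#' the first measurement after glucose injection through the measurement
#' prior to the next injection (or the end of the assay). This is the
#' "post-glucose peak" used to compare glycolytic responses across glucose
#' concentrations and, on the OCR channel, to detect glucose oxidation.
#'
#' @inheritParams glyco_params
#' @param channel `"ecar"` or `"ocr"`.
#' @param glucose_event schedule name of the glucose injection.
#' @return data.frame with columns `well`, `group`, `peak`.
#' @export
post_glucose_peak <- function(x, schedule = NULL,
                              channel = c("ecar", "ocr"),
                              glucose_event = "GLUC") {
  channel <- match.arg(channel)
  rs <- .resolve_traces(x, schedule)
  sch <- rs$schedule
  if (!glucose_event %in% sch$name)
    stop("schedule lacks the glucose event '", glucose_event, "'")
  out <- lapply(rs$traces, function(tr) {
    idx <- .event_window(sch, max(tr$index), glucose_event)
    data.frame(well = tr$well[1L], group = tr$group[1L],
               peak = max(.window_values(tr, idx, channel)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
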