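#' @importFrom stats median sd
NULL

# Internal: canonical trace columns, in order.
.trace_cols <- c("well", "group", "index", "time_min", "ecar", "ocr")

#' Construct an injection schedule
#'
#' An injection schedule is an ordered table of injection events. Each event
#' is anchored to a measurement cycle: `after_index` is the last measurement
#' cycle completed before the injection takes effect, reflecting the fact
#' that plate instruments queue injections between measure/mix cycles rather
#' than at clock times. When an experimental record gives an injection clock
#' time instead (e.g. "glucose at 36 min"), map it to the last measurement at
#' or before that time before building the schedule.
#'
#' @param name character vector of event names, e.g. `"GLUC"`, `"OLIGO"`,
#'   `"2-DG"`, `"FCCP"`, `"ROT/AA"`, `"PMA"`, `"IL-5"`, `"fMLP"`, `"PAF"`,
#'   `"GM-CSF"`, `"SULFITE"`, `"MEDIA"`.
#' @param after_index integer vector, same length as `name`; the 1-based
#'   measurement cycle after which each injection occurs. Must be strictly
#'   increasing and >= 1.
#' @param compound_conc optional character vector of compound concentrations
#'   (metadata only, e.g. `"10 mM"`).
#' @return A `data.frame` of class `"flux_schedule"` with columns `name`,
#'   `after_index`, `compound_conc`.
#' @examples
#' injection_schedule(c("GLUC", "OLIGO", "2-DG"), c(3, 6, 9),
#'                    c("10 mM", "2.5 uM", "100 mM"))
#' @export
injection_schedule <- function(name = character(), after_index = integer(),
                               compound_conc = NA_character_) {
  name <- as.character(name)
  after_index <- as.integer(after_index)
  if (length(name) != length(after_index))
    stop("'name' and 'after_index' must have equal length")
  if (length(after_index)) {
    if (any(is.na(after_index)) || any(after_index < 1L))
      stop("'after_index' must be >= 1")
    if (any(diff(after_index) <= 0L))
      stop("injection events must be strictly ordered by 'after_index'")
  }
  compound_conc <- rep_len(as.character(compound_conc),
                           length.out = length(name))
  out <- data.frame(name = name, after_index = after_index,
                    compound_conc = compound_conc,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_schedule", "data.frame")
  out
}

# Internal: validate a long-format trace table (one row per well x cycle).
.validate_traces <- function(traces) {
  need <- c("well", "group", "index", "time_min")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))
  if (!any(c("ecar", "ocr") %in% names(traces)))
    stop("trace table needs at least one of 'ecar'/'ocr'")
  if (!"ecar" %in% names(traces)) traces$ecar <- NA_real_
  if (!"ocr" %in% names(traces)) traces$ocr <- NA_real_
  traces <- traces[, .trace_cols]
  traces$well <- as.character(traces$well)
  traces$group <- as.character(traces$group)
  traces$index <- as.integer(traces$index)
  traces$time_min <- as.numeric(traces$time_min)
  traces$ecar <- as.numeric(traces$ecar)
  traces$ocr <- as.numeric(traces$ocr)
  if (any(is.na(traces$index)) || any(traces$index < 1L))
    stop("measurement 'index' must be a positive integer")
  if (any(is.na(traces$time_min)) || any(traces$time_min < 0))
    stop("'time_min' must be >= 0")
  if (any(is.na(traces$ecar) & is.na(traces$ocr)))
    stop("each measurement needs at least one of ecar/ocr")
  if (anyDuplicated(traces[, c("well", "index")]))
    stop("duplicated (well, index) measurement")
  traces <- traces[order(traces$well, traces$index), , drop = FALSE]
  rownames(traces) <- NULL
  for (w in unique(traces$well)) {
    tw <- traces[traces$well == w, , drop = FALSE]
    if (nrow(tw) < 2L)
      stop("well ", w, " has fewer than 2 measurements")
    if (length(unique(tw$group)) != 1L)
      stop("well ", w, " is assigned to more than one group")
    if (any(diff(tw$time_min) <= 0))
      stop("time must increase strictly with index within well ", w)
  }
  traces
}

#' Assemble a plate assay
#'
#' Bundles the per-well kinetic rate traces of one flux plate with the shared
#' injection schedule and assay metadata. Traces are stored long format (one
#' row per well and measurement cycle). Negative rates are physically
#' meaningful sensor readouts and are retained untouched.
#'
#' @param traces data.frame with columns `well`, `group`, `index`, `time_min`
#'   and at least one of `ecar` (mpH/min), `ocr` (pmol O2/min).
#' @param schedule a [injection_schedule()]; every event's `after_index` must
#'   fall strictly before the last measurement cycle.
#' @param cells_per_well cells seeded per well (default 150e3, i.e. 3e6/ml in
#'   50 ul, the density giving an even granulocyte monolayer).
#' @param ambient_o2_percent ambient oxygen as % (20.9 normoxia, 0.8 the
#'   hypoxic workstation condition).
#' @param glucose_mM assay-medium glucose concentration.
#' @return An object of class `"plate_assay"`: a list with elements `traces`,
#'   `schedule`, `cells_per_well`, `ambient_o2_percent`, `glucose_mM`.
#' @export
plate_assay <- function(traces, schedule = injection_schedule(),
                        cells_per_well = 150e3, ambient_o2_percent = 20.9,
                        glucose_mM = 10) {
  traces <- .validate_traces(traces)
  if (!inherits(schedule, "flux_schedule"))
    schedule <- injection_schedule(schedule$name, schedule$after_index,
                                   schedule$compound_conc)
  n_max <- max(traces$index)
  if (nrow(schedule) && any(schedule$after_index >= n_max))
    stop("schedule event beyond trace length (after_index must be < ",
         n_max, ")")
  if (!is.numeric(cells_per_well) || cells_per_well <= 0)
    stop("'cells_per_well' must be positive")
  structure(list(traces = traces, schedule = schedule,
                 cells_per_well = cells_per_well,
                 ambient_o2_percent = ambient_o2_percent,
                 glucose_mM = glucose_mM),
            class = "plate_assay")
}

#' @export
print.plate_assay <- function(x, ...) {
  wells <- unique(x$traces$well)
  cat("plate_assay:", length(wells), "wells,",
      max(x$traces$index), "measurement cycles,",
      nrow(x$schedule), "injection(s)\n")
  if (nrow(x$schedule))
    cat("  injections:", paste0(x$schedule$name, " (after cycle ",
                                x$schedule$after_index, ")",
                                collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$traces$group), collapse = ", "), "\n")
  cat("  cells/well:", format(x$cells_per_well, big.mark = ","),
      " ambient O2:", x$ambient_o2_percent, "%\n")
  invisible(x)
}

#' Extract the kinetic trace of one well
#'
#' @param assay a [plate_assay()].
#' @param well well label.
#' @return data.frame with the well's measurements ordered by cycle index.
#' @export
well_trace <- function(assay, well) {
  stopifnot(inherits(assay, "plate_assay"))
  tr <- assay$traces[assay$traces$well == well, , drop = FALSE]
  if (!nrow(tr)) stop("unknown well: ", well)
  rownames(tr) <- NULL
  tr
}

#' List wells of a plate assay
#' @param assay a [plate_assay()].
#' @param group optional group label to restrict to.
#' @return character vector of well labels.
#' @export
assay_wells <- function(assay, group = NULL) {
  tr <- assay$traces
  if (!is.null(group)) {
    if (!group %in% tr$group) stop("unknown group: ", group)
    tr <- tr[tr$group == group, , drop = FALSE]
  }
  unique(tr$well)
}

#' Read a rate table from disk
#'
#' Reads the package's canonical plain-text plate dialect: a long-format
#' delimited table (`well,group,index,time_min,ecar,ocr`) preceded by `#`
#' metadata headers and followed by a `# schedule` block holding the
#' injection table (`name,after_index,compound_conc`). The format is lossless
#' with respect to [write_rate_table()]; row order in the rate block is
#' irrelevant.
#'
#' @param file path or connection to the table.
#' @return A [plate_assay()].
#' @seealso [write_rate_table()]
#' @export
read_rate_table <- function(file) {
  lines <- readLines(file)
  meta <- list(cells_per_well = 150e3, ambient_o2_percent = 20.9,
               glucose_mM = 10)
  is_meta <- grepl("^#\\s*\\w+\\s*:", lines)
  for (ln in lines[is_meta]) {
    key <- sub("^#\\s*(\\w+)\\s*:.*$", "\\1", ln)
    val <- sub("^#\\s*\\w+\\s*:\\s*", "", ln)
    if (key %in% names(meta)) meta[[key]] <- as.numeric(val)
  }
  sched_at <- grep("^#\\s*schedule\\s*$", lines)
  body <- lines[!grepl("^#", lines)]
  if (length(sched_at)) {
    split_line <- sched_at[1L]
    rate_lines <- lines[seq_len(split_line - 1L)]
    sched_lines <- lines[seq(split_line + 1L, length(lines))]
    rate_lines <- rate_lines[!grepl("^#", rate_lines) & nzchar(rate_lines)]
    sched_lines <- sched_lines[!grepl("^#", sched_lines) & nzchar(sched_lines)]
  } else {
    rate_lines <- body[nzchar(body)]
    sched_lines <- character()
  }
  if (!length(rate_lines)) stop("no rate table found in ", file)
  traces <- utils::read.csv(text = rate_lines, stringsAsFactors = FALSE)
  if (length(sched_lines) > 1L) {
    sch <- utils::read.csv(text = sched_lines, stringsAsFactors = FALSE)
    schedule <- injection_schedule(sch$name, sch$after_index,
                                   sch$compound_conc)
  } else schedule <- injection_schedule()
  plate_assay(traces, schedule,
              cells_per_well = meta$cells_per_well,
              ambient_o2_percent = meta$ambient_o2_percent,
              glucose_mM = meta$glucose_mM)
}

#' Write a rate table to disk
#'
#' Serializes a [plate_assay()] losslessly to the canonical plain-text
#' dialect read by [read_rate_table()].
#'
#' @param assay a [plate_assay()].
#' @param file path or connection to write to.
#' @return `file`, invisibly.
#' @export
write_rate_table <- function(assay, file) {
  stopifnot(inherits(assay, "plate_assay"))
  con <- textConnection("out", "w", local = TRUE)
  writeLines(c("# granuloflux rate table v1",
               paste0("# cells_per_well: ", assay$cells_per_well),
               paste0("# ambient_o2_percent: ", assay$ambient_o2_percent),
               paste0("# glucose_mM: ", assay$glucose_mM)), con)
  utils::write.csv(assay$traces, con, row.names = FALSE, quote = FALSE)
  writeLines("# schedule", con)
  utils::write.csv(as.data.frame(assay$schedule)[, c("name", "after_index",
                                                     "compound_conc")],
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(out, file)
  invisible(file)
}

#' Segment measurement cycles into injection windows
#'
#' Partitions the 1-based measurement cycles `1..n_cycles` into contiguous
#' windows delimited by the injection schedule: the baseline window runs from
#' cycle 1 through the first event's `after_index`; the window of event *i*
#' runs from `after_index_i + 1` through the next event's `after_index` (the
#' last window extends to the final cycle). Every cycle belongs to exactly
#' one window. These windows are the domains over which the stress-test
#' parameter extrema ("maximal rate measurement after glucose injection
#' through measurement prior to oligomycin injection", etc.) are taken.
#'
#' @param schedule a [injection_schedule()].
#' @param n_cycles total number of measurement cycles.
#' @return data.frame with columns `label` (`"baseline"` then event names),
#'   `start`, `end` (inclusive cycle indices).
#' @examples
#' segment_windows(injection_schedule(c("GLUC", "OLIGO", "2-DG"),
#'                                    c(3, 6, 9)), 12)
#' @export
segment_windows <- function(schedule, n_cycles) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("'n_cycles' must be >= 1")
  if (!nrow(schedule))
    return(data.frame(label = "baseline", start = 1L, end = n_cycles,
                      stringsAsFactors = FALSE))
  ai <- as.integer(schedule$after_index)
  if (any(duplicated(ai)))
    stop("empty window: two events share an 'after_index'")
  if (any(ai >= n_cycles))
    stop("schedule event at or beyond final measurement cycle")
  starts <- c(1L, ai + 1L)
  ends <- c(ai, n_cycles)
  data.frame(label = c("baseline", schedule$name),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

# Internal: cycle indices of the window following event `event` (by name).
.event_window <- function(schedule, n_cycles, event) {
  w <- segment_windows(schedule, n_cycles)
  hit <- which(w$label == event)
  if (!length(hit))
    stop("event '", event, "' not found in schedule")
  seq.int(w$start[hit[1L]], w$end[hit[1L]])
}

#' Aggregate wells of a group into a mean trace
#'
#' Computes, for each measurement cycle and channel, the mean, SEM
#' (sample SD / sqrt(n)) and n over the group's wells, mirroring the
#' "mean +/- SEM" presentation of kinetic traces. An optional robust outlier
#' rule flags wells whose per-well mean rate has a median-absolute-deviation
#' robust z-score above `mad_threshold`; flagged wells are always *reported*
#' (in the `"flagged"` attribute) but excluded from the aggregate only when
#' `outlier_rule = "mad"`. The default applies no exclusion, matching assays
#' reported without well exclusions.
#'
#' @param assay a [plate_assay()].
#' @param group group label to aggregate.
#' @param outlier_rule `"none"` (default) or `"mad"`.
#' @param mad_threshold robust z cutoff (default 3.5).
#' @return data.frame of class `"flux_group_trace"` with columns `group`,
#'   `channel`, `index`, `time_min`, `mean`, `sem`, `n`; SEM is `NA` when
#'   n = 1. Attribute `"flagged"` lists wells flagged by the MAD rule.
#' @export
aggregate_group <- function(assay, group, outlier_rule = c("none", "mad"),
                            mad_threshold = 3.5) {
  stopifnot(inherits(assay, "plate_assay"))
  outlier_rule <- match.arg(outlier_rule)
  tr <- assay$traces[assay$traces$group == group, , drop = FALSE]
  if (!nrow(tr)) stop("unknown group: ", group)
  flagged <- character()
  for (ch in c("ecar", "ocr")) {
    if (all(is.na(tr[[ch]]))) next
    well_means <- tapply(tr[[ch]], tr$well, mean, na.rm = TRUE)
    md <- median(well_means)
    madv <- median(abs(well_means - md))
    if (madv > 0) {
      rz <- 0.6745 * abs(well_means - md) / madv
      flagged <- union(flagged, names(well_means)[rz > mad_threshold])
    }
  }
  use <- tr
  if (outlier_rule == "mad" && length(flagged))
    use <- tr[!tr$well %in% flagged, , drop = FALSE]
  if (!nrow(use)) stop("all wells in group '", group, "' were excluded")
  res <- list()
  for (ch in c("ecar", "ocr")) {
    v <- use[[ch]]
    if (all(is.na(v))) next
    agg <- do.call(rbind, lapply(split(use, use$index), function(d) {
      x <- d[[ch]][!is.na(d[[ch]])]
      n <- length(x)
      data.frame(group = group, channel = ch, index = d$index[1L],
                 time_min = mean(d$time_min), mean = mean(x),
                 sem = if (n > 1L) sd(x) / sqrt(n) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
    res[[ch]] <- agg
  }
  out <- do.call(rbind, res)
  out <- out[order(out$channel, out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  attr(out, "outlier_rule") <- outlier_rule
  class(out) <- c("flux_group_trace", "data.frame")
  out
}

#' @export
plot.flux_group_trace <- function(x, channel = c("ocr", "ecar"), ...) {
  channel <- match.arg(channel)
  d <- x[x$channel == channel, , drop = FALSE]
  if (!nrow(d)) stop("channel '", channel, "' not present")
  ylab <- if (channel == "ocr") "OCR (pmol O2/min)" else "ECAR (mpH/min)"
  graphics::plot(d$time_min, d$mean, type = "b", pch = 16,
                 xlab = "time (min)", ylab = ylab, ...)
  ok <- !is.na(d$sem)
  if (any(ok))
    graphics::arrows(d$time_min[ok], d$mean[ok] - d$sem[ok],
                     d$time_min[ok], d$mean[ok] + d$sem[ok],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Rescale a rate to a reference seeding density
#'
#' Basal and glucose-stimulated acidification scale linearly with the number
#' of cells per well over the usable seeding range, so rates measured at one
#' density are comparable at another by linear normalization:
#' `value * reference / cells_per_well`.
#'
#' @param value rate (any channel/unit).
#' @param cells_per_well cells in the measured well (> 0).
#' @param reference reference cell count (> 0), default 150e3.
#' @return rescaled rate.
#' @export
scale_to_reference_density <- function(value, cells_per_well,
                                       reference = 150e3) {
  if (any(cells_per_well <= 0) || any(reference <= 0))
    stop("cell counts must be positive")
  value * reference / cells_per_well
}
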