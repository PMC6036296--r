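# Shared fixtures: small hand-built traces with known window contents.

# Build a single-well trace data.frame from a vector of channel values.
toy_trace <- function(values, channel = "ecar", well = "A1", group = "g",
                      interval = 6) {
  d <- data.frame(well = well, group = group,
                  index = seq_along(values),
                  time_min = interval * seq_along(values),
                  ecar = NA_real_, ocr = NA_real_,
                  stringsAsFactors = FALSE)
  d[[channel]] <- values
  d
}

# Glycolysis stress-test fixture: baseline [8,9,10], post-GLUC [30,35,33],
# post-OLIGO [40,42,41], post-2DG [12,11].
glyco_fixture <- function() {
  list(trace = toy_trace(c(8, 9, 10, 30, 35, 33, 40, 42, 41, 12, 11)),
       schedule = injection_schedule(c("GLUC", "OLIGO", "2-DG"),
                                     c(3, 6, 9)))
}

# Mito stress-test fixture: baseline [48,49,50], post-OLIGO [22,20,21],
# post-FCCP [88,90,85], post-ROT/AA [6,5].
mito_fixture <- function() {
  list(trace = toy_trace(c(48, 49, 50, 22, 20, 21, 88, 90, 85, 6, 5),
                         channel = "ocr"),
       schedule = injection_schedule(c("OLIGO", "FCCP", "ROT/AA"),
                                     c(3, 6, 9)))
}

# Random multi-well assay for property-style tests.
random_assay <- function(n_wells = 4, n_cycles = 12, seed = 1,
                         events = c("GLUC", "OLIGO", "2-DG"),
                         after = c(3, 6, 9)) {
  set.seed(seed)
  rows <- lapply(seq_len(n_wells), function(w)
    data.frame(well = sprintf("W%02d", w),
               group = if (w <= n_wells / 2) "g1" else "g2",
               index = seq_len(n_cycles),
               time_min = 6 * seq_len(n_cycles),
               ecar = stats::runif(n_cycles, 5, 80),
               ocr = stats::runif(n_cycles, 5, 400),
               stringsAsFactors = FALSE))
  plate_assay(do.call(rbind, rows), injection_schedule(events, after))
}
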