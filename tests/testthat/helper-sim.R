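# Shared simulation cache: paced single-cell runs are expensive and reused
# across test files (the suite runs in one process), so they are memoised by
# cell type / scalings / protocol.

.sim_cache <- new.env(parent = emptyenv())

sim_key <- function(cell_type, scalings, cl, n_beats) {
  paste(cell_type, paste(signif(as.numeric(scalings), 12), collapse = ","),
        cl, n_beats, sep = "|")
}

# the panel protocol used by the steady-state checks: 100 paced beats at
# CL 1000 ms, dt 0.005 ms, hybrid integration
panel_protocol <- function(cl = 1000, n_beats = 100) {
  pacingProtocol(cl = cl, n_beats = n_beats, steady_tolerance = 0)
}

cached_pace <- function(cell_type, scalings = drugScalings(NULL),
                        cl = 1000, n_beats = 100) {
  key <- sim_key(cell_type, scalings, cl, n_beats)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- paceToSteadyState(
      cell_type, scalings, panel_protocol(cl, n_beats))
  }
  .sim_cache[[key]]
}

final_apd90 <- function(trace) tail(trace$apd90, 1)

bundled_drugs <- loadDrugTable()

# synthetic AP trace helper: piecewise-linear beat in apTrace-compatible form
synthetic_ap_trace <- function(time, vm, beat_start = 0) {
  list(time = time, vm = vm, beat_start = beat_start)
}

# cable-ECG conditions are also shared across acceptance blocks
cached_ecg <- function(scalings = drugScalings(NULL), cl = 1000,
                       window = 700, extra = 0) {
  key <- paste("ecg", sim_key("cable", scalings, cl, 2), window, extra,
               sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- cableEcgRun(
      buildCable(), scalings, cl = cl, n_beats = 2, prepace_beats = 100,
      analysis_window_ms = window, extra_ms = extra,
      prepace_cache = .sim_cache)
  }
  .sim_cache[[key]]
}
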