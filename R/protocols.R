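#' Pacing protocol for single-cell runs
#'
#' @param cl Cycle length (ms), > 0.  Default 1000 ms (60 bpm).
#' @param n_beats Maximum number of paced beats (default 100).
#' @param stim_amplitude Stimulus current (A/F); -80 A/F following the
#'   convention of the cell model's reference protocol.
#' @param stim_duration Stimulus duration (ms), must be < \code{cl}.
#' @param steady_tolerance Early-stop tolerance (ms) on the APD90 change
#'   between successive beats; 0 disables early stopping (the run always paces
#'   \code{n_beats} and the convergence flag reports whether the final
#'   beat-to-beat change was below 0.2 ms).
#' @param dt Integration step (ms), default 0.005.
#' @param method Gate integration, \code{"rl"} (default) or \code{"fe"}.
#' @param save_stride_ms Trace sampling interval (ms), default 0.1.
#' @return Object of class \code{pacingProtocol}.
#' @export
pacingProtocol <- function(cl = 1000, n_beats = 100, stim_amplitude = -80,
                           stim_duration = 0.5, steady_tolerance = 0,
                           dt = 0.005, method = c("rl", "fe"),
                           save_stride_ms = 0.1) {
  method <- match.arg(method)
  if (cl <= 0 || n_beats < 1 || dt <= 0) stop("invalid pacing protocol")
  if (stim_duration >= cl) stop("stim_duration must be smaller than cl")
  if (save_stride_ms < dt) save_stride_ms <- dt
  structure(list(cl = cl, n_beats = as.integer(n_beats),
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 steady_tolerance = steady_tolerance, dt = dt,
                 method = method, save_stride_ms = save_stride_ms),
            class = "pacingProtocol")
}

#' Pace a cell to (near) steady state
#'
#' Paces a single cell under a protocol and returns the recorded action
#' potential trace with per-beat APD90 bookkeeping.  Pacing stops early once
#' the APD90 change between successive beats falls below
#' \code{steady_tolerance} (when that tolerance is positive); a beat whose
#' action potential fails to repolarize to the 90% level before the next
#' stimulus gets an \code{NA} APD90 and sets the failure flag.
#'
#' @param cell_type \code{"endo"}, \code{"M"} or \code{"epi"}.
#' @param scalings Per-channel scalings (see \code{\link{drugScalings}}).
#' @param protocol A \code{\link{pacingProtocol}}.
#' @param init Optional \code{cellState} to start from (defaults to
#'   \code{initState(cell_type)}), e.g. to continue a previous run.
#' @return Object of class \code{apTrace} with fields \code{time} (ms),
#'   \code{vm} (mV), \code{cai} (mM), per-beat \code{apd90}, \code{beat_start},
#'   \code{t_upstroke}, \code{v_peak}, \code{v_rest}, logical
#'   \code{converged}/\code{repolarization_failure}, the final
#'   \code{cellState}, and the protocol.
#' @export
paceToSteadyState <- function(cell_type = c("endo", "M", "epi"),
                              scalings = drugScalings(NULL),
                              protocol = pacingProtocol(),
                              init = NULL) {
  cell_type <- match.arg(cell_type)
  stopifnot(inherits(protocol, "pacingProtocol"))
  y0 <- if (is.null(init)) ord_initial_state(cell_type) else init$state
  stride <- max(1L, as.integer(round(protocol$save_stride_ms / protocol$dt)))
  res <- ord_pace(y0, cell_type, .scal_vec(scalings),
                  protocol$cl, protocol$n_beats, protocol$dt,
                  protocol$stim_amplitude, protocol$stim_duration,
                  stride, protocol$steady_tolerance, 0.9, TRUE,
                  protocol$method)
  apd <- res$apd
  # a run with any non-repolarizing beat is never "converged", whatever the
  # final beat-to-beat difference happens to be
  converged <- if (anyNA(apd)) {
    FALSE
  } else if (protocol$steady_tolerance > 0) {
    res$converged
  } else {
    n <- length(apd)
    n >= 2 && abs(apd[n] - apd[n - 1]) < 0.2
  }
  structure(list(time = res$time, vm = res$vm, cai = res$cai,
                 apd90 = apd, beat_start = res$beat_start,
                 t_upstroke = res$t_upstroke,
                 v_peak = res$v_peak, v_rest = res$v_rest,
                 beats_run = res$beats_run, converged = converged,
                 repolarization_failure = anyNA(apd),
                 gates_in_range = res$gates_in_range,
                 final_state = structure(list(state = res$final_state,
                                              cell_type = cell_type,
                                              t = res$beats_run * protocol$cl),
                                         class = "cellState"),
                 cell_type = cell_type, protocol = protocol),
            class = "apTrace")
}

#' @export
print.apTrace <- function(x, ...) {
  cat("<apTrace> ", x$cell_type, " cell, ", x$beats_run, " beat(s) at CL ",
      x$protocol$cl, " ms\n", sep = "")
  cat("  final APD90: ",
      ifelse(is.na(tail(x$apd90, 1)), "no repolarization",
             paste0(round(tail(x$apd90, 1), 1), " ms")),
      "; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Action potential duration from a voltage trace
#'
#' Duration from the time of maximum upstroke velocity to the first time the
#' membrane potential falls below \code{V_peak - level * (V_peak - V_rest)},
#' with \code{V_rest} taken immediately before the stimulus.  Implemented
#' directly on the sampled trace, independently of the stepper's internal
#' per-beat bookkeeping.
#'
#' @param trace An \code{apTrace} (or a list with \code{time}, \code{vm},
#'   \code{beat_start}).
#' @param level Repolarization fraction in (0, 1); 0.9 gives APD90.
#' @param beat_index Which beat to measure (default: last recorded beat).
#' @return Duration in ms, or \code{NA} when the trace never crosses the
#'   repolarization level before the next stimulus (failure marker).
#' @export
apd <- function(trace, level = 0.9, beat_index = NULL) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  nb <- length(trace$beat_start)
  if (is.null(beat_index)) beat_index <- nb
  if (beat_index < 1 || beat_index > nb) stop("beat_index out of range")
  t0 <- trace$beat_start[beat_index]
  t1 <- if (beat_index < nb) trace$beat_start[beat_index + 1] else
    max(trace$time)
  sel <- trace$time >= t0 & trace$time <= t1
  tt <- trace$time[sel]
  vv <- trace$vm[sel]
  if (length(tt) < 4) stop("beat window contains too few samples")
  v_rest <- vv[1]
  v_peak <- max(vv)
  if (v_peak - v_rest < 20) return(NA_real_) # no action potential elicited
  dv <- diff(vv) / diff(tt)
  i_up <- which.max(dv)
  t_up <- tt[i_up + 1]
  v_level <- v_peak - level * (v_peak - v_rest)
  i_peak <- which.max(vv)
  after <- seq(i_peak, length(vv))
  below <- after[vv[after] < v_level]
  if (!length(below)) return(NA_real_)
  i_c <- below[1]
  # linear interpolation of the crossing time
  t_cross <- if (i_c > 1 && vv[i_c - 1] > v_level) {
    tt[i_c - 1] + (vv[i_c - 1] - v_level) / (vv[i_c - 1] - vv[i_c]) *
      (tt[i_c] - tt[i_c - 1])
  } else tt[i_c]
  t_cross - t_up
}

#' Change in APD90 caused by a drug
#'
#' APD90 under the drug minus APD90 of the drug-free control under an
#' identical protocol.  A repolarization failure in either run propagates as
#' \code{NA} (the failure marker).
#'
#' @param drug A \code{drugRecord}.
#' @param multiplier Cmax multiplier (>= 0).
#' @param cell_type \code{"endo"}, \code{"M"} or \code{"epi"}.
#' @param protocol A \code{\link{pacingProtocol}}.
#' @param control Optional pre-computed control \code{apTrace} for the same
#'   cell type and protocol (saves re-running the control).
#' @return List with \code{delta_apd90} (ms or \code{NA}), \code{apd90_drug},
#'   \code{apd90_control}, and the two traces.
#' @export
deltaApd90 <- function(drug, multiplier, cell_type, protocol = pacingProtocol(),
                       control = NULL) {
  if (is.null(control))
    control <- paceToSteadyState(cell_type, drugScalings(NULL), protocol)
  drugged <- paceToSteadyState(cell_type, drugScalings(drug, multiplier),
                               protocol)
  a_d <- tail(drugged$apd90, 1)
  a_c <- tail(control$apd90, 1)
  list(delta_apd90 = a_d - a_c, apd90_drug = a_d, apd90_control = a_c,
       trace_drug = drugged, trace_control = control)
}

#' Transmural dispersion of repolarization
#'
#' Difference between the largest and smallest APD90 among the endocardial,
#' M and epicardial cells.  Any failure marker (\code{NA}) propagates.
#'
#' @param apd_endo,apd_m,apd_epi APD90 values (ms).
#' @return TDR in ms (non-negative), or \code{NA} if any input is \code{NA}.
#' @export
tdr <- function(apd_endo, apd_m, apd_epi) {
  vals <- c(apd_endo, apd_m, apd_epi)
  if (anyNA(vals)) return(NA_real_)
  max(vals) - min(vals)
}

#' Detect early afterdepolarization or repolarization failure in a beat
#'
#' A beat fails repolarization when its membrane potential never returns
#' below the 90% repolarization level before the next stimulus.  An EAD is a
#' sustained positive dV/dt excursion (> \code{dvdt_threshold} for at least
#' \code{sustain_ms}) during the repolarization phase (after the plateau
#' peak, before the 90% crossing).
#'
#' @param trace An \code{apTrace}.
#' @param beat_index Beat to analyse (default: last).
#' @param dvdt_threshold EAD slope threshold (mV/ms), default +0.02.
#' @param sustain_ms Minimum sustained duration (ms) above the slope
#'   threshold, default 5.
#' @return One of \code{"none"}, \code{"EAD"}, \code{"repolarization_failure"}.
#' @export
detectEadOrFailure <- function(trace, beat_index = NULL,
                               dvdt_threshold = 0.02, sustain_ms = 5) {
  nb <- length(trace$beat_start)
  if (is.null(beat_index)) beat_index <- nb
  t0 <- trace$beat_start[beat_index]
  t1 <- if (beat_index < nb) trace$beat_start[beat_index + 1] else
    max(trace$time)
  sel <- trace$time >= t0 & trace$time <= t1
  tt <- trace$time[sel]
  vv <- trace$vm[sel]
  v_rest <- vv[1]
  v_peak <- max(vv)
  if (v_peak - v_rest < 20) return("none") # no action potential at all
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  i_peak <- which.max(vv)
  after <- seq(i_peak, length(vv))
  below <- after[vv[after] < v90]
  if (!length(below)) return("repolarization_failure")
  i90 <- below[1]
  # repolarization window: past the peak, before the 90% crossing; a
  # depolarizing excursion only counts as an EAD when it takes off from a
  # voltage at least 30% repolarized (the physiological notch-and-dome of
  # epicardial cells rises again near the peak and must not be flagged)
  dts <- diff(tt)
  win <- which(tt > tt[i_peak] + 10 & seq_along(tt) < i90)
  if (length(win) < 3) return("none")
  kk <- pmin(win, length(dts))
  dv <- diff(vv)[kk] / dts[kk]
  pos <- dv > dvdt_threshold
  v30 <- v_peak - 0.3 * (v_peak - v_rest)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  step_ms <- stats::median(dts)
  for (k in which(r$values)) {
    if (r$lengths[k] * step_ms >= sustain_ms &&
        vv[win[starts[k]]] < v30) return("EAD")
  }
  "none"
}
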