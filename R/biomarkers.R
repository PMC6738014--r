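# ECG interval biomarkers: fiducial detection, rate correction, VT flags,
# and the JTpeak-rate relationship.

#' Detect ECG fiducials for one beat
#'
#' Works on a single-lead trace.  QRS onset is the first suprathreshold
#' \code{|dV/dt|} after the pacing time; the J point is the return of the QRS
#' complex into a baseline amplitude band; T peak is the largest absolute
#' excursion after the J point; T end is found by the tangent method
#' (steepest post-peak tangent extrapolated to baseline).
#'
#' @param ecg An \code{ecgTrace}.
#' @param pacing_time Onset (ms) of the analysed beat.
#' @param window_ms Analysis window length after \code{pacing_time} (default:
#'   up to the next pacing time or the end of the trace).
#' @param lead Lead name (default: first lead).
#' @param slope_frac QRS-onset slope threshold as a fraction of the peak
#'   absolute slope (default 0.05).
#' @param baseline_frac J-point amplitude band as a fraction of the peak QRS
#'   amplitude (default 0.15).
#' @return Object of class \code{intervalSet}: QRS onset, J point, T peak,
#'   T end (ms, absolute trace times), plus derived \code{qt}, \code{jtpeak},
#'   \code{tpeak_tend} (ms).  When no T wave is identifiable the fiducials
#'   are \code{NA} (measurement-failure marker).
#' @export
detectIntervals <- function(ecg, pacing_time = 0, window_ms = NULL,
                            lead = NULL, slope_frac = 0.05,
                            baseline_frac = 0.15) {
  if (is.null(lead)) lead <- rownames(ecg$leads)[1]
  tt <- ecg$time
  ss <- ecg$leads[lead, ]
  if (is.null(window_ms)) {
    nxt <- ecg$pacing_times[ecg$pacing_times > pacing_time]
    window_ms <- if (length(nxt)) min(nxt) - pacing_time else
      max(tt) - pacing_time
  }
  sel <- tt >= pacing_time & tt <= pacing_time + window_ms
  tt <- tt[sel]; ss <- ss[sel]
  fail <- structure(list(qrs_onset = NA_real_, j_point = NA_real_,
                         t_peak = NA_real_, t_end = NA_real_,
                         qt = NA_real_, jtpeak = NA_real_,
                         tpeak_tend = NA_real_, lead = lead),
                    class = "intervalSet")
  if (length(tt) < 10) return(fail)
  baseline <- ss[1]
  s0 <- ss - baseline
  amp <- max(abs(s0))
  if (amp < 1e-12) return(fail) # flat trace: measurement failure
  dt <- diff(tt)
  slope <- diff(s0) / dt
  # QRS onset: first time |slope| exceeds slope_frac * max|slope|
  smax <- max(abs(slope))
  i_on <- which(abs(slope) > slope_frac * smax)[1]
  if (is.na(i_on)) return(fail)
  qrs_onset <- tt[i_on]
  # QRS peak: largest |signal| within 80 ms of onset
  qrs_win <- which(tt >= qrs_onset & tt <= qrs_onset + 80)
  i_r <- qrs_win[which.max(abs(s0[qrs_win]))]
  r_amp <- abs(s0[i_r])
  # J point: first return into the baseline band after the QRS peak (slope
  # must also have decayed, so the tail of the R downstroke is not cut)
  after_r <- seq(min(i_r + 1, length(ss)), length(ss))
  in_band <- after_r[abs(s0[after_r]) < baseline_frac * r_amp]
  if (!length(in_band)) return(fail)
  i_j <- in_band[1]
  j_point <- tt[i_j]
  # T wave: extremum of |signal| from 40 ms past J to the window end
  t_win <- which(tt >= j_point + 40)
  if (length(t_win) < 5) return(fail)
  i_tp <- t_win[which.max(abs(s0[t_win]))]
  t_amp <- s0[i_tp]
  if (abs(t_amp) < 0.02 * r_amp || i_tp >= length(ss) - 2) return(fail)
  t_peak <- tt[i_tp]
  # T end, tangent method: steepest tangent on the return limb, extrapolated
  # to the baseline
  ret <- seq(i_tp, length(ss) - 1)
  sl_ret <- slope[pmin(ret, length(slope))]
  i_st <- if (t_amp > 0) ret[which.min(sl_ret)] else ret[which.max(sl_ret)]
  k <- slope[min(i_st, length(slope))]
  if (!is.finite(k) || abs(k) < 1e-12) return(fail)
  t_end <- tt[i_st] + (0 - s0[i_st]) / k
  if (!is.finite(t_end) || t_end <= t_peak || t_end > max(tt) + 50)
    return(fail)
  structure(list(qrs_onset = qrs_onset, j_point = j_point, t_peak = t_peak,
                 t_end = t_end, qt = t_end - qrs_onset,
                 jtpeak = t_peak - j_point, tpeak_tend = t_end - t_peak,
                 lead = lead),
            class = "intervalSet")
}

#' @export
print.intervalSet <- function(x, ...) {
  if (is.na(x$qt)) {
    cat("<intervalSet> measurement failure (no identifiable T wave)\n")
  } else {
    cat(sprintf(paste0("<intervalSet> lead %s: QRS onset %.1f, J %.1f, ",
                       "Tpeak %.1f, Tend %.1f ms\n  QT %.1f ms, JTpeak %.1f ",
                       "ms, Tpeak-Tend %.1f ms\n"),
                x$lead, x$qrs_onset, x$j_point, x$t_peak, x$t_end,
                x$qt, x$jtpeak, x$tpeak_tend))
  }
  invisible(x)
}

#' Heart-rate correction of an ECG interval
#'
#' @param interval Interval (ms).
#' @param rr RR interval (ms), > 0.
#' @param method \code{"fridericia"} (default, interval / (RR/1000)^(1/3)),
#'   \code{"bazett"} (exponent 1/2) or \code{"none"}.
#' @return Corrected interval (ms).
#' @export
rateCorrect <- function(interval, rr, method = c("fridericia", "bazett",
                                                 "none")) {
  method <- match.arg(method)
  if (any(rr <= 0)) stop("RR must be positive")
  switch(method,
         fridericia = interval / (rr / 1000)^(1 / 3),
         bazett = interval / (rr / 1000)^(1 / 2),
         none = interval)
}

#' Detect ventricular-tachycardia-like activity on an ECG
#'
#' VT is flagged when deflections persist beyond the control QT plus a guard
#' interval with amplitude above a baseline-noise band (cumulative 40 ms), or
#' when the underlying tissue recording shows continued activations after
#' pacing stops (see \code{\link{detectSustainedActivity}}).  On
#' electrotonically coupled synthetic tissue a drug-induced repolarization
#' failure presents as such a persisting late deflection rather than a
#' polymorphic oscillation.
#'
#' @param ecg An \code{ecgTrace}.
#' @param control_qt Drug-free QT (ms) under the same protocol.
#' @param guard_ms Guard after the control QT (default 200 ms).
#' @param noise_frac Amplitude threshold as a fraction of the trace's peak
#'   absolute amplitude (default 0.1).
#' @param lead Lead to analyse (default: first).
#' @param recording Optional underlying \code{tissueRecording} for the
#'   sustained-activation criterion.
#' @return Logical VT flag.
#' @export
detectVt <- function(ecg, control_qt, guard_ms = 200, noise_frac = 0.1,
                     lead = NULL, recording = NULL) {
  if (is.null(lead)) lead <- rownames(ecg$leads)[1]
  last_pace <- if (length(ecg$pacing_times)) max(ecg$pacing_times) else 0
  quiet_from <- last_pace + control_qt + guard_ms
  tt <- ecg$time
  ss <- ecg$leads[lead, ] - ecg$leads[lead, 1]
  if (max(tt) <= quiet_from)
    stop("analysis window must extend beyond control QT + guard")
  amp <- max(abs(ss))
  late <- tt > quiet_from
  osc <- FALSE
  if (any(late)) {
    # deflections persisting beyond the guarded window: cumulative
    # above-band time of at least 40 ms (a repolarization that ended in
    # time leaves the late window flat)
    above <- abs(ss[late]) > noise_frac * amp
    step <- stats::median(diff(tt))
    osc <- sum(above) * step >= 40
  }
  sustained <- if (!is.null(recording))
    detectSustainedActivity(recording, quiet_from) else FALSE
  osc || sustained
}

#' JTpeak across pacing rates
#'
#' Runs the single-cable tissue + forward-ECG pipeline at each heart rate and
#' extracts JTpeak of the final paced beat.
#'
#' @param heart_rates_bpm Heart rates (beats/min), >= 2 values for a
#'   monotonicity readout.
#' @param scalings Channel scalings (default: drug-free).
#' @param model Tissue model (default cable; smaller cables speed this up).
#' @param n_beats Beats simulated per rate (default 2; the last is analysed).
#' @param prepace_beats Single-cell pre-pacing beats used to initialize the
#'   tissue at each rate (default 50).
#' @param ... Passed to \code{\link{runTissueSimulation}}.
#' @return data.frame with columns \code{rate_bpm}, \code{cl_ms},
#'   \code{jtpeak_ms}, \code{qt_ms} (NA on measurement failure).
#' @export
jtpeakRateCurve <- function(heart_rates_bpm = c(60, 80, 100),
                            scalings = drugScalings(NULL),
                            model = buildCable(), n_beats = 2,
                            prepace_beats = 50, ...) {
  out <- data.frame(rate_bpm = heart_rates_bpm,
                    cl_ms = 60000 / heart_rates_bpm,
                    jtpeak_ms = NA_real_, qt_ms = NA_real_)
  for (r in seq_len(nrow(out))) {
    cl <- out$cl_ms[r]
    res <- cableEcgRun(model, scalings, cl = cl, n_beats = n_beats,
                       prepace_beats = prepace_beats, ...)
    iv <- res$intervals
    out$jtpeak_ms[r] <- iv$jtpeak
    out$qt_ms[r] <- iv$qt
  }
  out
}

#' Paced cable run with forward ECG and interval extraction
#'
#' Convenience pipeline used by the screening driver: pre-paces each cell
#' type in isolation at the requested cycle length, initializes every cable
#' node with its type's pre-paced state, runs \code{n_beats} paced beats of
#' tissue simulation with endocardial-end stimulation, computes the forward
#' ECG, and measures the intervals of the last beat.
#'
#' @param model A cable-like \code{tissueModel}.
#' @param scalings Channel scalings.
#' @param cl Cycle length (ms).
#' @param n_beats Tissue beats (default 2; last analysed).
#' @param prepace_beats Single-cell pre-pacing beats (default 50).
#' @param analysis_window_ms Recorded window after the final beat's pacing
#'   time (default: the full cycle length); shorter windows save simulation
#'   time when only the intervals are needed.
#' @param extra_ms Extra quiescent recording time after the last beat
#'   (default 0; used by VT analysis).
#' @param schedule Stimulation schedule (default: the first two endocardial
#'   nodes, PMJ rule).
#' @param dt,save_stride_ms,method Tissue integration settings.
#' @param prepace_cache Optional environment used to memoise single-cell
#'   pre-pacing runs across calls (keyed by type/scalings/cl).
#' @return List: \code{recording}, \code{ecg}, \code{intervals} (of the last
#'   beat), \code{pacing_times}, \code{prepaced} per-type traces.
#' @export
cableEcgRun <- function(model, scalings = drugScalings(NULL), cl = 1000,
                        n_beats = 2, prepace_beats = 50,
                        analysis_window_ms = NULL, extra_ms = 0,
                        schedule = NULL, dt = 0.01, save_stride_ms = 1,
                        method = "rl", prepace_cache = NULL) {
  if (is.null(analysis_window_ms)) analysis_window_ms <- cl
  types <- unique(model$cell_type)
  prot <- pacingProtocol(cl = cl, n_beats = prepace_beats,
                         steady_tolerance = 0)
  prepaced <- list()
  for (ty in types) {
    key <- paste(ty, paste(signif(as.numeric(scalings), 12), collapse = ","),
                 cl, prepace_beats, sep = "|")
    if (!is.null(prepace_cache) && !is.null(prepace_cache[[key]])) {
      prepaced[[ty]] <- prepace_cache[[key]]
    } else {
      prepaced[[ty]] <- paceToSteadyState(ty, scalings, prot)
      if (!is.null(prepace_cache)) prepace_cache[[key]] <- prepaced[[ty]]
    }
  }
  init <- vapply(model$cell_type, function(ty)
    prepaced[[ty]]$final_state$state, numeric(41))
  pacing_times <- (seq_len(n_beats) - 1) * cl
  if (is.null(schedule)) schedule <- directSchedule(nodes = c(1L, 2L))
  duration <- (n_beats - 1) * cl + analysis_window_ms + extra_ms
  rec <- runTissueSimulation(model, schedule, duration = duration,
                             pacing_times = pacing_times,
                             scalings = scalings, init_states = init,
                             dt = dt, save_stride_ms = save_stride_ms,
                             method = method)
  ecg <- forwardEcg(rec)
  iv <- detectIntervals(ecg, pacing_time = pacing_times[n_beats],
                        window_ms = analysis_window_ms + extra_ms)
  list(recording = rec, ecg = ecg, intervals = iv,
       pacing_times = pacing_times, prepaced = prepaced)
}
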