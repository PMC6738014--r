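#' Purkinje network as a unidirectional activation-time scheduler
#'
#' The conduction system is represented as a tree of segments with per-segment
#' conduction speeds; it transmits the pacing stimulus unidirectionally from
#' the His-bundle root to the Purkinje-muscle junctions (PMJs) at its leaves.
#' No retrograde myocardium-to-Purkinje coupling exists by construction.
#'
#' @param segments data.frame with columns \code{id}, \code{parent}
#'   (\code{NA} for the root segment), \code{length_cm} (>= 0) and
#'   \code{speed_cm_per_ms} (> 0).
#' @param pmj data.frame with columns \code{segment} (leaf segment id) and
#'   \code{node} (mesh node index stimulated by that PMJ).
#' @return Object of class \code{purkinjeNetwork}.
#' @export
purkinjeNetwork <- function(segments, pmj) {
  segments <- as.data.frame(segments)
  pmj <- as.data.frame(pmj)
  req <- c("id", "parent", "length_cm", "speed_cm_per_ms")
  if (!all(req %in% names(segments)))
    stop("segments needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(segments$id)) stop("duplicate segment ids")
  if (any(segments$length_cm < 0)) stop("segment lengths must be >= 0")
  if (any(segments$speed_cm_per_ms <= 0)) stop("conduction speeds must be > 0")
  known <- c(NA, segments$id)
  if (!all(segments$parent %in% known))
    stop("parent references unknown segment id(s)")
  if (sum(is.na(segments$parent)) != 1L)
    stop("exactly one root segment (parent = NA) is required")
  # acyclicity: walking up from every segment must terminate at the root
  idx <- match(segments$parent, segments$id)
  for (s in seq_len(nrow(segments))) {
    seen <- integer(0)
    cur <- s
    while (!is.na(idx[cur])) {
      if (cur %in% seen) stop("cycle detected in Purkinje network")
      seen <- c(seen, cur)
      cur <- idx[cur]
    }
  }
  if (!all(c("segment", "node") %in% names(pmj)))
    stop("pmj needs columns 'segment' and 'node'")
  if (!all(pmj$segment %in% segments$id))
    stop("pmj references unknown segment id(s)")
  structure(list(segments = segments, pmj = pmj),
            class = "purkinjeNetwork")
}

#' @export
print.purkinjeNetwork <- function(x, ...) {
  cat("<purkinjeNetwork> ", nrow(x$segments), " segment(s), ",
      nrow(x$pmj), " PMJ(s)\n", sep = "")
  invisible(x)
}

# conduction delay from root to (the distal end of) a segment
.segment_delay <- function(network, id) {
  seg <- network$segments
  idx <- match(id, seg$id)
  delay <- 0
  while (!is.na(idx)) {
    delay <- delay + seg$length_cm[idx] / seg$speed_cm_per_ms[idx]
    idx <- match(seg$parent[idx], seg$id)
  }
  delay
}

#' Activation schedule from a Purkinje network
#'
#' Each PMJ fires at \code{pacing_time} plus the sum of segment length /
#' segment speed along the unique root-to-leaf path.
#'
#' @param network A \code{\link{purkinjeNetwork}}.
#' @param pacing_time His-bundle pacing time (ms), default 0.
#' @param stim_amplitude Stimulus current (A/F), default -80 (depolarizing,
#'   negative).
#' @param cutoff_mV Stimulation stops once the node's membrane potential
#'   exceeds this voltage; default -10 mV.
#' @return Object of class \code{activationSchedule}: data.frame with columns
#'   \code{node}, \code{delay_ms} (from pacing time), \code{t_start}
#'   (absolute, ms), \code{amplitude}, \code{cutoff_mV}.
#' @export
scheduleFromNetwork <- function(network, pacing_time = 0,
                                stim_amplitude = -80, cutoff_mV = -10) {
  stopifnot(inherits(network, "purkinjeNetwork"))
  if (stim_amplitude >= 0) stop("stimulus amplitude must be negative (depolarizing)")
  delays <- vapply(network$pmj$segment, function(id)
    .segment_delay(network, id), numeric(1))
  out <- data.frame(node = network$pmj$node, delay_ms = delays,
                    t_start = pacing_time + delays,
                    amplitude = stim_amplitude, cutoff_mV = cutoff_mV)
  class(out) <- c("activationSchedule", "data.frame")
  out
}

#' Single-node activation schedule
#'
#' Convenience schedule stimulating the given mesh nodes directly (e.g. one
#' cable end), with zero Purkinje delay.
#'
#' @param nodes Mesh node indices to stimulate.
#' @param delay_ms Delay after each pacing time (ms), recycled.
#' @param stim_amplitude,cutoff_mV As in \code{\link{scheduleFromNetwork}}.
#' @return An \code{activationSchedule}.
#' @export
directSchedule <- function(nodes, delay_ms = 0, stim_amplitude = -80,
                           cutoff_mV = -10) {
  n <- length(nodes)
  out <- data.frame(node = nodes, delay_ms = rep_len(delay_ms, n),
                    t_start = rep_len(delay_ms, n),
                    amplitude = rep_len(stim_amplitude, n),
                    cutoff_mV = rep_len(cutoff_mV, n))
  class(out) <- c("activationSchedule", "data.frame")
  out
}

#' PMJ stimulation rule (reference implementation)
#'
#' Pure-R implementation of the stimulation rule used inside the tissue
#' stepper, exposed for verification: a scheduled node receives the stimulus
#' amplitude from its start time until its membrane potential first exceeds
#' the cutoff, after which it is latched off for the rest of the beat.
#'
#' @param vm Per-node membrane potentials (mV) at time \code{t}.
#' @param schedule An \code{\link{activationSchedule}}.
#' @param t Current time (ms).
#' @param latched Logical per-schedule-row latch state from the previous call
#'   (default: all unlatched).
#' @return List with \code{stim} (per-node current, A/F) and the updated
#'   \code{latched} vector.
#' @export
pmjStimulate <- function(vm, schedule, t, latched = NULL) {
  sched <- as.data.frame(schedule)
  if (is.null(latched)) latched <- rep(FALSE, nrow(sched))
  stim <- numeric(length(vm))
  for (r in seq_len(nrow(sched))) {
    if (t < sched$t_start[r] || latched[r]) next
    node <- sched$node[r]
    if (vm[node] > sched$cutoff_mV[r]) {
      latched[r] <- TRUE
    } else {
      stim[node] <- stim[node] + sched$amplitude[r]
    }
  }
  list(stim = stim, latched = latched)
}

#' Parametric binary-tree Purkinje network over endocardial nodes
#'
#' Synthetic stand-in for a digitized Purkinje geometry: a balanced binary
#' tree of given depth whose leaves are mapped (in order) onto the supplied
#' endocardial mesh nodes, producing a spread of PMJ activation times.
#'
#' @param leaf_nodes Mesh node indices to attach PMJs to (one per leaf; the
#'   tree depth is \code{ceiling(log2(length(leaf_nodes)))}).
#' @param branch_length_cm Segment length (cm), default 1.
#' @param speed_cm_per_ms Conduction speed (cm/ms), default 0.2 (placeholder;
#'   regional speeds are configurable per segment).
#' @param jitter_fraction Deterministic per-leaf path-length modulation in
#'   [0, 1) spreading PMJ times (default 0.25); leaf k gets an extra terminal
#'   length of \code{branch_length_cm * jitter_fraction * k / n_leaves}.
#' @return A \code{\link{purkinjeNetwork}}.
#' @export
binaryTreePurkinje <- function(leaf_nodes, branch_length_cm = 1,
                               speed_cm_per_ms = 0.2,
                               jitter_fraction = 0.25) {
  n_leaves <- length(leaf_nodes)
  if (n_leaves < 1) stop("at least one leaf node required")
  depth <- max(1, ceiling(log2(n_leaves)))
  segs <- data.frame(id = 1L, parent = NA_integer_,
                     length_cm = branch_length_cm,
                     speed_cm_per_ms = speed_cm_per_ms)
  level_ids <- 1L
  next_id <- 2L
  for (d in seq_len(depth)) {
    new_ids <- integer(0)
    for (p in level_ids) {
      for (k in 1:2) {
        segs <- rbind(segs, data.frame(id = next_id, parent = p,
                                       length_cm = branch_length_cm,
                                       speed_cm_per_ms = speed_cm_per_ms))
        new_ids <- c(new_ids, next_id)
        next_id <- next_id + 1L
      }
    }
    level_ids <- new_ids
  }
  leaves <- head(level_ids, n_leaves)
  # deterministic terminal-length modulation so PMJs fire in a spread
  extra <- branch_length_cm * jitter_fraction * seq_len(n_leaves) / n_leaves
  for (k in seq_len(n_leaves)) {
    segs$length_cm[segs$id == leaves[k]] <-
      segs$length_cm[segs$id == leaves[k]] + extra[k]
  }
  purkinjeNetwork(segs, data.frame(segment = leaves, node = leaf_nodes))
}

#' Serialize / load a Purkinje network as JSON
#' @param network A \code{purkinjeNetwork}.
#' @param path Output (input) path.
#' @return \code{path} invisibly (\code{writePurkinje}); a
#'   \code{purkinjeNetwork} (\code{readPurkinje}).
#' @export
writePurkinje <- function(network, path) {
  jsonlite::write_json(list(segments = network$segments, pmj = network$pmj),
                       path, dataframe = "columns", digits = NA, na = "null")
  invisible(path)
}

#' @rdname writePurkinje
#' @export
readPurkinje <- function(path) {
  obj <- jsonlite::fromJSON(path)
  purkinjeNetwork(as.data.frame(obj$segments), as.data.frame(obj$pmj))
}
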