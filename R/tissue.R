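#' Tissue model: discretized geometry with per-node cell types
#'
#' @param nodes Numeric matrix (n x dim) of node coordinates in cm
#'   (dim = 1, 2 or 3).
#' @param elements Integer matrix (m x (k+1)) of simplex connectivity
#'   (segments, triangles or tetrahedra; 1-based node indices).
#' @param cell_type Character vector, one of \code{"endo"}, \code{"M"},
#'   \code{"epi"} per node.
#' @param D Diffusion coefficient, isotropic scalar, one value or one per
#'   element.  Units are set by \code{d_time_unit}: the bundled default is the
#'   printed literature value 0.00154 with \code{d_time_unit = "ms"}
#'   (i.e. cm^2/ms).  NOTE: the source table prints "cm^2/s"; taken literally
#'   (\code{d_time_unit = "s"}) that value yields unphysiologically slow
#'   conduction (~0.5 mm/s), so the package defaults to the per-millisecond
#'   reading and exposes the switch rather than silently rescaling.
#' @param d_time_unit \code{"ms"} (default) or \code{"s"}; with \code{"s"}
#'   the coefficient is divided by 1000 to express it in cm^2/ms internally.
#' @param Cm Membrane capacitance (uF/cm^2), default 2.0.  Metadata: the
#'   reaction currents are per capacitance (A/F), so Cm does not enter the
#'   update; it is kept for conductivity-based workflows.
#' @return Object of class \code{tissueModel}.
#' @export
tissueModel <- function(nodes, elements, cell_type, D = 0.00154,
                        d_time_unit = c("ms", "s"), Cm = 2.0) {
  d_time_unit <- match.arg(d_time_unit)
  nodes <- as.matrix(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  n <- nrow(nodes)
  if (!all(cell_type %in% c("endo", "M", "epi")))
    stop("every node must be typed 'endo', 'M' or 'epi'")
  if (length(cell_type) != n) stop("one cell_type per node required")
  if (min(elements) < 1 || max(elements) > n)
    stop("element connectivity references nodes out of range")
  D_ms <- if (d_time_unit == "s") D / 1000 else D
  if (any(D_ms <= 0)) stop("diffusion coefficient must be positive")
  if (!length(D_ms) %in% c(1L, nrow(elements)))
    stop("D must be scalar or one value per element")
  model <- structure(list(nodes = nodes, elements = elements,
                          cell_type = cell_type,
                          D = rep_len(D_ms, nrow(elements)),
                          d_printed = D, d_time_unit = d_time_unit,
                          Cm = Cm),
                     class = "tissueModel")
  if (!.mesh_connected(model)) stop("mesh is not connected")
  model
}

.mesh_connected <- function(model) {
  n <- nrow(model$nodes)
  el <- model$elements
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    idx <- el[r, ]
    for (i in idx) adj[[i]] <- c(adj[[i]], idx)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, unique(new))
  }
  all(seen)
}

#' @export
print.tissueModel <- function(x, ...) {
  dim <- ncol(x$nodes)
  cat("<tissueModel> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " elements (", c("1D cable", "2D sheet", "3D volume")[dim], ")\n",
      sep = "")
  cat("  cell types:", paste(names(table(x$cell_type)),
                             table(x$cell_type), collapse = ", "), "\n")
  cat("  D = ", x$d_printed, " cm^2/", x$d_time_unit,
      " (internal: ", signif(x$D[1], 4), " cm^2/ms), Cm = ", x$Cm,
      " uF/cm^2\n", sep = "")
  invisible(x)
}

#' Build a 1D transmural cable
#'
#' Endocardial nodes at the low-index end, epicardial at the high-index end,
#' M cells in between, with layer thicknesses given as fractions of the
#' cable.
#'
#' @param n_nodes Number of nodes (>= 3), default 165 (a ~1.65 cm wall at the
#'   default spacing).
#' @param dx Node spacing (cm), default 0.01.
#' @param layer_fractions Named fractions \code{c(endo=, M=, epi=)} summing to
#'   1 (tolerance 1e-9), default equal thirds.
#' @param ... Passed to \code{\link{tissueModel}} (e.g. \code{D}).
#' @return A \code{tissueModel}.
#' @export
buildCable <- function(n_nodes = 165, dx = 0.01,
                       layer_fractions = c(endo = 1/3, M = 1/3, epi = 1/3),
                       ...) {
  if (n_nodes < 3) stop("n_nodes must be >= 3")
  if (abs(sum(layer_fractions) - 1) > 1e-9)
    stop("layer fractions must sum to 1")
  counts <- round(n_nodes * cumsum(layer_fractions[c("endo", "M", "epi")]))
  types <- character(n_nodes)
  types[seq_len(counts[1])] <- "endo"
  if (counts[2] > counts[1]) types[(counts[1] + 1):counts[2]] <- "M"
  if (counts[3] > counts[2]) types[(counts[2] + 1):counts[3]] <- "epi"
  nodes <- matrix((seq_len(n_nodes) - 1) * dx, ncol = 1)
  elements <- cbind(seq_len(n_nodes - 1), seq_len(n_nodes - 1) + 1L)
  tissueModel(nodes, elements, types, ...)
}

# P1 simplex geometry: volume (length/area/volume) and barycentric gradients
.simplex_geom <- function(X) {
  d <- ncol(X)
  k <- nrow(X) - 1L
  E <- t(X[-1, , drop = FALSE]) - X[1, ] # d x k edge matrix
  if (k == d) {
    vol <- abs(det(E)) / factorial(k)
  } else {
    vol <- sqrt(abs(det(crossprod(E)))) / factorial(k)
  }
  if (vol <= 0) stop("degenerate element (zero measure)")
  # gradients of barycentric coordinates: rows of G (k+1 x d)
  Einv <- solve(crossprod(E), t(E)) # k x d pseudo-inverse for affine coords
  G <- rbind(-colSums(Einv), Einv)
  list(vol = vol, G = G)
}

#' Assemble the zero-flux diffusion operator
#'
#' Linear finite elements with mass lumping on the simplicial mesh; the
#' resulting sparse operator maps nodal Vm to an approximation of
#' div(D grad Vm) with natural (zero-flux) boundaries.  On a uniform 1D grid
#' the interior rows reduce exactly to the second-difference stencil
#' \code{D/dx^2 * (1, -2, 1)}.
#'
#' @param model A \code{\link{tissueModel}}.
#' @return Sparse \code{dgCMatrix} (n x n) of class attribute
#'   \code{diffusionOperator}; row sums are zero (a uniform field diffuses to
#'   zero).
#' @export
assembleDiffusion <- function(model) {
  stopifnot(inherits(model, "tissueModel"))
  el <- model$elements
  nn <- nrow(model$nodes)
  nv <- ncol(el)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  lump <- numeric(nn)
  for (e in seq_len(nrow(el))) {
    idx <- el[e, ]
    g <- .simplex_geom(model$nodes[idx, , drop = FALSE])
    Ke <- model$D[e] * g$vol * tcrossprod(g$G) # (k+1)x(k+1) stiffness
    ii <- c(ii, rep(idx, each = nv))
    jj <- c(jj, rep(idx, times = nv))
    xx <- c(xx, as.vector(t(Ke)))
    lump[idx] <- lump[idx] + g$vol / nv
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  L <- -Matrix::Diagonal(x = 1 / lump) %*% K
  L <- methods::as(L, "CsparseMatrix")
  attr(L, "lumped_mass") <- lump
  L
}

#' Explicit stability bound for the diffusion update
#'
#' Conservative forward-Euler bound \code{dt <= 1 / max|diag(L)|} from the
#' Gershgorin estimate of the operator spectrum.
#'
#' @param operator Operator from \code{\link{assembleDiffusion}}.
#' @return Maximum stable dt (ms).
#' @export
dtMaxExplicit <- function(operator) {
  1 / max(abs(Matrix::diag(operator)))
}

#' One explicit monodomain step (reference implementation)
#'
#' Advances every node by one step: reaction via the single-cell model,
#' diffusion via the supplied operator.  This R-level stepper exists for
#' small meshes and verification; long runs use
#' \code{\link{runTissueSimulation}}.
#'
#' @param states Numeric matrix (41 x n) of per-node state vectors.
#' @param cell_type Character vector of per-node cell types.
#' @param operator Diffusion operator from \code{\link{assembleDiffusion}}.
#' @param dt Time step (ms); must satisfy the explicit stability bound.
#' @param scalings Channel scalings (default: none).
#' @param stim Per-node stimulus vector (A/F), default all zero.
#' @param method Gate integration method.
#' @return Updated state matrix.
#' @export
stepTissue <- function(states, cell_type, operator, dt,
                       scalings = drugScalings(NULL), stim = NULL,
                       method = "rl") {
  n <- ncol(states)
  if (is.null(stim)) stim <- numeric(n)
  if (dt > dtMaxExplicit(operator))
    stop(sprintf("dt = %g exceeds the explicit stability bound %.4g ms",
                 dt, dtMaxExplicit(operator)))
  vm_old <- states[1, ]
  diff_term <- as.numeric(operator %*% vm_old)
  out <- states
  for (j in seq_len(n)) {
    out[, j] <- ord_step(states[, j], cell_type[j], .scal_vec(scalings),
                         stim[j], dt, method)
  }
  out[1, ] <- out[1, ] + dt * diff_term
  out
}

#' Run a monodomain tissue simulation
#'
#' Integrates the monodomain reaction-diffusion system with the compiled
#' stepper.  Stimulation follows the Purkinje-muscle-junction rule by
#' default: a scheduled node receives \code{stim_amplitude} from its start
#' time until its membrane potential first exceeds \code{cutoff_mV}, then is
#' latched off for that beat (\code{latch = FALSE} switches to a plain
#' fixed-duration stimulus).
#'
#' @param model A \code{\link{tissueModel}}.
#' @param schedule An \code{\link{activationSchedule}} (or a data.frame with
#'   columns \code{node}, \code{delay_ms}).
#' @param duration Total simulated time (ms).
#' @param pacing_times Numeric vector of pacing onset times (ms), default 0.
#' @param scalings Channel scalings applied to all nodes.
#' @param init_states Optional 41 x n state matrix (default: per-type resting
#'   initial conditions).
#' @param dt Time step (ms), default 0.01; checked against the explicit
#'   stability bound.
#' @param save_stride_ms Vm sampling interval (ms), default 1.
#' @param stim_amplitude,cutoff_mV PMJ rule parameters, defaults -80 A/F and
#'   -10 mV.
#' @param stim_duration Fixed stimulus length (ms) when \code{latch = FALSE}.
#' @param latch Use the voltage-cutoff latch rule (default TRUE).
#' @param activation_threshold Vm crossing (mV) defining the per-node
#'   activation time, default -40.
#' @param method Gate integration method.
#' @param operator Optional pre-assembled diffusion operator.
#' @return Object of class \code{tissueRecording}: \code{time} (ms),
#'   \code{vm} (n x T matrix, mV), \code{activation_time} (ms per node,
#'   \code{NA} if never activated), \code{final_states}, plus protocol
#'   metadata.
#' @export
runTissueSimulation <- function(model, schedule, duration,
                                pacing_times = 0,
                                scalings = drugScalings(NULL),
                                init_states = NULL, dt = 0.01,
                                save_stride_ms = 1,
                                stim_amplitude = -80, cutoff_mV = -10,
                                stim_duration = 0.5, latch = TRUE,
                                activation_threshold = -40,
                                method = "rl", operator = NULL) {
  stopifnot(inherits(model, "tissueModel"))
  if (is.null(operator)) operator <- assembleDiffusion(model)
  n <- nrow(model$nodes)
  dt_max <- dtMaxExplicit(operator)
  if (dt > dt_max)
    stop(sprintf(paste0("dt = %g ms violates the explicit stability bound ",
                        "%.4g ms for this mesh; reduce dt"), dt, dt_max))
  if (is.null(init_states)) {
    init_states <- vapply(model$cell_type, ord_initial_state,
                          numeric(41))
  }
  if (!all(dim(init_states) == c(41L, n)))
    stop("init_states must be a 41 x n_nodes matrix")
  sched <- as.data.frame(schedule)
  if (!all(c("node", "delay_ms") %in% names(sched)))
    stop("schedule needs columns 'node' and 'delay_ms'")
  if (any(sched$node < 1 | sched$node > n))
    stop("schedule references nodes outside the mesh")
  delay <- rep(NA_real_, n)
  delay[sched$node] <- sched$delay_ms
  ctypes <- match(model$cell_type, c("endo", "epi", "M")) - 1L
  stride <- max(1L, as.integer(round(save_stride_ms / dt)))
  res <- ord_tissue_run(init_states, ctypes, .scal_vec(scalings),
                        operator@i, operator@p, operator@x,
                        dt, duration, pacing_times, delay,
                        stim_amplitude, cutoff_mV, stim_duration,
                        latch, stride, activation_threshold, method)
  structure(list(time = res$time, vm = res$vm,
                 activation_time = res$activation_time,
                 final_states = res$final_states,
                 model = model, pacing_times = pacing_times,
                 dt = dt, save_stride_ms = save_stride_ms,
                 scalings = scalings),
            class = "tissueRecording")
}

#' @export
print.tissueRecording <- function(x, ...) {
  cat("<tissueRecording> ", nrow(x$vm), " nodes x ", length(x$time),
      " samples (", max(x$time), " ms)\n", sep = "")
  at <- x$activation_time
  cat("  activated nodes: ", sum(is.finite(at)), "/", length(at), sep = "")
  if (any(is.finite(at)))
    cat(", activation spread ", round(min(at, na.rm = TRUE), 2), " - ",
        round(max(at, na.rm = TRUE), 2), " ms", sep = "")
  cat("\n")
  invisible(x)
}

#' Detect sustained activity after pacing stops
#'
#' Flags re-entry-like behaviour: any node whose membrane potential rises
#' through the activation threshold after the last stimulus-driven activation
#' window has passed.
#'
#' @param recording A \code{tissueRecording}.
#' @param quiescent_after Time (ms) after which no new suprathreshold
#'   depolarization is expected (e.g. last pacing time + control QT + guard).
#' @param threshold Vm threshold (mV), default -40.
#' @return Logical: TRUE when sustained/ectopic activity is present.
#' @export
detectSustainedActivity <- function(recording, quiescent_after,
                                    threshold = -40) {
  tt <- recording$time
  idx <- which(tt > quiescent_after)
  idx <- idx[idx > 1L]
  if (!length(idx)) return(FALSE)
  vmw <- recording$vm[, idx, drop = FALSE]
  vmw_prev <- recording$vm[, idx - 1L, drop = FALSE]
  any(vmw >= threshold & vmw_prev < threshold)
}
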