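#' @useDynLib cardioscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Names of the gating variables (dimensionless, bounded in [0, 1])
#' @return Character vector of gate names in state-vector order.
#' @export
gateNames <- function() {
  c("m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1")
}

#' Names of the intracellular/subspace concentration variables (mM)
#' @return Character vector of concentration names.
#' @export
concentrationNames <- function() {
  c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")
}

#' Cell-model parameter set
#'
#' @param cell_type One of \code{"endo"}, \code{"M"}, \code{"epi"} — the
#'   transmural variant of the ventricular myocyte model.
#' @param channel_scalings Per-channel conductance/permeability scalings in
#'   \code{[0, 1]} (see \code{\link{drugScalings}}); default: no block.
#' @param membrane_capacitance Tissue membrane capacitance (uF/cm^2), used by
#'   the monodomain coupling only — single-cell currents are per capacitance
#'   (A/F) and independent of it.
#' @return Object of class \code{cellParams}.
#' @export
cellParams <- function(cell_type = c("endo", "M", "epi"),
                       channel_scalings = drugScalings(NULL),
                       membrane_capacitance = 2.0) {
  cell_type <- match.arg(cell_type)
  sc <- as.numeric(channel_scalings)
  if (length(sc) != 4L || anyNA(sc) || any(sc < 0 | sc > 1))
    stop("channel_scalings must be 4 values in [0, 1] (INa, INaL, ICaL, IKr)")
  names(sc) <- channelNames()
  structure(list(cell_type = cell_type, channel_scalings = sc,
                 membrane_capacitance = membrane_capacitance),
            class = "cellParams")
}

# scaling vector in the order the compiled model expects
.scal_vec <- function(channel_scalings) {
  as.numeric(channel_scalings[channelNames()])
}

#' Initial (resting) cell state
#'
#' Returns the published resting initial conditions of the ventricular cell
#' model for the requested transmural variant.  Deterministic.
#'
#' @inheritParams cellParams
#' @return Object of class \code{cellState}: named state vector (membrane
#'   potential \code{v} in mV, gates, concentrations in mM, CaMK-bound
#'   fraction) plus the simulation time.
#' @export
initState <- function(cell_type = c("endo", "M", "epi")) {
  cell_type <- match.arg(cell_type)
  structure(list(state = ord_initial_state(cell_type),
                 cell_type = cell_type, t = 0),
            class = "cellState")
}

#' @export
print.cellState <- function(x, ...) {
  cat("<cellState> ", x$cell_type, " cell at t = ", x$t, " ms, Vm = ",
      round(x$state[["v"]], 2), " mV\n", sep = "")
  cat("  [Ca]i = ", signif(x$state[["cai"]], 3), " mM, [Na]i = ",
      signif(x$state[["nai"]], 3), " mM, [K]i = ",
      signif(x$state[["ki"]], 4), " mM\n", sep = "")
  invisible(x)
}

#' Membrane potential of a cell state (mV)
#' @param state A \code{cellState}.
#' @export
vm <- function(state) state$state[["v"]]

#' Gate variables of a cell state
#' @param state A \code{cellState}.
#' @return Named numeric of gating variables, each in \code{[0, 1]}.
#' @export
gates <- function(state) state$state[gateNames()]

#' Concentration variables of a cell state (mM)
#' @param state A \code{cellState}.
#' @export
concentrations <- function(state) state$state[concentrationNames()]

#' Instantaneous ionic currents (A/F)
#'
#' Evaluates every ionic current of the cell model at the given state, with
#' the drug scalings of \code{params} applied.  \code{Iion} is the sum of all
#' components and \code{dVdt = -(Iion + Istim)}.
#'
#' @param state A \code{cellState}.
#' @param params A \code{cellParams}.
#' @param stim Stimulus current (A/F), default 0.
#' @return Object of class \code{currentSet} (named list of currents, A/F).
#' @export
computeCurrents <- function(state, params, stim = 0) {
  stopifnot(inherits(state, "cellState"), inherits(params, "cellParams"))
  if (anyNA(state$state) || any(!is.finite(state$state)))
    stop("non-finite value in cell state")
  out <- ord_currents(state$state, params$cell_type,
                      .scal_vec(params$channel_scalings), stim)
  structure(out, class = "currentSet")
}

#' @export
print.currentSet <- function(x, ...) {
  cat("<currentSet> Iion =", signif(x$Iion, 4), "A/F, dV/dt =",
      signif(x$dVdt, 4), "mV/ms\n")
  comp <- unlist(x[setdiff(names(x), c("Iion", "Istim", "dVdt"))])
  print(signif(comp, 3))
  invisible(x)
}

#' Advance a cell state by one explicit time step
#'
#' Default integration is the hybrid scheme used by the reference code of the
#' cell model: exponential (Rush-Larsen) updates for the relaxation-form
#' gating variables and forward Euler for membrane potential, concentrations
#' and CaMK; \code{method = "fe"} selects pure forward Euler.
#'
#' @param state A \code{cellState}.
#' @param params A \code{cellParams}.
#' @param stim Stimulus current (A/F, negative = depolarizing).
#' @param dt Time step (ms), positive; 0.005 ms is the package default.
#' @param method \code{"rl"} (default) or \code{"fe"}.
#' @return The advanced \code{cellState}.
#' @export
stepCell <- function(state, params, stim = 0, dt = 0.005, method = c("rl", "fe")) {
  stopifnot(inherits(state, "cellState"), inherits(params, "cellParams"))
  method <- match.arg(method)
  new_state <- ord_step(state$state, params$cell_type,
                        .scal_vec(params$channel_scalings), stim, dt, method)
  structure(list(state = new_state, cell_type = state$cell_type,
                 t = state$t + dt),
            class = "cellState")
}
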