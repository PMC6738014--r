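# Forward ECG: volume-conductor potentials from monodomain sources.
#
# The source current density on each element is J_c = -D grad(Vm) (constant
# per linear element).  The default forward model is the homogeneous
# unbounded-medium reduction of the surface-potential equation (all
# conductivity jumps zero); a single-closed-surface boundary-element model of
# an insulated torso is available as an option.  Potentials are reported in
# units proportional to mV (the 1D/2D source embedding fixes no absolute
# cross-sectional area); all interval biomarkers are amplitude-invariant.

# embed mesh coordinates in 3D
.embed3 <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 3) X <- cbind(X, matrix(0, nrow(X), 3 - ncol(X)))
  X
}

# per-element geometry: centroids (3D), volumes, gradient operators
.element_geometry <- function(model) {
  el <- model$elements
  m <- nrow(el)
  nv <- ncol(el)
  nodes3 <- .embed3(model$nodes)
  cent <- matrix(0, m, 3)
  vol <- numeric(m)
  # sparse gradient operators: per-component m x n matrices
  ii <- rep(seq_len(m), each = nv)
  jj <- as.vector(t(el))
  gx <- gy <- gz <- numeric(m * nv)
  d <- ncol(model$nodes)
  for (e in seq_len(m)) {
    idx <- el[e, ]
    g <- .simplex_geom(model$nodes[idx, , drop = FALSE])
    vol[e] <- g$vol
    cent[e, ] <- colMeans(nodes3[idx, , drop = FALSE])
    G3 <- matrix(0, nv, 3)
    G3[, seq_len(d)] <- g$G
    rng <- ((e - 1) * nv + 1):(e * nv)
    gx[rng] <- G3[, 1]; gy[rng] <- G3[, 2]; gz[rng] <- G3[, 3]
  }
  n <- nrow(model$nodes)
  list(centroid = cent, vol = vol,
       Gx = Matrix::sparseMatrix(i = ii, j = jj, x = gx, dims = c(m, n)),
       Gy = Matrix::sparseMatrix(i = ii, j = jj, x = gy, dims = c(m, n)),
       Gz = Matrix::sparseMatrix(i = ii, j = jj, x = gz, dims = c(m, n)))
}

#' Source current density field from a tissue recording
#'
#' Per-element source current density \code{J_c = -D grad(Vm)} (constant on
#' linear elements), with element centroid positions.
#'
#' @param recording A \code{tissueRecording}.
#' @param model The \code{tissueModel} the recording was produced on
#'   (default: the model stored in the recording).
#' @param time_index Which saved sample(s) to evaluate (default: all).
#' @return Object of class \code{sourceField}: list with \code{centroid}
#'   (m x 3, cm), \code{vol} (element measures), and \code{J} — a list of
#'   m x 3 matrices, one per requested time sample.
#' @export
computeSources <- function(recording, model = recording$model,
                           time_index = NULL) {
  stopifnot(inherits(model, "tissueModel"))
  if (nrow(recording$vm) != nrow(model$nodes))
    stop("recording and mesh are inconsistent")
  if (is.null(time_index)) time_index <- seq_along(recording$time)
  geo <- .element_geometry(model)
  J <- lapply(time_index, function(k) {
    v <- recording$vm[, k]
    cbind(-model$D * as.numeric(geo$Gx %*% v),
          -model$D * as.numeric(geo$Gy %*% v),
          -model$D * as.numeric(geo$Gz %*% v))
  })
  structure(list(centroid = geo$centroid, vol = geo$vol, J = J,
                 time = recording$time[time_index]),
            class = "sourceField")
}

#' Infinite-medium potential of a source field
#'
#' Evaluates the homogeneous unbounded-medium reduction of the forward
#' problem at arbitrary field points by single-point (centroid) quadrature
#' per source element: \code{phi(r) = 1/(4 pi sigma) * sum_e vol_e J_e .
#' (r - c_e)/|r - c_e|^3}.
#'
#' @param sources A \code{sourceField} (see \code{\link{computeSources}}),
#'   or a list with \code{centroid}, \code{vol} and \code{J}.
#' @param points Field points, k x 3 matrix (cm); must lie outside the
#'   source support.
#' @param sigma Medium conductivity (mS/cm), default 2.0.
#' @return Matrix k x length(sources$J) of potentials.
#' @export
potentialHomogeneous <- function(sources, points, sigma = 2.0) {
  points <- .embed3(points)
  cent <- sources$centroid
  out <- matrix(0, nrow(points), length(sources$J))
  for (p in seq_len(nrow(points))) {
    rvec <- sweep(-cent, 2, points[p, ], "+") # r - c_e
    dist <- sqrt(rowSums(rvec^2))
    if (any(dist < 1e-9))
      stop("field point coincides with a source element centroid")
    w <- sources$vol * rvec / dist^3 / (4 * pi * sigma)
    for (k in seq_along(sources$J))
      out[p, k] <- sum(w * sources$J[[k]])
  }
  out
}

# van Oosterom & Strackee: solid angle of triangle (p1,p2,p3) at the origin
.solid_angle <- function(p1, p2, p3) {
  n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2)); n3 <- sqrt(sum(p3^2))
  num <- p1[1] * (p2[2] * p3[3] - p2[3] * p3[2]) -
    p1[2] * (p2[1] * p3[3] - p2[3] * p3[1]) +
    p1[3] * (p2[1] * p3[2] - p2[2] * p3[1])
  den <- n1 * n2 * n3 + sum(p1 * p2) * n3 + sum(p1 * p3) * n2 +
    sum(p2 * p3) * n1
  2 * atan2(num, den)
}

#' Surface potentials on a closed torso surface (boundary-element model)
#'
#' Solves the single-surface collocation form of the surface-potential
#' equation \code{phi(r) = 1/(2 pi (s- + s+)) [ 4 pi s phi_inf(r) +
#' (s- - s+) sum_j Omega_ij phi_j ]} with solid angles from the analytic
#' triangle formula and collocation at triangle centroids.  For the
#' torso-air boundary (\code{sigma_out = 0}) the system is singular up to an
#' additive constant; the rank deficiency is removed by deflation and the
#' result returned in a zero-mean gauge (lead voltages are invariant to the
#' free constant).  With \code{sigma_out = sigma_in} the conductivity jump
#' vanishes and the solution reduces to the infinite-medium potential.
#'
#' @param sources A \code{sourceField}.
#' @param surface A closed triangulated surface: list with \code{nodes}
#'   (k x 3, cm) and \code{triangles} (t x 3, outward-oriented).
#' @param sigma_in Interior conductivity (mS/cm), default 2.0 (also the
#'   source-region conductivity).
#' @param sigma_out Exterior conductivity (mS/cm), default 0 (air).
#' @return Matrix (n_triangles x n_times) of centroid potentials (zero-mean
#'   gauge when \code{sigma_out = 0}).
#' @export
bemSurfacePotentials <- function(sources, surface, sigma_in = 2.0,
                                 sigma_out = 0) {
  if (sigma_in <= 0 || sigma_out < 0) stop("invalid conductivities")
  tri <- as.matrix(surface$triangles)
  nod <- .embed3(surface$nodes)
  if (!.surface_closed(tri))
    stop("surface is not closed (every edge must belong to exactly 2 triangles)")
  nt <- nrow(tri)
  cent <- t(vapply(seq_len(nt), function(e)
    colMeans(nod[tri[e, ], , drop = FALSE]), numeric(3)))
  # solid-angle matrix: Omega[i, j] = angle of triangle j seen from centroid
  # i (vectorized van Oosterom-Strackee over j for each collocation point)
  V1 <- nod[tri[, 1], , drop = FALSE]
  V2 <- nod[tri[, 2], , drop = FALSE]
  V3 <- nod[tri[, 3], , drop = FALSE]
  Omega <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    P1 <- sweep(V1, 2, cent[i, ])
    P2 <- sweep(V2, 2, cent[i, ])
    P3 <- sweep(V3, 2, cent[i, ])
    n1 <- sqrt(rowSums(P1^2)); n2 <- sqrt(rowSums(P2^2))
    n3 <- sqrt(rowSums(P3^2))
    cr <- cbind(P2[, 2] * P3[, 3] - P2[, 3] * P3[, 2],
                P2[, 3] * P3[, 1] - P2[, 1] * P3[, 3],
                P2[, 1] * P3[, 2] - P2[, 2] * P3[, 1])
    num <- rowSums(P1 * cr)
    den <- n1 * n2 * n3 + rowSums(P1 * P2) * n3 + rowSums(P1 * P3) * n2 +
      rowSums(P2 * P3) * n1
    Omega[i, ] <- 2 * atan2(num, den)
    Omega[i, i] <- 0 # flat element subtends zero angle at its own centroid
  }
  ratio <- (sigma_in - sigma_out) / (sigma_in + sigma_out)
  A <- diag(nt) - ratio * Omega / (2 * pi)
  phi_inf <- potentialHomogeneous(sources, cent, sigma = sigma_in)
  b <- (2 * sigma_in / (sigma_in + sigma_out)) * phi_inf
  if (sigma_out == 0) {
    # deflation: add a rank-one term to remove the constant nullspace
    A <- A + matrix(1 / nt, nt, nt)
    phi <- solve(A, b)
    sweep(phi, 2, colMeans(phi)) # zero-mean gauge
  } else {
    solve(A, b)
  }
}

.surface_closed <- function(tri) {
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Lead voltages from electrode potentials
#'
#' @param potentials Named list or matrix of per-electrode potential traces
#'   (electrodes x time), rownames = electrode names.
#' @param leads Named list of 2-element character vectors
#'   \code{c(positive, negative)}; default: lead I = LA - RA.
#' @param time Time grid (ms).
#' @param pacing_times Pacing markers (ms).
#' @return Object of class \code{ecgTrace}: \code{time}, matrix \code{leads}
#'   (lead x time), \code{pacing_times}.
#' @export
leadVoltage <- function(potentials, leads = list(leadI = c("LA", "RA")),
                        time = NULL, pacing_times = numeric(0)) {
  pot <- as.matrix(potentials)
  out <- matrix(0, length(leads), ncol(pot),
                dimnames = list(names(leads), NULL))
  for (nm in names(leads)) {
    pair <- leads[[nm]]
    if (!all(pair %in% rownames(pot)))
      stop("undefined electrode(s): ",
           paste(setdiff(pair, rownames(pot)), collapse = ", "))
    out[nm, ] <- pot[pair[1], ] - pot[pair[2], ]
  }
  structure(list(time = time, leads = out, pacing_times = pacing_times),
            class = "ecgTrace")
}

#' @export
print.ecgTrace <- function(x, ...) {
  cat("<ecgTrace> ", nrow(x$leads), " lead(s) x ", ncol(x$leads),
      " samples", sep = "")
  if (!is.null(x$time)) cat(" (", max(x$time), " ms)", sep = "")
  cat("\n  leads:", paste(rownames(x$leads), collapse = ", "), "\n")
  invisible(x)
}

#' Default electrode positions for a tissue model
#'
#' Canonical fixed coordinates: for a cable along x, "LA" sits beyond the
#' epicardial end and "RA" beyond the endocardial end (2 cm axial clearance,
#' 0.5 cm lateral offset); "LL" sits below the midpoint.  For 2D/3D meshes
#' the same pattern is applied along the first coordinate axis.
#'
#' @param model A \code{tissueModel}.
#' @param clearance_cm Axial distance beyond the tissue extent, default 2.
#' @return Matrix 3 x 3 with rownames RA, LA, LL (cm).
#' @export
torsoElectrodes <- function(model, clearance_cm = 2) {
  nodes3 <- .embed3(model$nodes)
  lo <- min(nodes3[, 1]); hi <- max(nodes3[, 1])
  mid <- colMeans(nodes3)
  rbind(RA = c(lo - clearance_cm, mid[2] + 0.5, mid[3]),
        LA = c(hi + clearance_cm, mid[2] + 0.5, mid[3]),
        LL = c(mid[1], mid[2] - clearance_cm, mid[3]))
}

#' Forward-computed ECG from a tissue recording
#'
#' Runs the default homogeneous forward model: sources from the recording,
#' infinite-medium potentials at the electrodes, lead voltages.  With
#' \code{forward = "bem"} the electrode potentials are taken from the
#' boundary-element torso-surface solution at the surface triangles nearest
#' each electrode.
#'
#' @param recording A \code{tissueRecording}.
#' @param electrodes Electrode matrix (rows named RA/LA/..., cm); default
#'   \code{\link{torsoElectrodes}}.
#' @param leads Lead definitions as in \code{\link{leadVoltage}}.
#' @param sigma Conductivity (mS/cm), default 2.0.
#' @param forward \code{"homogeneous"} (default) or \code{"bem"}.
#' @param surface Closed torso surface (required for \code{"bem"}).
#' @return An \code{ecgTrace}.
#' @export
forwardEcg <- function(recording, electrodes = NULL,
                       leads = list(leadI = c("LA", "RA")),
                       sigma = 2.0,
                       forward = c("homogeneous", "bem"),
                       surface = NULL) {
  forward <- match.arg(forward)
  if (is.null(electrodes)) electrodes <- torsoElectrodes(recording$model)
  src <- computeSources(recording)
  if (forward == "homogeneous") {
    pot <- potentialHomogeneous(src, electrodes, sigma)
    rownames(pot) <- rownames(electrodes)
  } else {
    if (is.null(surface)) stop("forward = 'bem' requires a torso surface")
    phi <- bemSurfacePotentials(src, surface, sigma_in = sigma)
    tri <- as.matrix(surface$triangles)
    nod <- .embed3(surface$nodes)
    cent <- t(vapply(seq_len(nrow(tri)), function(e)
      colMeans(nod[tri[e, ], , drop = FALSE]), numeric(3)))
    idx <- vapply(seq_len(nrow(electrodes)), function(p)
      which.min(rowSums(sweep(cent, 2, .embed3(electrodes)[p, ])^2)),
      integer(1))
    pot <- phi[idx, , drop = FALSE]
    rownames(pot) <- rownames(electrodes)
  }
  leadVoltage(pot, leads, time = recording$time,
              pacing_times = recording$pacing_times)
}
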