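# Synthetic geometry generators: desk-scale stand-ins for a patient-specific
# ventricular mesh and torso surface.  All generators are deterministic.

# unit icosahedron surface subdivided n times (a geodesic sphere)
.icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c3 <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  # orient all faces outward (centroid test on the unit sphere)
  for (r in seq_len(nrow(f))) {
    p1 <- v[f[r, 1], ]; p2 <- v[f[r, 2], ]; p3 <- v[f[r, 3], ]
    nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
             (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
             (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
    if (sum(nrm * (p1 + p2 + p3)) < 0) f[r, ] <- f[r, c(1, 3, 2)]
  }
  list(nodes = v, triangles = f)
}

#' Idealized closed torso surface
#'
#' A triangulated ellipsoid (geodesic subdivision of an icosahedron, outward
#' oriented) standing in for a patient torso boundary.
#'
#' @param semi_axes Ellipsoid semi-axes (cm), default \code{c(15, 10, 25)}.
#' @param subdiv Geodesic subdivision level (default 3: 1280 triangles).
#' @param center Center coordinates (cm).
#' @return List with \code{nodes} (k x 3) and \code{triangles} (t x 3,
#'   outward oriented), class \code{torsoSurface}.
#' @export
torsoSurface <- function(semi_axes = c(15, 10, 25), subdiv = 3,
                         center = c(0, 0, 0)) {
  ico <- .icosphere(subdiv)
  nodes <- sweep(sweep(ico$nodes, 2, semi_axes, "*"), 2, center, "+")
  structure(list(nodes = nodes, triangles = ico$triangles,
                 semi_axes = semi_axes, center = center),
            class = "torsoSurface")
}

#' Build a 2D tissue sheet
#'
#' Structured rectangle triangulated with a consistent diagonal; transmural
#' layers run along x (endo at low x, epi at high x).
#'
#' @param nx,ny Node counts (>= 2).
#' @param dx Node spacing (cm).
#' @param layer_fractions As in \code{\link{buildCable}}.
#' @param ... Passed to \code{\link{tissueModel}}.
#' @return A \code{tissueModel}.
#' @export
buildSheet <- function(nx = 40, ny = 20, dx = 0.02,
                       layer_fractions = c(endo = 1/3, M = 1/3, epi = 1/3),
                       ...) {
  if (abs(sum(layer_fractions) - 1) > 1e-9)
    stop("layer fractions must sum to 1")
  nodes <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * dx,
                                 y = (seq_len(ny) - 1) * dx))
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c3 <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      tris <- rbind(tris, c(a, b, d), c(a, d, c3))
    }
  }
  xf <- nodes[, 1] / max(nodes[, 1])
  cuts <- cumsum(layer_fractions[c("endo", "M", "epi")])
  types <- ifelse(xf <= cuts[1] + 1e-12, "endo",
                  ifelse(xf <= cuts[2] + 1e-12, "M", "epi"))
  tissueModel(nodes, tris, types, ...)
}

# split the prism (bottom triangle b1 b2 b3, top t1 t2 t3) into 3 tetrahedra
# with conforming diagonals (rotate so the smallest global index leads, then
# choose diagonals toward smaller indices)
.prism_tets <- function(b, t) {
  k <- which.min(c(b, t))
  if (k > 3) { tmp <- b; b <- t; t <- tmp; k <- k - 3 } # smallest on bottom
  rot <- ((k - 1) + 0:2) %% 3 + 1
  b <- b[rot]; t <- t[rot]
  # vertex 1 = b[1] is global minimum; faces (b2,b3,t3,t2) diagonal choice
  if (min(b[2], t[3]) < min(b[3], t[2])) {
    rbind(c(b[1], b[2], b[3], t[3]),
          c(b[1], b[2], t[3], t[2]),
          c(b[1], t[2], t[3], t[1]))
  } else {
    rbind(c(b[1], b[2], b[3], t[2]),
          c(b[1], t[2], b[3], t[3]),
          c(b[1], t[2], t[3], t[1]))
  }
}

#' Build a small 3D slab
#'
#' Triangulated sheet extruded along z into conforming tetrahedra; layers
#' along x as in \code{\link{buildCable}}.
#'
#' @param nx,ny,nz Node counts per direction.
#' @param dx Spacing (cm).
#' @param layer_fractions As in \code{\link{buildCable}}.
#' @param ... Passed to \code{\link{tissueModel}}.
#' @return A \code{tissueModel}.
#' @export
buildSlab <- function(nx = 20, ny = 8, nz = 4, dx = 0.02,
                      layer_fractions = c(endo = 1/3, M = 1/3, epi = 1/3),
                      ...) {
  sheet <- buildSheet(nx, ny, dx, layer_fractions)
  n2 <- nrow(sheet$nodes)
  nodes <- do.call(rbind, lapply(seq_len(nz) - 1, function(l)
    cbind(sheet$nodes, z = l * dx)))
  tets <- matrix(0L, 0, 4)
  for (l in seq_len(nz - 1) - 1) {
    off_b <- l * n2; off_t <- (l + 1) * n2
    for (r in seq_len(nrow(sheet$elements))) {
      tri <- sheet$elements[r, ]
      tets <- rbind(tets, .prism_tets(tri + off_b, tri + off_t))
    }
  }
  types <- rep(sheet$cell_type, nz)
  tissueModel(nodes, tets, types, ...)
}

#' Build a 3D ellipsoid-shell ventricular stand-in
#'
#' A closed shell between two concentric ellipsoidal surfaces, meshed by
#' extruding a geodesic sphere radially into prisms split into conforming
#' tetrahedra.  Transmural cell-type layers run radially: endocardium at the
#' inner surface, epicardium at the outer.
#'
#' @param semi_axes_outer Outer semi-axes (cm), default \code{c(1.5, 1.5, 2)}.
#' @param wall_fraction Wall thickness as a fraction of the semi-axes,
#'   default 0.35.
#' @param subdiv Geodesic subdivision of the surfaces (default 2: 320
#'   triangles per surface).
#' @param n_layers Radial element layers (default 3).
#' @param layer_fractions As in \code{\link{buildCable}} (radial fractions).
#' @param ... Passed to \code{\link{tissueModel}}.
#' @return A \code{tissueModel}; attribute \code{"inner_nodes"} lists the
#'   endocardial-surface node indices (PMJ candidates), attribute
#'   \code{"boundary"} the closed boundary triangulation.
#' @export
ellipsoidShell <- function(semi_axes_outer = c(1.5, 1.5, 2),
                           wall_fraction = 0.35, subdiv = 2, n_layers = 3,
                           layer_fractions = c(endo = 1/3, M = 1/3, epi = 1/3),
                           ...) {
  if (wall_fraction <= 0 || wall_fraction >= 1)
    stop("wall_fraction must be in (0, 1)")
  ico <- .icosphere(subdiv)
  ns <- nrow(ico$nodes)
  radial <- seq(1 - wall_fraction, 1, length.out = n_layers + 1)
  nodes <- do.call(rbind, lapply(radial, function(r)
    sweep(ico$nodes * r, 2, semi_axes_outer, "*")))
  tets <- matrix(0L, 0, 4)
  for (l in seq_len(n_layers) - 1) {
    off_b <- l * ns; off_t <- (l + 1) * ns
    for (r in seq_len(nrow(ico$triangles))) {
      tri <- ico$triangles[r, ]
      tets <- rbind(tets, .prism_tets(tri + off_b, tri + off_t))
    }
  }
  # radial layer fraction per node -> transmural type
  frac <- rep((radial - radial[1]) / (radial[length(radial)] - radial[1]),
              each = ns)
  cuts <- cumsum(layer_fractions[c("endo", "M", "epi")])
  types <- ifelse(frac <= cuts[1] + 1e-12, "endo",
                  ifelse(frac <= cuts[2] + 1e-12, "M", "epi"))
  model <- tissueModel(nodes, tets, types, ...)
  attr(model, "inner_nodes") <- seq_len(ns)
  inner_tri <- ico$triangles[, c(1, 3, 2)] # inward-facing shell boundary
  outer_tri <- ico$triangles + n_layers * ns
  attr(model, "boundary") <- rbind(inner_tri, outer_tri)
  model
}

#' Generate and write a synthetic geometry
#'
#' Deterministic geometry factory for the supported kinds; writes the mesh
#' (and any auxiliary artifacts) as plain-text files and returns the objects.
#'
#' @param kind One of \code{"cable"}, \code{"sheet"}, \code{"slab"},
#'   \code{"ellipsoid_shell"}, \code{"torso_surface"}.
#' @param params Named list of generator arguments (see the individual
#'   builders).
#' @param dir Output directory (created if needed); \code{NULL} skips
#'   writing.
#' @return The generated \code{tissueModel} or \code{torsoSurface};
#'   for \code{"ellipsoid_shell"} the attached Purkinje network (over a
#'   subset of inner-surface nodes) is written alongside.
#' @export
generateGeometry <- function(kind = c("cable", "sheet", "slab",
                                      "ellipsoid_shell", "torso_surface"),
                             params = list(), dir = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    cable = do.call(buildCable, params),
    sheet = do.call(buildSheet, params),
    slab = do.call(buildSlab, params),
    ellipsoid_shell = do.call(ellipsoidShell, params),
    torso_surface = do.call(torsoSurface, params))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (kind == "torso_surface") {
      writeMesh(list(nodes = obj$nodes, elements = obj$triangles),
                file.path(dir, paste0(kind, ".mesh")))
    } else {
      writeMesh(obj, file.path(dir, paste0(kind, ".mesh")))
      if (kind == "ellipsoid_shell") {
        inner <- attr(obj, "inner_nodes")
        pk <- binaryTreePurkinje(inner[seq(1, length(inner), by = 4)])
        writePurkinje(pk, file.path(dir, "purkinje.json"))
      }
    }
  }
  obj
}
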