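# Synthetic geometry generators and mesh I/O.

euler_characteristic <- function(tri) {
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- unique(paste(pmin(edges[, 1], edges[, 2]),
                      pmax(edges[, 1], edges[, 2])))
  length(unique(as.vector(tri))) - length(key) + nrow(tri)
}

test_that("cable geometry has the stated node and element counts", {
  m <- generateGeometry("cable", list(n_nodes = 165, dx = 0.01))
  expect_equal(nrow(m$nodes), 165)
  expect_equal(nrow(m$elements), 164)
})

test_that("the torso surface is closed, outward-oriented, genus 0", {
  surf <- torsoSurface(subdiv = 2)
  expect_equal(nrow(surf$triangles), 320)
  expect_true(cardioscreen:::.surface_closed(surf$triangles))
  expect_equal(euler_characteristic(surf$triangles), 2)
  # outward orientation: positive enclosed volume via the divergence theorem
  vol <- sum(vapply(seq_len(nrow(surf$triangles)), function(r) {
    p <- surf$nodes[surf$triangles[r, ], ]
    det(p) / 6
  }, numeric(1)))
  expect_gt(vol, 0)
  # ~ellipsoid volume 4/3 pi abc at this refinement
  expect_equal(vol, 4 / 3 * pi * prod(surf$semi_axes), tolerance = 0.05)
})

test_that("the ellipsoid shell is a valid closed-shell tet mesh", {
  m <- ellipsoidShell(subdiv = 1, n_layers = 2)
  expect_s3_class(m, "tissueModel")
  # all tetrahedra non-degenerate with consistent decomposition: FEM
  # assembly succeeds and conserves constants
  L <- assembleDiffusion(m)
  expect_lt(max(abs(L %*% rep(1, nrow(m$nodes)))), 1e-8)
  # boundary = inner + outer closed surfaces: total Euler characteristic 4
  bnd <- attr(m, "boundary")
  expect_true(cardioscreen:::.surface_closed(bnd))
  expect_equal(euler_characteristic(bnd), 4)
  # transmural typing: inner nodes endocardial, outermost epicardial
  inner <- attr(m, "inner_nodes")
  expect_true(all(m$cell_type[inner] == "endo"))
  expect_true(all(m$cell_type[(nrow(m$nodes) - length(inner) + 1):
                                nrow(m$nodes)] == "epi"))
  # mesh volume approximates the analytic shell volume
  vols <- vapply(seq_len(nrow(m$elements)), function(e)
    cardioscreen:::.simplex_geom(m$nodes[m$elements[e, ], ])$vol, numeric(1))
  a <- c(1.5, 1.5, 2)
  shell <- 4 / 3 * pi * (prod(a) - prod(a * 0.65))
  expect_equal(sum(vols), shell, tolerance = 0.15)
})

test_that("slab extrusion produces a connected conforming tet mesh", {
  m <- buildSlab(nx = 6, ny = 4, nz = 3, dx = 0.02)
  expect_equal(nrow(m$nodes), 6 * 4 * 3)
  L <- assembleDiffusion(m)
  expect_lt(max(abs(L %*% rep(2, nrow(m$nodes)))), 1e-8)
  vols <- vapply(seq_len(nrow(m$elements)), function(e)
    cardioscreen:::.simplex_geom(m$nodes[m$elements[e, ], ])$vol, numeric(1))
  expect_equal(sum(vols), 0.1 * 0.06 * 0.04, tolerance = 1e-9)
})

test_that("geometry generation is deterministic (byte-identical files)", {
  d1 <- file.path(tempdir(), "geo1")
  d2 <- file.path(tempdir(), "geo2")
  generateGeometry("ellipsoid_shell", list(subdiv = 1), dir = d1)
  generateGeometry("ellipsoid_shell", list(subdiv = 1), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("meshes round-trip through the node/element text format", {
  m <- buildSheet(nx = 5, ny = 4)
  tf <- tempfile(fileext = ".mesh")
  writeMesh(m, tf)
  back <- readMesh(tf)
  expect_equal(back$nodes, unname(m$nodes), tolerance = 1e-12)
  expect_equal(unname(back$elements), unname(m$elements))
  expect_equal(back$cell_type, m$cell_type)
  unlink(tf)
})

test_that("VTK snapshots carry the mesh and the Vm field", {
  m <- buildCable(9)
  tf <- tempfile(fileext = ".vtk")
  writeVtkSnapshot(m, rep(-85, 9), tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl("^POINTS 9 double", lines)))
  expect_true(any(grepl("^SCALARS Vm double", lines)))
  unlink(tf)
})
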