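# Forward ECG: source fields, infinite-medium potentials, BEM torso, leads.

# small helper: recording-like object with prescribed Vm columns
fake_recording <- function(model, vm_matrix, time = seq_len(ncol(vm_matrix))) {
  structure(list(time = time, vm = vm_matrix, model = model,
                 pacing_times = 0), class = "tissueRecording")
}

point_dipole <- function(p = c(0, 0, 1)) {
  list(centroid = matrix(0, 1, 3), vol = 1, J = list(matrix(p, 1, 3)))
}

test_that("sources vanish for uniform Vm and are constant for a linear ramp", {
  m <- buildCable(21, dx = 0.01)
  rec <- fake_recording(m, cbind(rep(-80, 21), 5 * m$nodes[, 1], -m$nodes[, 1]))
  src <- computeSources(rec)
  expect_equal(max(abs(src$J[[1]])), 0)
  ramp <- src$J[[2]][, 1]
  expect_equal(ramp, rep(-m$D[1] * 5, 20), tolerance = 1e-12)
  # sign reversal of the Vm profile reverses all sources
  expect_equal(src$J[[3]][, 1], -ramp / 5, tolerance = 1e-12)
})

test_that("a point dipole reproduces the textbook on-axis potential", {
  src <- point_dipole(c(0, 0, 1))
  sigma <- 2
  for (r in c(3, 5, 10)) {
    phi <- potentialHomogeneous(src, matrix(c(0, 0, r), 1), sigma)
    expect_equal(phi[1, 1], 1 / (4 * pi * sigma * r^2), tolerance = 1e-12)
  }
  # mirror symmetry: zero on the dipole's equatorial plane
  phi_eq <- potentialHomogeneous(src, matrix(c(4, 2, 0), 1), sigma)
  expect_equal(phi_eq[1, 1], 0)
})

test_that("a compact dipolar source decays as 1/r^2", {
  # two opposite monopole-like elements -> dipole far field
  src <- list(centroid = rbind(c(0, 0, 0.05), c(0, 0, -0.05)),
              vol = c(1, 1),
              J = list(rbind(c(0, 0, 1), c(0, 0, 1))))
  r1 <- 20; r2 <- 40
  p1 <- potentialHomogeneous(src, matrix(c(0, 0, r1), 1))
  p2 <- potentialHomogeneous(src, matrix(c(0, 0, r2), 1))
  expect_equal(p2[1, 1] / p1[1, 1], 0.25, tolerance = 0.02)
})

test_that("field points inside the source support are rejected", {
  expect_error(potentialHomogeneous(point_dipole(), matrix(0, 1, 3)),
               "coincides")
})

test_that("BEM sphere solution matches the analytic bounded-sphere dipole", {
  surf <- torsoSurface(semi_axes = c(1, 1, 1), subdiv = 2) # 320 triangles
  src <- point_dipole(c(0, 0, 1))
  phi <- bemSurfacePotentials(src, surf, sigma_in = 1, sigma_out = 0)
  cent <- t(vapply(seq_len(nrow(surf$triangles)), function(e)
    colMeans(surf$nodes[surf$triangles[e, ], ]), numeric(3)))
  rr <- sqrt(rowSums(cent^2))
  ana <- 3 * (cent[, 3] / rr) / (4 * pi * rr^2)
  expect_lt(max(abs(phi - ana)) / max(abs(ana)), 0.05)
  # insulation amplifies the surface potential ~3x over the infinite medium
  phi_inf <- potentialHomogeneous(src, cent, sigma = 1)
  expect_equal(max(phi) / max(phi_inf), 3, tolerance = 0.1)
})

test_that("with no conductivity jump the BEM reduces to the infinite medium", {
  surf <- torsoSurface(semi_axes = c(1, 1, 1), subdiv = 1)
  src <- point_dipole()
  cent <- t(vapply(seq_len(nrow(surf$triangles)), function(e)
    colMeans(surf$nodes[surf$triangles[e, ], ]), numeric(3)))
  phi_eq <- bemSurfacePotentials(src, surf, sigma_in = 2, sigma_out = 2)
  phi_inf <- potentialHomogeneous(src, cent, sigma = 2)
  expect_equal(phi_eq, phi_inf, tolerance = 1e-10)
})

test_that("open surfaces are rejected", {
  surf <- torsoSurface(subdiv = 1)
  surf$triangles <- surf$triangles[-1, ]
  expect_error(bemSurfacePotentials(point_dipole(), surf), "not closed")
})

test_that("lead voltages are differences and obey their symmetries", {
  pot <- rbind(LA = c(1, 2, 3), RA = c(1, 1, 1))
  tr <- leadVoltage(pot, list(leadI = c("LA", "RA")))
  expect_equal(as.numeric(tr$leads["leadI", ]), c(0, 1, 2))
  swapped <- leadVoltage(pot, list(leadI = c("RA", "LA")))
  expect_equal(swapped$leads["leadI", ], -tr$leads["leadI", ])
  same <- leadVoltage(rbind(LA = c(5, 5), RA = c(5, 5)))
  expect_equal(as.numeric(same$leads), c(0, 0))
  expect_error(leadVoltage(pot, list(leadI = c("LA", "LL"))), "undefined")
})

test_that("uniformly polarized tissue yields a flat zero ECG", {
  m <- buildCable(21)
  rec <- fake_recording(m, matrix(-85, 21, 5))
  ecg <- forwardEcg(rec)
  expect_equal(max(abs(ecg$leads)), 0)
})

test_that("the forward map is linear in the source field", {
  m <- buildCable(21)
  v1 <- outer(m$nodes[, 1], c(1, 2, 3))
  v2 <- outer(sin(10 * m$nodes[, 1]), c(3, 1, 0))
  e1 <- forwardEcg(fake_recording(m, v1))$leads
  e2 <- forwardEcg(fake_recording(m, v2))$leads
  e12 <- forwardEcg(fake_recording(m, v1 + v2))$leads
  expect_equal(e12, e1 + e2, tolerance = 1e-10)
})

test_that("homogeneous and BEM forward models time-align the T peak", {
  # shared recording: one depolarization/repolarization cycle on a short
  # cable, compared through both forward models on a small closed torso
  m <- buildCable(41, layer_fractions = c(endo = 1, M = 0, epi = 0))
  rec <- runTissueSimulation(m, directSchedule(c(1L, 2L)), duration = 320,
                             dt = 0.01, save_stride_ms = 2)
  surf <- torsoSurface(semi_axes = c(3, 2.5, 2.5), subdiv = 2,
                       center = c(0.2, 0, 0))
  ecg_h <- forwardEcg(rec)
  ecg_b <- forwardEcg(rec, forward = "bem", surface = surf)
  tw <- rec$time > 150 # T-wave window, past the QRS
  tp_h <- rec$time[tw][which.max(abs(ecg_h$leads[1, tw]))]
  tp_b <- rec$time[tw][which.max(abs(ecg_b$leads[1, tw]))]
  expect_lt(abs(tp_h - tp_b), 5)
})
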