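# Monodomain tissue: mesh builders, FEM diffusion operator, explicit
# stepping, activation ordering.

test_that("buildCable lays out transmural layers as requested", {
  m <- buildCable(165, 0.01)
  expect_equal(as.integer(table(m$cell_type)[c("endo", "M", "epi")]),
               c(55L, 55L, 55L))
  expect_equal(nrow(m$elements), 164)
  # node-order convention: endo indices < M indices < epi indices
  expect_true(max(which(m$cell_type == "endo")) <
                min(which(m$cell_type == "M")))
  expect_true(max(which(m$cell_type == "M")) <
                min(which(m$cell_type == "epi")))
  all_endo <- buildCable(9, 0.01, c(endo = 1, M = 0, epi = 0))
  expect_true(all(all_endo$cell_type == "endo"))
  expect_error(buildCable(9, 0.01, c(endo = 0.5, M = 0.2, epi = 0.2)),
               "sum to 1")
})

test_that("the printed diffusion coefficient and its unit switch are stored", {
  m <- buildCable(9)
  expect_equal(m$d_printed, 0.00154)
  expect_equal(m$D[1], 0.00154) # default reading: cm^2/ms
  m_s <- buildCable(9, D = 0.00154, d_time_unit = "s")
  expect_equal(m_s$D[1], 0.00154 / 1000)
})

test_that("diffusion operator conserves constants and matches the 1D stencil", {
  m <- buildCable(9, dx = 0.01)
  L <- assembleDiffusion(m)
  expect_lt(max(abs(L %*% rep(3.7, 9))), 1e-10)
  D <- m$D[1]
  expect_equal(as.numeric(L[5, 4:6]), D / 0.01^2 * c(1, -2, 1),
               tolerance = 1e-10)
  # symmetric in the mass inner product (stiffness symmetry)
  K <- Matrix::Diagonal(x = attr(L, "lumped_mass")) %*% L
  expect_lt(max(abs(K - Matrix::t(K))), 1e-10)
})

test_that("pure diffusion reproduces the analytic Neumann decay within 1%", {
  n <- 201
  dx <- 0.005
  m <- buildCable(n, dx = dx)
  L <- assembleDiffusion(m)
  Lx <- (n - 1) * dx
  D <- m$D[1]
  v <- cos(pi * m$nodes[, 1] / Lx) # Neumann eigenmode, rate D*(pi/Lx)^2
  dt <- 0.005
  t_end <- 5
  for (s in seq_len(round(t_end / dt))) v <- v + dt * as.numeric(L %*% v)
  decay <- exp(-D * (pi / Lx)^2 * t_end)
  expect_equal(max(v), decay, tolerance = 0.01)
})

test_that("degenerate elements are rejected", {
  nodes <- matrix(c(0, 0, 0.01), ncol = 1)
  el <- rbind(c(1, 2), c(2, 3))
  m <- tissueModel(nodes, el, rep("endo", 3))
  expect_error(assembleDiffusion(m), "degenerate")
})

test_that("a uniform unstimulated tissue follows the single-cell trajectory", {
  m <- buildCable(21, layer_fractions = c(endo = 1, M = 0, epi = 0))
  rec <- runTissueSimulation(m, directSchedule(integer(0)), duration = 20,
                             pacing_times = numeric(0), dt = 0.01,
                             save_stride_ms = 1)
  single <- paceToSteadyState("endo", protocol = pacingProtocol(
    cl = 20, n_beats = 1, stim_amplitude = 0, dt = 0.01, save_stride_ms = 1))
  # all nodes identical, equal to the single cell, to ~1e-9 mV
  for (k in seq_along(rec$time)) {
    expect_lt(diff(range(rec$vm[, k])), 1e-9)
  }
  vm_node <- rec$vm[10, ]
  vm_cell <- approx(single$time, single$vm, xout = rec$time, rule = 2)$y
  expect_lt(max(abs(vm_node - vm_cell)), 1e-6)
})

test_that("dt above the explicit stability bound is refused", {
  m <- buildCable(21)
  L <- assembleDiffusion(m)
  expect_error(runTissueSimulation(m, directSchedule(1L), duration = 5,
                                   dt = 2 * dtMaxExplicit(L)),
               "stability bound")
  states <- vapply(m$cell_type, cardioscreen:::ord_initial_state, numeric(41))
  expect_error(stepTissue(states, m$cell_type, L, dt = 2 * dtMaxExplicit(L)),
               "stability bound")
})

test_that("end-stimulated cable activates in strictly increasing order", {
  m <- buildCable(61)
  rec <- runTissueSimulation(m, directSchedule(c(1L, 2L)), duration = 60,
                             dt = 0.01, save_stride_ms = 0.5)
  at <- rec$activation_time
  expect_true(all(is.finite(at)))
  expect_true(all(diff(at[3:61]) > 0))
  # epicardial activation strictly after endocardial (endo-before-epi)
  expect_gt(min(at[m$cell_type == "epi"]), max(at[m$cell_type == "endo"]))
})

test_that("two simultaneous end stimuli collide at the cable midpoint", {
  m <- buildCable(61, layer_fractions = c(endo = 1, M = 0, epi = 0))
  rec <- runTissueSimulation(m, directSchedule(c(1L, 61L)), duration = 60,
                             dt = 0.01, save_stride_ms = 0.5)
  at <- rec$activation_time
  expect_equal(which.max(at), 31)
  expect_equal(at, rev(at), tolerance = 1e-9)
})

test_that("conduction velocity scales as sqrt(D) and converges in dx", {
  # measure CV from the activation-time slope over the cable interior; a
  # several-node stimulus is used so capture succeeds at the larger space
  # constant of the 4D case, and dx is refined (the continuum CV ratio is
  # approached only as the wavefront is resolved)
  cv_for <- function(Dval, dx, dt, n) {
    m <- buildCable(n, dx = dx, D = Dval,
                    layer_fractions = c(endo = 1, M = 0, epi = 0))
    rec <- runTissueSimulation(m, directSchedule(1:6), duration = 100,
                               dt = dt, save_stride_ms = 0.5)
    at <- rec$activation_time
    idx <- round(n / 3):round(0.85 * n)
    fit <- stats::lm(at[idx] ~ m$nodes[idx, 1])
    1 / unname(stats::coef(fit)[2]) # cm/ms
  }
  cv1 <- cv_for(0.00154, 0.005, 0.005, 241)
  cv4 <- cv_for(4 * 0.00154, 0.005, 0.002, 241)
  expect_equal(cv4 / cv1, 2, tolerance = 0.05)
  # discretization robustness: doubling dx moves CV by < 5%
  cv_coarse <- cv_for(0.00154, 0.01, 0.005, 121)
  expect_equal(cv_coarse / cv1, 1, tolerance = 0.05)
})

test_that("a drug at 0x leaves the tissue recording bit-identical", {
  m <- buildCable(21)
  r1 <- runTissueSimulation(m, directSchedule(1L), duration = 30, dt = 0.01)
  r2 <- runTissueSimulation(m, directSchedule(1L), duration = 30, dt = 0.01,
                            scalings = drugScalings(bundled_drugs$verapamil,
                                                    0))
  expect_identical(r1$vm, r2$vm)
})

test_that("activation sequence is invariant to node renumbering", {
  m <- buildCable(31, layer_fractions = c(endo = 1, M = 0, epi = 0))
  rec <- runTissueSimulation(m, directSchedule(1L), duration = 40, dt = 0.01)
  perm <- c(seq(1, 31, by = 2), seq(2, 30, by = 2)) # odd nodes first
  m2 <- tissueModel(m$nodes[perm, , drop = FALSE],
                    matrix(match(as.vector(m$elements), perm),
                           ncol = 2),
                    m$cell_type[perm])
  rec2 <- runTissueSimulation(m2, directSchedule(match(1L, perm)),
                              duration = 40, dt = 0.01)
  expect_equal(rec2$activation_time[match(seq_len(31), perm)],
               rec$activation_time, tolerance = 1e-12)
})
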