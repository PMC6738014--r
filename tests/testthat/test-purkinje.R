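# Purkinje activation scheduler and the PMJ stimulation rule.

simple_net <- function(len = 2, speed = 0.2, node = 5L) {
  purkinjeNetwork(
    data.frame(id = 1L, parent = NA_integer_, length_cm = len,
               speed_cm_per_ms = speed),
    data.frame(segment = 1L, node = node))
}

test_that("PMJ times are path sums of length over speed", {
  sch <- scheduleFromNetwork(simple_net(2, 0.2), pacing_time = 0)
  expect_equal(sch$delay_ms, 10)
  sch5 <- scheduleFromNetwork(simple_net(2, 0.2), pacing_time = 5)
  expect_equal(sch5$t_start, 15)
  # two-level path: delays add along the unique root-to-leaf path
  net <- purkinjeNetwork(
    data.frame(id = 1:3, parent = c(NA, 1L, 2L),
               length_cm = c(1, 2, 0.5),
               speed_cm_per_ms = c(0.2, 0.1, 0.25)),
    data.frame(segment = 3L, node = 1L))
  expect_equal(scheduleFromNetwork(net)$delay_ms, 1 / 0.2 + 2 / 0.1 + 0.5 / 0.25)
})

test_that("doubling all speeds halves all delays", {
  net <- binaryTreePurkinje(1:8, branch_length_cm = 0.8,
                            speed_cm_per_ms = 0.2)
  net2 <- net
  net2$segments$speed_cm_per_ms <- 2 * net2$segments$speed_cm_per_ms
  d1 <- scheduleFromNetwork(net)$delay_ms
  d2 <- scheduleFromNetwork(net2)$delay_ms
  expect_equal(d2, d1 / 2)
})

test_that("a degenerate zero-length root fires the PMJ at the pacing time", {
  sch <- scheduleFromNetwork(simple_net(0, 0.2), pacing_time = 3)
  expect_equal(sch$t_start, 3)
})

test_that("cycles and invalid parameters are rejected", {
  expect_error(purkinjeNetwork(
    data.frame(id = 1:2, parent = c(2L, 1L), length_cm = 1,
               speed_cm_per_ms = 0.2),
    data.frame(segment = 2L, node = 1L)))
  expect_error(purkinjeNetwork(
    data.frame(id = 1L, parent = NA, length_cm = 1, speed_cm_per_ms = 0),
    data.frame(segment = 1L, node = 1L)), "speeds")
})

test_that("the PMJ rule stimulates, latches at the cutoff, never retriggers", {
  sch <- directSchedule(2L)
  vm <- c(-85, -85, -85)
  r1 <- pmjStimulate(vm, sch, t = 0)
  expect_equal(r1$stim, c(0, -80, 0))
  # node already above the cutoff at its start time: no stimulus, latch set
  vm2 <- c(-85, -5, -85)
  r2 <- pmjStimulate(vm2, sch, t = 0)
  expect_equal(r2$stim, c(0, 0, 0))
  expect_true(r2$latched)
  # once latched, a later sub-cutoff voltage draws no further current
  r3 <- pmjStimulate(c(-85, -85, -85), sch, t = 1, latched = r2$latched)
  expect_equal(r3$stim, c(0, 0, 0))
})

test_that("tissue activation never precedes the earliest PMJ time", {
  m <- buildCable(41)
  net <- binaryTreePurkinje(c(1L, 3L, 5L), branch_length_cm = 0.4,
                            speed_cm_per_ms = 0.2)
  sch <- scheduleFromNetwork(net)
  rec <- runTissueSimulation(m, sch, duration = 60, dt = 0.01,
                             save_stride_ms = 0.25)
  at <- rec$activation_time
  expect_gte(min(at, na.rm = TRUE), min(sch$t_start))
  # endocardial PMJs: epicardial activation strictly later
  expect_gt(min(at[m$cell_type == "epi"]), max(at[m$cell_type == "endo"]))
})

test_that("schedules referencing nodes outside the mesh are rejected", {
  m <- buildCable(11)
  expect_error(runTissueSimulation(m, directSchedule(99L), duration = 5,
                                   dt = 0.01), "outside the mesh")
})

test_that("a Purkinje network round-trips through JSON", {
  net <- binaryTreePurkinje(1:5)
  tf <- tempfile(fileext = ".json")
  writePurkinje(net, tf)
  back <- readPurkinje(tf)
  expect_equal(back$segments$length_cm, net$segments$length_cm)
  expect_equal(back$pmj$node, net$pmj$node)
  unlink(tf)
})
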