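# Ventricular myocyte model: initial conditions, current scalings, stepper
# consistency and gate-boundedness.

test_that("initState is deterministic and respects state-variable bounds", {
  s1 <- initState("endo")
  s2 <- initState("endo")
  expect_identical(s1$state, s2$state)
  g <- gates(s1)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(concentrations(s1) > 0))
  expect_true(vm(s1) >= -120 && vm(s1) <= 60)
  expect_error(initState("purkinje"))
})

test_that("channel scalings act multiplicatively and exactly at zero", {
  # evaluate at a depolarized mid-AP state so every scaled current is active
  tr <- cached_pace("endo", n_beats = 2)
  st <- tr$final_state
  st$state[["v"]] <- -20
  for (ch in channelNames()) {
    sc0 <- drugScalings(NULL)
    sc0[[ch]] <- 0
    cur0 <- computeCurrents(st, cellParams("endo", sc0))
    expect_identical(cur0[[ch]], 0)
    sc5 <- drugScalings(NULL)
    sc5[[ch]] <- 0.37
    cur5 <- computeCurrents(st, cellParams("endo", sc5))
    cur1 <- computeCurrents(st, cellParams("endo"))
    expect_equal(cur5[[ch]], 0.37 * cur1[[ch]], tolerance = 1e-12)
  }
})

test_that("Iion is the sum of its components and consistent with dV/dt", {
  cur <- computeCurrents(initState("M"), cellParams("M"), stim = -80)
  comp <- c("INa", "INaL", "Ito", "ICaL", "ICaNa", "ICaK", "IKr", "IKs",
            "IK1", "INaCa_i", "INaCa_ss", "INaK", "INab", "IKb", "IpCa",
            "ICab")
  expect_equal(cur$Iion, sum(unlist(cur[comp])), tolerance = 1e-12)
  expect_equal(cur$dVdt, -(cur$Iion + cur$Istim), tolerance = 1e-12)
})

test_that("an unstimulated cell stays at rest", {
  # from the published initial conditions: < 1e-3 mV per 0.005 ms step
  st <- initState("endo")
  st2 <- stepCell(st, cellParams("endo"), stim = 0, dt = 0.005)
  expect_lt(abs(vm(st2) - vm(st)), 1e-3)
  # drift over 10 s unstimulated stays within 1.2 mV of the initial value
  # (the published starting point relaxes ~1 mV to the model's true rest)
  prot <- pacingProtocol(cl = 10000, n_beats = 1, stim_amplitude = 0)
  tr <- paceToSteadyState("endo", protocol = prot)
  expect_lt(max(abs(tr$vm - tr$vm[1])), 1.2)
  # after relaxing, the quasi-steady rest satisfies |dV/dt| < 0.01 mV/ms
  # throughout a further unstimulated second
  tr2 <- paceToSteadyState("endo", protocol = pacingProtocol(
    cl = 1000, n_beats = 1, stim_amplitude = 0), init = tr$final_state)
  dv <- diff(tr2$vm) / diff(tr2$time)
  expect_lt(max(abs(dv)), 0.01)
})

test_that("halving dt leaves the one-beat trace and APD90 converged", {
  p1 <- pacingProtocol(n_beats = 1, dt = 0.005, save_stride_ms = 0.1)
  p2 <- pacingProtocol(n_beats = 1, dt = 0.0025, save_stride_ms = 0.1)
  t1 <- paceToSteadyState("endo", protocol = p1)
  t2 <- paceToSteadyState("endo", protocol = p2)
  v2 <- approx(t2$time, t2$vm, xout = t1$time, rule = 2)$y
  # the O(dt) phase shift of the ~300 mV/ms upstroke dominates pointwise
  # error in the first milliseconds; away from it the traces agree closely
  past_upstroke <- t1$time > 5
  expect_lt(max(abs(t1$vm - v2)[past_upstroke]), 0.5)
  expect_lt(abs(t1$apd90 - t2$apd90), 0.2)
})

test_that("Rush-Larsen and forward Euler agree within 1 mV over one beat", {
  p_rl <- pacingProtocol(n_beats = 1, method = "rl")
  p_fe <- pacingProtocol(n_beats = 1, method = "fe")
  t_rl <- paceToSteadyState("endo", protocol = p_rl)
  t_fe <- paceToSteadyState("endo", protocol = p_fe)
  expect_lt(max(abs(t_rl$vm - t_fe$vm)), 1)
})

test_that("gates stay in [0,1] during paced runs of every cell type", {
  for (ty in c("endo", "M", "epi")) {
    tr <- cached_pace(ty, n_beats = 100)
    expect_true(tr$gates_in_range, info = ty)
    expect_true(all(is.finite(tr$vm)), info = ty)
  }
})

test_that("IKr block monotonically prolongs APD90 in all cell types", {
  prot <- pacingProtocol(n_beats = 20, steady_tolerance = 0)
  for (ty in c("endo", "M", "epi")) {
    apds <- vapply(c(1, 0.8, 0.6, 0.4), function(s) {
      sc <- drugScalings(NULL)
      sc[["IKr"]] <- s
      tail(paceToSteadyState(ty, sc, prot)$apd90, 1)
    }, numeric(1))
    expect_true(all(diff(apds) > 0), info = ty)
  }
})

test_that("a NaN state is rejected, instability is reported by variable", {
  st <- initState("endo")
  st$state[["v"]] <- NaN
  expect_error(computeCurrents(st, cellParams("endo")), "non-finite")
  st2 <- initState("endo")
  st2$state[["v"]] <- 1e4 # overflow regime: the step must fail loudly
  expect_error(stepCell(st2, cellParams("endo"), 0, 0.005), "instability")
})
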