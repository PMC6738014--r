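# Pacing protocols and single-cell biomarkers (APD, TDR, EAD detection).

test_that("apd recovers the analytic value on a triangular action potential", {
  # instant rise -85 -> +35 mV, linear fall back over 300 ms
  tt <- seq(0, 500, by = 0.1)
  vv <- ifelse(tt < 1, -85,
               ifelse(tt < 301, 35 - (35 - (-85)) * (tt - 1) / 300, -85))
  tr <- synthetic_ap_trace(tt, vv)
  expect_equal(apd(tr, level = 0.9), 270, tolerance = 0.01)
  expect_equal(apd(tr, level = 0.5), 150, tolerance = 0.01)
})

test_that("APD at a lower repolarization level never exceeds APD90", {
  tr <- cached_pace("endo", n_beats = 2)
  expect_lte(apd(tr, 0.5), apd(tr, 0.9))
  expect_lte(apd(tr, 0.3), apd(tr, 0.5))
})

test_that("trace-based APD agrees with the stepper's per-beat bookkeeping", {
  for (ty in c("endo", "epi")) {
    tr <- cached_pace(ty, n_beats = 2)
    expect_equal(apd(tr, 0.9, beat_index = 2), tr$apd90[2], tolerance = 0.2,
                 info = ty)
  }
})

test_that("tdr is max minus min, permutation invariant, NA-propagating", {
  expect_equal(tdr(200, 250, 220), 50)
  expect_equal(tdr(210, 210, 210), 0)
  expect_equal(tdr(250, 200, 220), tdr(200, 250, 220))
  expect_equal(tdr(220, 200, 250), tdr(250, 220, 200))
  expect_true(is.na(tdr(200, NA, 220)))
  expect_gte(tdr(1, 5, 3), 0)
})

test_that("a drug at 0x concentration reproduces the control exactly", {
  prot <- pacingProtocol(n_beats = 3, steady_tolerance = 0)
  ctrl <- paceToSteadyState("epi", drugScalings(NULL), prot)
  zero <- paceToSteadyState("epi", drugScalings(bundled_drugs$dofetilide, 0),
                            prot)
  expect_identical(ctrl$vm, zero$vm)
  expect_identical(ctrl$apd90, zero$apd90)
})

test_that("the paced pipeline is deterministic (bit-for-bit)", {
  prot <- pacingProtocol(n_beats = 3, steady_tolerance = 0)
  sc <- drugScalings(bundled_drugs$ranolazine, 1)
  a <- paceToSteadyState("M", sc, prot)
  b <- paceToSteadyState("M", sc, prot)
  expect_identical(a$vm, b$vm)
  expect_identical(a$final_state$state, b$final_state$state)
})

test_that("steady_tolerance stops pacing early once APD90 settles", {
  prot <- pacingProtocol(n_beats = 50, steady_tolerance = 0.2)
  tr <- paceToSteadyState("endo", protocol = prot)
  expect_lt(tr$beats_run, 50)
  expect_true(tr$converged)
  n <- tr$beats_run
  expect_lt(abs(tr$apd90[n] - tr$apd90[n - 1]), 0.2)
})

test_that("EAD/failure detection classifies synthetic repolarization shapes", {
  tt <- seq(0, 999, by = 0.5)
  # clean monotone repolarization
  clean <- ifelse(tt < 1, -85, ifelse(tt < 300, 30 - 115 * (tt - 1) / 299,
                                      -85))
  expect_equal(detectEadOrFailure(synthetic_ap_trace(tt, clean)), "none")
  # EAD: a 40 ms depolarizing hump during late repolarization
  ead <- clean + ifelse(tt > 180 & tt < 220,
                        25 * sin(pi * (tt - 180) / 40)^2, 0)
  expect_equal(detectEadOrFailure(synthetic_ap_trace(tt, ead)), "EAD")
  # failure: never returns below the 90% level
  fail_v <- ifelse(tt < 1, -85, ifelse(tt < 200, 30 - 40 * (tt - 1) / 199,
                                       -10))
  expect_equal(detectEadOrFailure(synthetic_ap_trace(tt, fail_v)),
               "repolarization_failure")
})

test_that("control traces of all cell types carry no EAD or failure flag", {
  for (ty in c("endo", "M", "epi"))
    expect_equal(detectEadOrFailure(cached_pace(ty, n_beats = 2)), "none",
                 info = ty)
})

test_that("deltaApd90 is zero at 0x and negative for an IKr-sparing blocker", {
  prot <- pacingProtocol(n_beats = 3, steady_tolerance = 0)
  res <- deltaApd90(bundled_drugs$bepridil, 0, "endo", prot)
  expect_equal(res$delta_apd90, 0)
})
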