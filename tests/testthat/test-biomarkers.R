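# ECG fiducials, rate correction, VT flag.

gaussian_ecg <- function(t_qrs = 20, t_t = 250, cl = 600, dt = 1,
                         a_qrs = 1, a_t = 0.3, shift = 0) {
  tt <- seq(0, cl, by = dt)
  ss <- a_qrs * exp(-((tt - shift - t_qrs) / 6)^2) +
    a_t * exp(-((tt - shift - t_t) / 25)^2)
  structure(list(time = tt, leads = matrix(ss, 1, length(tt),
                                           dimnames = list("leadI", NULL)),
                 pacing_times = shift), class = "ecgTrace")
}

test_that("fiducials are recovered on a constructed Gaussian QRS+T signal", {
  ecg <- gaussian_ecg()
  iv <- detectIntervals(ecg, pacing_time = 0, window_ms = 600)
  expect_equal(iv$t_peak, 250, tolerance = 2)
  expect_lt(iv$qrs_onset, 20)
  expect_gt(iv$j_point, 20)
  expect_lt(iv$j_point, 60)
  expect_gt(iv$t_end, 250)
  expect_equal(iv$qt, iv$t_end - iv$qrs_onset)
  expect_equal(iv$jtpeak, iv$t_peak - iv$j_point)
  expect_gt(iv$tpeak_tend, 0)
})

test_that("a flat trace yields a measurement failure, not numbers", {
  tt <- seq(0, 500, by = 1)
  flat <- structure(list(time = tt,
                         leads = matrix(0, 1, length(tt),
                                        dimnames = list("leadI", NULL)),
                         pacing_times = 0), class = "ecgTrace")
  iv <- detectIntervals(flat, 0, 500)
  expect_true(is.na(iv$qt))
  expect_true(is.na(iv$t_peak))
})

test_that("time-shifting the trace shifts fiducials but not intervals", {
  iv0 <- detectIntervals(gaussian_ecg(shift = 0), 0, 600)
  iv50 <- detectIntervals(gaussian_ecg(shift = 50, cl = 700), 50, 600)
  expect_equal(iv50$t_peak - iv0$t_peak, 50, tolerance = 2)
  expect_equal(iv50$qt, iv0$qt, tolerance = 2)
  expect_equal(iv50$jtpeak, iv0$jtpeak, tolerance = 2)
})

test_that("rate correction matches its closed forms", {
  expect_equal(rateCorrect(400, 1000, "fridericia"), 400)
  expect_equal(rateCorrect(380, 800, "fridericia"), 380 / 0.8^(1 / 3))
  expect_equal(rateCorrect(380, 800, "bazett"), 380 / sqrt(0.8))
  expect_equal(rateCorrect(412, 740, "none"), 412)
  expect_error(rateCorrect(400, 0), "positive")
  expect_error(rateCorrect(400, 1000, "framingham"))
})

test_that("detectVt flags sustained oscillation and spares quiet traces", {
  tt <- seq(0, 2000, by = 2)
  quiet <- exp(-tt / 100) * sin(tt / 20)
  vt <- sin(tt / 40) # sustained oscillation through the whole window
  mk <- function(ss) structure(
    list(time = tt, leads = matrix(ss, 1, length(tt),
                                   dimnames = list("leadI", NULL)),
         pacing_times = 0), class = "ecgTrace")
  expect_false(detectVt(mk(quiet), control_qt = 400))
  expect_true(detectVt(mk(vt), control_qt = 400))
  expect_error(detectVt(mk(vt), control_qt = 2500), "window")
})

test_that("detectSustainedActivity sees late depolarizations only", {
  m <- buildCable(5)
  act <- matrix(-85, 5, 100)
  rec <- structure(list(time = seq_len(100) * 10, vm = act, model = m),
                   class = "tissueRecording")
  expect_false(detectSustainedActivity(rec, 500))
  act2 <- act
  act2[3, 80:85] <- 10 # ectopic depolarization at t = 800 ms
  rec2 <- rec; rec2$vm <- act2
  expect_true(detectSustainedActivity(rec2, 500))
  expect_false(detectSustainedActivity(rec2, 900))
})
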