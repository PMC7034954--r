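test_that("trial constructor enforces stimulus ordering and duration", {
  expect_error(conditioning_trial(cs_onset = 0.2, us_onset = 0.1),
               "us_onset")
  expect_error(conditioning_trial(us_onset = 0.3, trial_duration = 0.2),
               "trial_duration")
  tr <- conditioning_trial(cs_onset = 0.1, us_onset = 0.25)
  expect_equal(tr$trial_duration, 2.75)
  probe <- conditioning_trial(us_onset = NA)
  expect_true(is.na(probe$us_onset))
})

test_that("protocol constructors validate their inputs", {
  expect_error(stimulus_protocol(list()), "at least one")
  expect_error(training_protocol(0, 150), "n_pairings")
  expect_error(training_protocol(2, -5), "isi_ms")
  proto <- training_protocol(3, 150, iti_s = 5)
  expect_length(proto$trials, 3)
  expect_equal(proto$inter_trial_interval, 5)
  expect_equal(proto$trials[[1]]$us_onset - proto$trials[[1]]$cs_onset, 0.15)
})

test_that("degenerate inter-stimulus intervals are rejected", {
  p <- default_parameters()
  tr <- conditioning_trial(cs_onset = 0.1, us_onset = 0.1 + 1e-5)
  expect_error(run_trial(initial_state(p), tr, p, fast_config(dt = 1e-3)),
               "degenerate")
})

test_that("CS duration and strength descriptors never affect the dynamics", {
  p <- default_parameters()
  ref <- run_trial(initial_state(p), conditioning_trial(), p, fast_config())
  set.seed(99)
  for (i in 1:5) {
    tr <- conditioning_trial(cs_duration = runif(1, 0.001, 0.5),
                             cs_strength = runif(1, 0.1, 20))
    res <- run_trial(initial_state(p), tr, p, fast_config())
    expect_identical(res$trace, ref$trace)
  }
})

test_that("without a US the coincidence detector stays at baseline", {
  p <- default_parameters()
  probe <- conditioning_trial(us_onset = NA)
  res <- run_trial(initial_state(p), probe, p, fast_config())
  expect_true(all(res$trace$Gs == 0))
  # with Gs = 0, r1 = r1_bl: AC can never exceed its baseline equilibrium
  ac_eq <- p$r1_bl / (p$r1_bl + p$r2_bl) * p$AC_total
  expect_lt(max(res$trace$AC), ac_eq + 1e-6)
})

test_that("US before CS produces a far smaller AC response than after", {
  p <- default_parameters()
  cfg <- fast_config()
  s0 <- initial_state(p)
  fwd <- integrate_model(s0, p, cfg, duration = 2.5, cs_times = 0.3,
                         us_times = 0.45)
  rev <- integrate_model(s0, p, cfg, duration = 2.5, cs_times = 0.3,
                         us_times = 0.15)
  # calcium is still near basal for most of the reversed Gs window, so
  # the synergy engages less than with the conditioning order
  expect_lt(max(rev$trace$AC), 0.9 * max(fwd$trace$AC))
})

test_that("a second pairing releases more calcium than the first", {
  p <- default_parameters()
  res <- run_training(training_protocol(2, 150), p, fast_config())
  expect_equal(nrow(res), 2)
  expect_gt(res$Ca_integral[2], res$Ca_integral[1])
  expect_gt(res$peak_Ca[2], res$peak_Ca[1])
  expect_gt(res$PKA_end[1], 0)
})

test_that("slow species persist across trials while fast ones reset", {
  p <- default_parameters()
  cfg <- fast_config()
  res <- run_training(training_protocol(2, 150), p, cfg,
                      keep_traces = TRUE)
  traces <- attr(res, "traces")
  # PKA carried over: trial 2 starts near where trial 1 ended
  expect_gt(traces[[2]]$PKA[1], 0.5 * res$PKA_end[1])
  # pool calcium re-initialized at the second CS
  i_cs <- which(traces[[2]]$event == "CS")
  expect_equal(traces[[2]]$x[i_cs], p$x_init_on_CS)
})

test_that("training results satisfy the anticipation bookkeeping", {
  p <- default_parameters()
  res <- run_training(training_protocol(14, 150), p, fast_config(),
                      stop_at_anticipation = TRUE)
  last <- nrow(res)
  expect_true(res$anticipated[last])
  expect_false(is.na(res$rgs_activation_time[last]))
  expect_lt(res$rgs_activation_time[last], res$isi[last])
  expect_true(all(!res$anticipated[-last]))
})
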