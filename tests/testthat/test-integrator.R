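test_that("backward Euler reproduces the closed-form implicit decay update", {
  p <- decay_only_params(r4 = 2)
  s <- model_state(z = 0.05)  # below the switch threshold: pure decay
  for (dt in c(25e-6, 1e-3, 0.05)) {
    s1 <- step_state(s, p, integrator_config(dt = dt))
    expect_equal(s1[["z"]], 0.05 / (1 + 2 * dt), tolerance = 1e-9)
    others <- setdiff(names(s1), "z")
    expect_equal(as.numeric(s1[others]), as.numeric(s[others]))
  }
})

test_that("an all-zero quiescent state is a fixed point of the step", {
  p <- decay_only_params()
  s <- model_state()
  for (m in c("backward_euler", "rk4")) {
    s1 <- step_state(s, p, integrator_config(dt = 1e-3, method = m))
    expect_equal(as.numeric(s1), as.numeric(s))
  }
})

test_that("trace sampling arithmetic matches duration, step and stride", {
  p <- default_parameters()
  res <- integrate_model(initial_state(p), p,
                         integrator_config(dt = 25e-6, record_stride = 40),
                         duration = 1)
  expect_equal(nrow(res$trace), 1001)
  expect_equal(res$trace$time[2] - res$trace$time[1], 1e-3)
})

test_that("with no stimuli the read-out stays basal and inputs stay zero", {
  p <- default_parameters()
  res <- integrate_model(initial_state(p), p, fast_config(), duration = 2)
  expect_true(all(res$trace$Ca == p$B_Ca))
  expect_true(all(res$trace$Gi == 0))
  expect_true(all(res$trace$Gs == 0))
})

test_that("a CS event resets the pool calcium and is annotated", {
  p <- default_parameters()
  res <- integrate_model(initial_state(p), p, fast_config(), duration = 1,
                         cs_times = 0.2)
  i <- which(res$trace$event == "CS")
  expect_length(i, 1)
  expect_equal(res$trace$time[i], 0.2)
  expect_equal(res$trace$x[i], p$x_init_on_CS)
  expect_equal(res$trace$y[i], p$gamma / p$beta)
  expect_true(all(res$trace$x[seq_len(i - 1)] < 1))
})

test_that("events must fall on the integration grid", {
  p <- default_parameters()
  cfg <- integrator_config(dt = 1e-3)
  expect_error(integrate_model(initial_state(p), p, cfg, duration = 1,
                               cs_times = 0.10037), "grid")
  expect_error(integrate_model(initial_state(p), p, cfg, duration = 0.1005),
               "multiple")
})

test_that("backward Euler agrees with an adaptive reference integration", {
  skip_if_not_installed("deSolve")
  p <- default_parameters()
  # relaxation from a perturbed, stimulus-free state
  s0 <- model_state(x = 5, y = 1.2, AC = 0.05, cAMP = 3, PKA = 0.4,
                    PDE = 0.8, RGS = 0.4, z = 0.05)
  res <- integrate_model(s0, p, integrator_config(dt = 25e-6,
                                                  record_stride = 2000),
                         duration = 0.5)
  deriv <- function(t, yv, parms) {
    s <- model_state(x = yv[1], y = yv[2], AC = yv[3], cAMP = yv[4],
                     PKA = yv[5], PDE = yv[6], RGS = yv[7], z = yv[8])
    list(unname(model_rhs(s, p)))
  }
  ref <- deSolve::lsoda(as.numeric(s0), times = res$trace$time, func = deriv,
                        rtol = 1e-10, atol = 1e-12)
  sim <- as.matrix(res$trace[, c("x", "y", "AC", "cAMP", "PKA", "PDE",
                                 "RGS", "z")])
  # first-order global error of the implicit scheme on the stiff cAMP
  # branch dominates; two percent at 25 us comfortably brackets it
  rel <- abs(sim - ref[, -1]) / (abs(ref[, -1]) + 1e-6)
  expect_lt(max(rel), 0.02)
})

test_that("halving the step changes a paired trial by less than one percent", {
  p <- default_parameters()
  tr <- conditioning_trial(trial_duration = 1.5)
  a <- run_trial(initial_state(p), tr, p,
                 integrator_config(dt = 2e-4, record_stride = 50))$trace
  b <- run_trial(initial_state(p), tr, p,
                 integrator_config(dt = 1e-4, record_stride = 100))$trace
  for (sp in c("x", "y", "Ca", "AC", "cAMP", "PKA", "PDE", "RGS", "z")) {
    scale <- max(abs(b[[sp]]), 1e-6)
    expect_lt(max(abs(a[[sp]] - b[[sp]])) / scale, 0.01)
  }
})

test_that("identical configurations give bit-identical traces", {
  p <- default_parameters()
  tr <- conditioning_trial()
  a <- run_trial(initial_state(p), tr, p, fast_config())
  b <- run_trial(initial_state(p), tr, p, fast_config())
  expect_identical(a$trace, b$trace)
  expect_identical(as.numeric(a$state), as.numeric(b$state))
})

test_that("active species stay within their conserved totals along a trial", {
  p <- default_parameters()
  res <- run_trial(initial_state(p), conditioning_trial(), p, fast_config())
  tr <- res$trace
  expect_true(all(tr$AC >= 0 & tr$AC <= p$AC_total + 1e-9))
  expect_true(all(tr$PKA >= 0 & tr$PKA <= p$PKA_total + 1e-9))
  expect_true(all(tr$PDE >= 0 & tr$PDE <= p$PDE_total + 1e-9))
  expect_true(all(tr$RGS >= 0 & tr$RGS <= 1 + 1e-9))
  expect_true(all(tr$z >= 0 & tr$z <= 1 + 1e-9))
})

test_that("calcium bookkeeping holds along a trace: d(x+y) = gamma - beta y", {
  p <- default_parameters()
  res <- run_trial(initial_state(p),
                   conditioning_trial(trial_duration = 1.5), p,
                   integrator_config(dt = 1e-4, record_stride = 1))
  tr <- res$trace
  # away from the CS discontinuity, compare the discrete derivative of the
  # recorded total with the flux implied by y at the step end (backward
  # Euler evaluates the RHS at the end of the step)
  i <- which(tr$time > 0.11 & tr$time < 1.49)
  lhs <- (tr$x[i] + tr$y[i] - tr$x[i - 1] - tr$y[i - 1]) / 1e-4
  rhs <- p$gamma - p$beta * tr$y[i]
  expect_lt(max(abs(lhs - rhs)), 1e-5)
})
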