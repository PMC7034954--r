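test_that("CICR activation function matches its closed form", {
  expect_equal(f_cicr(1.5, h = 1.5, n = 4), 0.5)
  expect_equal(f_cicr(0, h = 2, n = 2), 0)
  expect_equal(f_cicr(3, h = 1, n = 2), 9 / 10)  # 9h^2 / (9h^2 + h^2)
  expect_error(f_cicr(-1, h = 1, n = 2), "non-negative")
  expect_error(f_cicr(1, h = 0, n = 2), "positive")
})

test_that("CICR activation is monotone and bounded for random parameters", {
  set.seed(11)
  for (i in 1:25) {
    h <- runif(1, 0.1, 5); n <- runif(1, 1, 6)
    y <- sort(runif(20, 0, 10))
    f <- f_cicr(y, h, n)
    expect_true(all(f >= 0 & f < 1))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("calcium store derivatives sum to influx minus efflux", {
  p <- default_parameters()
  expect_equal(unname(calcium_store_rhs(model_state(x = 0, y = 0), p)),
               c(0, p$gamma))
  set.seed(7)
  for (i in 1:20) {
    s <- model_state(x = runif(1, 0, 30), y = runif(1, 0, 5))
    d <- calcium_store_rhs(s, p)
    expect_equal(unname(d[1] + d[2]), p$gamma - p$beta * s[["y"]],
                 tolerance = 1e-12)
  }
})

test_that("synaptic calcium read-out switches between basal and amplified", {
  p <- default_parameters()
  s0 <- model_state(y = 2, PKA = 0.1)  # no CS yet
  expect_equal(effective_calcium(s0, p), p$B_Ca)
  s1 <- model_state(y = 2, PKA = 0, t_since_cs = 1)
  expect_equal(effective_calcium(s1, p), 2)  # factor 1 + 10*0
  s2 <- model_state(y = 2, PKA = 0.1, t_since_cs = 1)
  expect_equal(effective_calcium(s2, p), 4)  # factor 1 + 10*0.1 = 2
  s3 <- model_state(y = 2, PKA = 0.1, t_since_cs = p$ca_window + 0.5)
  expect_equal(effective_calcium(s3, p), p$B_Ca)
})

test_that("Gi transient grows, holds, and is deactivated after its cutoff", {
  p <- default_parameters()
  expect_equal(gi_input(NA, p), 0)
  expect_equal(gi_input(0, p), p$gi_a)
  expect_equal(gi_input(0.6, model_parameters(gi_b = 0)), 1)
  hold <- p$gi_a * exp(p$gi_b * p$gi_rise_window)
  expect_equal(gi_input(p$gi_rise_window, p), hold)
  expect_equal(gi_input((p$gi_rise_window + p$gi_off_time) / 2, p), hold)
  expect_equal(gi_input(2.5, p), 0)
  expect_equal(gi_input(p$gi_off_time, p), 0)
  expect_error(gi_input(-0.1, p), "non-negative")
})

test_that("Gs input is windowed and strictly decreasing in RGS", {
  p <- default_parameters()
  expect_equal(gs_input(0.05, 0, p), p$gs_amplitude)
  expect_equal(gs_input(0.05, p$K_g, p), p$gs_amplitude / 2)
  expect_equal(gs_input(0.3, 0.2, p), 0)   # outside the 200 ms window
  expect_equal(gs_input(NA, 0.2, p), 0)
  rgs <- seq(0, 1, length.out = 30)
  vals <- vapply(rgs, function(r) gs_input(0.1, r, p), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("AC activation requires the calcium-Gs coincidence", {
  p <- default_parameters()
  for (ca in c(0, 0.5, 2, 10))
    expect_equal(ac_rates(ca, Gs = 0, Gi = 0.3, p)[["r1"]], p$r1_bl)
  r <- ac_rates(p$K_ca_AC, Gs = 2, Gi = p$K_Gi, p)
  expect_equal(r[["r1"]], p$r1_bl + p$r_cag * 2 * 0.5 * 0.5)
  expect_equal(ac_rates(0, Gs = 1, Gi = 0, p)[["r2"]], p$r2_bl)
  expect_equal(ac_rates(3, Gs = 1, Gi = 0, p)[["r2"]], p$r2_bl + p$r_ca * 3)
})

test_that("AC synergy factors are monotone in their principal argument", {
  set.seed(21)
  for (i in 1:15) {
    p <- model_parameters(K_ca_AC = runif(1, 0.2, 3),
                          K_Gi = runif(1, 0.05, 2),
                          r_cag = runif(1, 1, 50))
    ca <- sort(runif(15, 0, 8))
    r1 <- vapply(ca, function(v) ac_rates(v, 1, 0.5, p)[["r1"]], numeric(1))
    expect_true(all(diff(r1) >= -1e-12))
    gi <- sort(runif(15, 0, 50))
    r1g <- vapply(gi, function(v) ac_rates(2, 1, v, p)[["r1"]], numeric(1))
    expect_true(all(diff(r1g) <= 1e-12))
  }
})

test_that("PKA pathway derivatives honor conservation closure", {
  p <- default_parameters()
  s <- model_state(AC = p$AC_total, cAMP = 1, PDE = 0.1)
  d <- pka_pathway_rhs(s, p)
  # no inactive AC left: only deactivation (r2 at basal calcium) remains
  expect_equal(d[["dAC"]], -(p$r2_bl + p$r_ca * p$B_Ca) * p$AC_total)
  s <- model_state(AC = 0, cAMP = 0, PDE = 0.1)
  expect_equal(pka_pathway_rhs(s, p)[["dcAMP"]], 0)
  expect_equal(pka_pathway_rhs(s, p)[["dPKA"]], 0)
  bad <- model_state(AC = p$AC_total, cAMP = 0)
  bad[["AC"]] <- p$AC_total * 1.5
  expect_error(pka_pathway_rhs(bad, p), "exceed")
})

test_that("RGS switch is a strict threshold on z", {
  p <- default_parameters()
  expect_equal(rgs_switch(0.2, p), 1)
  expect_equal(rgs_switch(0.05, p), 0)
  expect_equal(rgs_switch(0.1, p), 0)  # strict inequality
})

test_that("RGS kinetics follow the printed activation form", {
  p <- default_parameters()
  d <- rgs_rhs(model_state(RGS = 1, z = 0.5), Ca = 1, p)
  expect_equal(d[["dRGS"]], -p$r6)
  d0 <- rgs_rhs(model_state(RGS = 0.3, z = 0.4), Ca = 0, p)
  expect_equal(d0[["dz"]], -p$r4 * 0.4)
  dn <- rgs_rhs(model_state(RGS = 0, z = 0), Ca = 2, p)
  expect_true(all(dn >= 0))  # both start rising from the naive state
  expect_equal(dn[["dz"]],
               p$r3_bl * 4 / (p$K_ca_RGS + 2))
})

test_that("reference R kinetics and compiled core agree on derivatives", {
  p <- default_parameters()
  set.seed(42)
  for (i in 1:30) {
    s <- random_state(p)
    expect_equal(compiled_rhs(s, p), model_rhs(s, p), tolerance = 1e-12)
  }
})
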