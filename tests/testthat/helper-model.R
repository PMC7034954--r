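# Shared helpers: coarse integrator settings keep unit tests fast; the
# step-size robustness of the scheme is itself under test elsewhere.

fast_config <- function(dt = 2e-4, ...) {
  integrator_config(dt = dt, record_stride = max(1L, round(1e-3 / dt)), ...)
}

# A parameter set whose only non-zero kinetics is pure z decay (rate r4):
# with no stimuli the synaptic calcium is basal B_Ca = 0, so dz/dt = -r4 z
# and every other derivative vanishes.
decay_only_params <- function(r4 = 2) {
  model_parameters(
    k1 = 0, k2 = 0, alpha_store = 0, beta = 1, gamma = 0, B_Ca = 0,
    gi_a = 0, r1_bl = 0, r_cag = 0, r2_bl = 0, r_ca = 0,
    k8 = 0, k10 = 0, ka7 = 0, k7 = 0, k13 = 0, k14 = 0, k15 = 0,
    r5 = 0, r6 = 0, r3_bl = 0, r4 = r4,
    init_cAMP = 0, init_PDE = 0)
}

random_state <- function(params) {
  model_state(
    x = runif(1, 0, 25), y = runif(1, 0, 3),
    AC = runif(1, 0, params$AC_total),
    cAMP = runif(1, 0, 5), PKA = runif(1, 0, params$PKA_total),
    PDE = runif(1, 0, params$PDE_total),
    RGS = runif(1), z = runif(1),
    t_since_cs = sample(c(NA_real_, runif(1, 0, 2.5)), 1),
    t_since_us = sample(c(NA_real_, runif(1, 0, 0.4)), 1))
}
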