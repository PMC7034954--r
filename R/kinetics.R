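#' CICR activation function
#'
#' Hill-type fraction `f(y) = y^n / (y^n + h^n)` governing calcium-induced
#' calcium release from the store: the released flux is
#' `alpha_store * f(y) * x`.
#'
#' @param y cytosolic calcium concentration (uM), non-negative.
#' @param h half-activation concentration (uM), positive.
#' @param n Hill exponent, at least 1.
#' @return A value in `[0, 1)`, monotone non-decreasing in `y`.
#' @export
#' @examples
#' f_cicr(1.5, h = 1.5, n = 4)  # half-saturation
f_cicr <- function(y, h, n) {
  if (any(y < 0)) stop("y must be non-negative")
  if (any(h <= 0)) stop("h must be positive")
  if (any(n < 1)) stop("n must be >= 1")
  yn <- y^n
  yn / (yn + h^n)
}

#' Model state constructor
#'
#' A model state is a named numeric vector of the eight dynamical species
#' (`x`, `y`, `AC`, `cAMP`, `PKA`, `PDE`, `RGS`, `z`) with attributes
#' `t_since_cs` and `t_since_us` holding the time elapsed since the most
#' recent CS / US onset (`NA` if no stimulus has occurred).
#'
#' @param x,y pool and cytosolic calcium (uM).
#' @param AC,cAMP,PKA,PDE active pathway species (uM).
#' @param RGS,z active RGS fraction and its gating variable, in `[0, 1]`.
#' @param t_since_cs,t_since_us stimulus timers (s), `NA` for "no stimulus".
#' @return A named numeric vector of class `"pt_state"`.
#' @export
model_state <- function(x = 0, y = 0, AC = 0, cAMP = 0, PKA = 0, PDE = 0,
                        RGS = 0, z = 0, t_since_cs = NA_real_,
                        t_since_us = NA_real_) {
  s <- c(x = x, y = y, AC = AC, cAMP = cAMP, PKA = PKA, PDE = PDE,
         RGS = RGS, z = z)
  if (any(s < 0)) stop("all concentrations must be non-negative")
  if (RGS > 1 || z > 1) stop("RGS and z must lie in [0, 1]")
  attr(s, "t_since_cs") <- as.numeric(t_since_cs)
  attr(s, "t_since_us") <- as.numeric(t_since_us)
  class(s) <- "pt_state"
  s
}

#' Resting initial state
#'
#' The pre-training state: the calcium pool empty, cytosolic calcium at the
#' unstimulated fixed point `gamma / beta` of the store equations, the
#' pathway species at their configured initial concentrations (active PKA
#' and RGS/z at zero), and no stimulus timers running.
#'
#' @param params a `pt_params` object.
#' @return A `"pt_state"` vector.
#' @export
initial_state <- function(params) {
  validate_parameters(params)
  model_state(x = 0, y = params$gamma / params$beta,
              AC = params$init_AC, cAMP = params$init_cAMP, PKA = 0,
              PDE = params$init_PDE, RGS = 0, z = 0)
}

#' Calcium store kinetics
#'
#' Pool/cytosol exchange with CICR:
#' `dx/dt = k1*y - k2*x - alpha_store*f(y)*x` and
#' `dy/dt = k2*x - k1*y + alpha_store*f(y)*x + gamma - beta*y`.
#' Their sum is exactly `gamma - beta*y`: total calcium changes only
#' through influx and efflux.
#'
#' @param state a `pt_state` (only `x` and `y` are read).
#' @param params a `pt_params` object.
#' @return Named vector `c(dx, dy)` (uM/s).
#' @export
calcium_store_rhs <- function(state, params) {
  x <- state[["x"]]; y <- state[["y"]]
  cicr <- params$alpha_store * f_cicr(y, params$h, params$n) * x
  dx <- params$k1 * y - params$k2 * x - cicr
  dy <- params$k2 * x - params$k1 * y + cicr + params$gamma - params$beta * y
  c(dx = dx, dy = dy)
}

#' Synaptic calcium read-out
#'
#' Basal calcium `B_Ca` outside the post-CS window; inside the window (the
#' first `ca_window` seconds after a CS) the PKA-amplified oscillator
#' calcium `(1 + pka_gain * PKA) * y`.
#'
#' @param state a `pt_state`; the CS timer is read from its attribute.
#' @param params a `pt_params` object.
#' @return Effective synaptic calcium (uM).
#' @export
effective_calcium <- function(state, params) {
  tcs <- attr(state, "t_since_cs")
  if (is.null(tcs) || is.na(tcs) || tcs > params$ca_window)
    return(params$B_Ca)
  if (tcs < 0) stop("t_since_cs must be non-negative")
  (1 + params$pka_gain * state[["PKA"]]) * state[["y"]]
}

#' CS-driven Gi transient
#'
#' Inhibitory G-alpha input after a CS: exponential growth
#' `gi_a * exp(gi_b * t)` for `gi_rise_window` seconds, held at its
#' end-of-growth value until `gi_off_time`, then zero. Zero before any CS.
#'
#' @param t_since_cs time since CS onset (s), or `NA` for "no CS yet".
#' @param params a `pt_params` object.
#' @return Gi level (uM).
#' @export
gi_input <- function(t_since_cs, params) {
  if (is.na(t_since_cs)) return(0)
  if (t_since_cs < 0) stop("t_since_cs must be non-negative")
  if (t_since_cs >= params$gi_off_time) return(0)
  params$gi_a * exp(params$gi_b * min(t_since_cs, params$gi_rise_window))
}

#' US-driven Gs input
#'
#' Stimulatory G-alpha generated for `gs_window` seconds after a US,
#' suppressed by active RGS:
#' `gs_amplitude * K_g^3 / (K_g^3 + RGS^3)`. Zero outside the window and
#' before any US; strictly decreasing in RGS.
#'
#' @param t_since_us time since US onset (s), or `NA` for "no US yet".
#' @param RGS active RGS fraction in `[0, 1]`.
#' @param params a `pt_params` object.
#' @return Gs level (uM).
#' @export
gs_input <- function(t_since_us, RGS, params) {
  if (RGS < 0 || RGS > 1) stop("RGS must lie in [0, 1]")
  if (is.na(t_since_us) || t_since_us < 0 || t_since_us > params$gs_window)
    return(0)
  kg3 <- params$K_g^3
  params$gs_amplitude * kg3 / (kg3 + RGS^3)
}

#' Adenylyl cyclase activation and deactivation rates
#'
#' The coincidence detector:
#' `r1 = r1_bl + r_cag * Gs * Ca^3/(K_ca_AC^3 + Ca^3) * K_Gi/(K_Gi + Gi)`
#' and `r2 = r2_bl + r_ca * Ca`. Without Gs the synergy term vanishes and
#' `r1` stays at baseline: calcium alone does not activate AC.
#'
#' @param Ca effective synaptic calcium (uM).
#' @param Gs,Gi stimulatory / inhibitory G-alpha levels (uM).
#' @param params a `pt_params` object.
#' @return Named vector `c(r1, r2)` (1/s).
#' @export
ac_rates <- function(Ca, Gs, Gi, params) {
  if (Ca < 0 || Gs < 0 || Gi < 0) stop("Ca, Gs, Gi must be non-negative")
  ca3 <- Ca^3
  r1 <- params$r1_bl +
    params$r_cag * Gs * ca3 / (params$K_ca_AC^3 + ca3) *
    params$K_Gi / (params$K_Gi + Gi)
  r2 <- params$r2_bl + params$r_ca * Ca
  c(r1 = r1, r2 = r2)
}

#' cAMP-PKA pathway kinetics
#'
#' Derivatives of active AC, cAMP, active PKA and active PDE, with the
#' inactive pools closed by conservation (`inactive = total - active`):
#' \preformatted{
#' dAC/dt   = r1*(AC_total - AC) - r2*AC
#' dcAMP/dt = k8*AC - k10*PDE*cAMP/(km + cAMP)
#' dPKA/dt  = ka7*(PKA_total - PKA)*cAMP - k7*PKA
#' dPDE/dt  = k13 + k14*PKA*PDEi/(km2 + PDEi) - k15*PDE
#' }
#'
#' @param state a `pt_state`; stimulus timers are read from its attributes
#'   to evaluate the effective calcium and G-protein inputs.
#' @param params a `pt_params` object.
#' @return Named vector `c(dAC, dcAMP, dPKA, dPDE)` (uM/s).
#' @export
pka_pathway_rhs <- function(state, params) {
  AC <- state[["AC"]]; cAMP <- state[["cAMP"]]
  PKA <- state[["PKA"]]; PDE <- state[["PDE"]]
  if (AC > params$AC_total + 1e-9 || PKA > params$PKA_total + 1e-9 ||
      PDE > params$PDE_total + 1e-9)
    stop("active species exceed their conserved totals")
  Ca <- effective_calcium(state, params)
  Gi <- gi_input(attr(state, "t_since_cs"), params)
  Gs <- gs_input(attr(state, "t_since_us"), state[["RGS"]], params)
  r <- ac_rates(Ca, Gs, Gi, params)
  PDEi <- params$PDE_total - PDE
  c(dAC = r[["r1"]] * (params$AC_total - AC) - r[["r2"]] * AC,
    dcAMP = params$k8 * AC - params$k10 * PDE * cAMP / (params$km + cAMP),
    dPKA = params$ka7 * (params$PKA_total - PKA) * cAMP - params$k7 * PKA,
    dPDE = params$k13 + params$k14 * PKA * PDEi / (params$km2 + PDEi) -
      params$k15 * PDE)
}

#' RGS activation switch
#'
#' Indicator of the gating variable exceeding its threshold:
#' 1 if `z > z_threshold` (strict), else 0. This switch term drives RGS
#' activation and defines the model's timed output.
#'
#' @param z gating variable in `[0, 1]`.
#' @param params a `pt_params` object.
#' @return 0 or 1.
#' @export
rgs_switch <- function(z, params) {
  if (z < 0 || z > 1) stop("z must lie in [0, 1]")
  as.numeric(z > params$z_threshold)
}

#' RGS protein kinetics
#'
#' `dRGS/dt = (r5 + switch(z))*(1 - RGS) - r6*RGS` and
#' `dz/dt = r3*(1 - z) - r4*z` with the calcium-dependent activation rate
#' `r3 = r3_bl * Ca^2 / (K_ca_RGS + Ca)` (squared numerator over a linear
#' denominator, as specified).
#'
#' @param state a `pt_state` (only `RGS` and `z` are read).
#' @param Ca effective synaptic calcium (uM).
#' @param params a `pt_params` object.
#' @return Named vector `c(dRGS, dz)` (1/s).
#' @export
rgs_rhs <- function(state, Ca, params) {
  if (Ca < 0) stop("Ca must be non-negative")
  RGS <- state[["RGS"]]; z <- state[["z"]]
  alpha <- rgs_switch(z, params)
  r3 <- params$r3_bl * Ca^2 / (params$K_ca_RGS + Ca)
  c(dRGS = (params$r5 + alpha) * (1 - RGS) - params$r6 * RGS,
    dz = r3 * (1 - z) - params$r4 * z)
}

#' Full model right-hand side (reference implementation)
#'
#' Composes the subsystem kinetics into the complete 8-species derivative.
#' This pure-R version is the reference against which the compiled
#' integration core is cross-checked; it is not used for production
#' integration.
#'
#' @param state a `pt_state` with stimulus-timer attributes.
#' @param params a `pt_params` object.
#' @return Named numeric vector of derivatives in state order.
#' @export
model_rhs <- function(state, params) {
  ca <- calcium_store_rhs(state, params)
  Ca <- effective_calcium(state, params)
  pk <- pka_pathway_rhs(state, params)
  rg <- rgs_rhs(state, Ca, params)
  c(x = ca[["dx"]], y = ca[["dy"]], AC = pk[["dAC"]], cAMP = pk[["dcAMP"]],
    PKA = pk[["dPKA"]], PDE = pk[["dPDE"]], RGS = rg[["dRGS"]],
    z = rg[["dz"]])
}
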