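#' Model parameters
#'
#' Builds the full parameter set of the dendritic timing model: the
#' Somogyi-Stucki calcium store, the CS-driven Gi transient, the adenylyl
#' cyclase / cAMP / PKA / PDE pathway, the RGS switch, and the US-driven Gs
#' input. All concentrations are in micromolar and all times in seconds.
#'
#' The shipped default values are re-calibrated against the model's
#' documented behaviors (first-pairing RGS delay of about one second after
#' the US at a 150 ms inter-stimulus interval, roughly 100% more calcium
#' release on a second pairing, anticipation after 11 pairings at 150 ms,
#' and learning of all intervals between 150 and 1000 ms within 70
#' pairings); they are one working set among many compatible with those
#' constraints, not an authoritative transcription. See
#' [calibrate_parameters()] to re-derive them.
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @param init_preset which reading of the duplicated inactive-species
#'   initial concentrations to use: `"pde-inactive-5"` (default) starts with
#'   0.1 uM inactive AC and 5 uM inactive PDE; `"ac-active-5"` starts with
#'   0.1 uM active AC and 5 uM inactive AC. Conserved totals
#'   (`AC_total`, `PKA_total`, `PDE_total`) are derived from the preset's
#'   active + inactive initial concentrations unless overridden.
#'
#' @return A named list of class `"pt_params"`.
#'
#' @details Field summary (rates in 1/s unless noted):
#' \describe{
#'   \item{k1, k2}{cytosol-to-pool and pool-to-cytosol calcium exchange.}
#'   \item{alpha_store}{calcium-induced calcium release flux coefficient
#'     multiplying `f(y) * x`.}
#'   \item{beta, gamma}{cytosolic calcium removal rate and constant influx
#'     (uM/s).}
#'   \item{h, n}{half-activation concentration (uM) and Hill exponent of the
#'     CICR activation function `f(y)`.}
#'   \item{B_Ca}{basal synaptic calcium (uM), read out when no CS window is
#'     active.}
#'   \item{pka_gain}{dimensionless PKA multiplier in the release read-out
#'     `(1 + pka_gain * PKA) * y`.}
#'   \item{x_init_on_CS, ca_window}{pool calcium set-point at CS arrival
#'     (uM) and duration (s) of the amplified read-out window.}
#'   \item{gi_a, gi_b, gi_rise_window, gi_off_time}{amplitude (uM),
#'     exponential growth rate, growth duration, and cutoff time of the
#'     CS-driven Gi transient.}
#'   \item{r1_bl, r_cag, K_ca_AC, K_Gi}{baseline AC activation rate, synergy
#'     gain, calcium half-activation of the cubic Hill term (uM), and Gi
#'     half-inhibition constant (uM).}
#'   \item{r2_bl, r_ca}{baseline and calcium-proportional AC deactivation.}
#'   \item{k8, k10, km}{cAMP synthesis rate per active AC, PDE hydrolysis
#'     Vmax factor, and hydrolysis Michaelis constant (uM).}
#'   \item{ka7, k7}{PKA activation (per uM cAMP) and deactivation rates.}
#'   \item{k13, k14, km2, k15}{PDE basal activation (uM/s), PKA-dependent
#'     activation Vmax factor, its Michaelis constant (uM), and PDE
#'     deactivation rate.}
#'   \item{r5, r6}{RGS baseline activation and deactivation rates.}
#'   \item{z_threshold}{switch level of the gating variable z.}
#'   \item{r3_bl, K_ca_RGS, r4}{z activation scale, calcium constant (uM) in
#'     the activation rate `r3 = r3_bl * Ca^2 / (K_ca_RGS + Ca)`, and z decay
#'     rate.}
#'   \item{K_g, gs_amplitude, gs_window}{RGS half-suppression constant (uM),
#'     scale (uM), and post-US generation window (s) of the Gs input.}
#'   \item{AC_total, PKA_total, PDE_total}{conserved active + inactive
#'     totals (uM).}
#'   \item{init_AC, init_ACi, init_cAMP, init_PKAi, init_PDE, init_PDEi}{
#'     initial concentrations (uM); active PKA starts at zero.}
#' }
#' @export
#' @examples
#' p <- model_parameters()
#' p$z_threshold
#' model_parameters(r_cag = 30)$r_cag
model_parameters <- function(..., init_preset = c("pde-inactive-5",
                                                  "ac-active-5")) {
  init_preset <- match.arg(init_preset)
  p <- .default_param_values()

  if (init_preset == "ac-active-5") {
    p$init_AC <- 0.1
    p$init_ACi <- 5
    p$init_PDE <- 0.1
    p$init_PDEi <- 0
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  # Conserved totals default to active + inactive initial concentrations.
  if (!"AC_total" %in% names(dots) || is.na(p$AC_total))
    p$AC_total <- p$init_AC + p$init_ACi
  if (!"PKA_total" %in% names(dots) || is.na(p$PKA_total))
    p$PKA_total <- p$init_PKAi  # active PKA starts at zero
  if (!"PDE_total" %in% names(dots) || is.na(p$PDE_total))
    p$PDE_total <- p$init_PDE + p$init_PDEi
  p <- lapply(p, as.numeric)
  class(p) <- "pt_params"
  validate_parameters(p)
  p
}

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

# Shipped defaults (re-calibrated; see calibration module).
.default_param_values <- function() {
  list(
    # calcium store: slow-onset transient rising over ~0.2 s and peaking
    # around 1 s (the onset lag is what makes very short intervals
    # unlearnable)
    k1 = 0.05, k2 = 0.29, alpha_store = 0.05, beta = 5.5, gamma = 0.275,
    h = 2, n = 4, B_Ca = 0.05,
    pka_gain = 10, x_init_on_CS = 25, ca_window = 2,
    # Gi transient: steep exponential growth makes a later US meet a far
    # more strongly inhibited cyclase
    gi_a = 1, gi_b = 7.5, gi_rise_window = 1.2, gi_off_time = 2,
    # adenylyl cyclase
    r1_bl = 0.002, r_cag = 25, K_ca_AC = 0.25, K_Gi = 0.4,
    r2_bl = 0.8, r_ca = 0.1,
    # cAMP / PKA / PDE
    k8 = 380, k10 = 143, km = 0.5, ka7 = 0.03, k7 = 1e-5,
    k13 = 0.05, k14 = 0.02, km2 = 5, k15 = 0.5,
    # RGS
    r5 = 0.005, r6 = 0.9, z_threshold = 0.1,
    r3_bl = 1.06, K_ca_RGS = 25, r4 = 0.4,
    # Gs input
    K_g = 0.26, gs_amplitude = 5, gs_window = 0.2,
    # conserved totals (derived from the initial concentrations)
    AC_total = NA, PKA_total = NA, PDE_total = NA,
    # initial concentrations (uM)
    init_AC = 0, init_ACi = 0.1, init_cAMP = 1.9, init_PKAi = 1,
    init_PDE = 0.1, init_PDEi = 5
  )
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model: non-negative rates,
#' concentrations and Hill constants, Hill exponent at least 1, switch
#' threshold inside (0, 1), and stimulus-window ordering
#' (`ca_window >= gi_rise_window`).
#'
#' @param p a `pt_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_parameters <- function(p) {
  if (!inherits(p, "pt_params")) stop("p must be a 'pt_params' object")
  vals <- unlist(p)
  if (anyNA(vals)) stop("parameters contain NA")
  if (any(vals < 0)) {
    bad <- names(vals)[vals < 0]
    stop("negative parameter(s): ", paste(bad, collapse = ", "))
  }
  if (p$n < 1) stop("Hill exponent n must be >= 1")
  if (p$h <= 0) stop("h must be positive")
  if (p$z_threshold <= 0 || p$z_threshold >= 1)
    stop("z_threshold must lie in (0, 1)")
  if (p$ca_window < p$gi_rise_window)
    stop("ca_window must be >= gi_rise_window")
  if (p$beta <= 0) stop("beta must be positive")
  invisible(p)
}

# Canonical numeric vector handed to the compiled core; order must match
# the Par enum in src/model.cpp.
.param_order <- c(
  "k1", "k2", "alpha_store", "beta", "gamma", "h", "n", "B_Ca",
  "pka_gain", "x_init_on_CS", "ca_window",
  "gi_a", "gi_b", "gi_rise_window", "gi_off_time",
  "r1_bl", "r_cag", "K_ca_AC", "K_Gi", "r2_bl", "r_ca",
  "k8", "k10", "km", "ka7", "k7",
  "k13", "k14", "km2", "k15",
  "r5", "r6", "z_threshold", "r3_bl", "K_ca_RGS", "r4",
  "K_g", "gs_amplitude", "gs_window",
  "AC_total", "PKA_total", "PDE_total"
)

param_vector <- function(p) {
  validate_parameters(p)
  unlist(p[.param_order])
}

#' Read or write a parameter file
#'
#' Parameter files are flat key-value YAML whose keys match the
#' [model_parameters()] field names exactly; unknown keys are an error.
#'
#' @param path file path.
#' @param p a `pt_params` object.
#' @return `read_parameters()` returns a `pt_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw)))
    stop("parameter file must be a flat key-value mapping: ", path)
  known <- names(.default_param_values())
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(model_parameters, raw)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  yaml::write_yaml(lapply(unclass(p), as.numeric), path)
  invisible(path)
}

#' @export
print.pt_params <- function(x, ...) {
  cat("Dendritic timing model parameters (uM, s)\n")
  v <- unlist(x)
  print(round(v, 6))
  invisible(x)
}

# Short stable hash of a parameter set, for trace metadata.
param_hash <- function(p) {
  s <- paste(names(param_vector(p)), sprintf("%.12g", param_vector(p)),
             collapse = ";")
  # Fold a simple polynomial hash into hex; stable across platforms.
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
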