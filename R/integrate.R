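#' Integrator configuration
#'
#' Fixed-step integration settings. The production scheme is backward Euler
#' at 25 microsecond steps; an explicit classical Runge-Kutta method of
#' order 4 on the same right-hand side is available as a high-accuracy
#' cross-validation oracle. There is no adaptive step-size control.
#'
#' @param dt step size in seconds (default `25e-6`).
#' @param method `"backward_euler"` (default) or `"rk4"`.
#' @param newton_tol relative residual tolerance of the implicit solve.
#' @param newton_max_iter iteration cap of the implicit solve.
#' @param record_stride number of steps between recorded samples (default
#'   40, i.e. 1 ms at the default step).
#' @return A list of class `"pt_config"`.
#' @export
integrator_config <- function(dt = 25e-6,
                              method = c("backward_euler", "rk4"),
                              newton_tol = 1e-10, newton_max_iter = 50,
                              record_stride = 40) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  if (newton_tol <= 0) stop("newton_tol must be positive")
  if (newton_max_iter < 1) stop("newton_max_iter must be >= 1")
  if (record_stride < 1) stop("record_stride must be >= 1")
  structure(list(dt = dt, method = method, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 record_stride = as.integer(record_stride)),
            class = "pt_config")
}

.method_code <- function(config) {
  switch(config$method, backward_euler = 0L, rk4 = 1L,
         stop("unknown method: ", config$method))
}

#' Advance a state by one integration step
#'
#' A single fixed step of the configured scheme, with stimulus inputs
#' evaluated at the step's end time. Mainly useful for testing; production
#' runs use [integrate_model()].
#'
#' @param state a `pt_state`.
#' @param params a `pt_params` object.
#' @param config a `pt_config` (only `dt`, `method` and the implicit-solve
#'   settings are used).
#' @return The advanced `pt_state` (timers advanced by `dt`).
#' @export
step_state <- function(state, params, config = integrator_config()) {
  res <- cpp_integrate(as.numeric(state), param_vector(params),
                       duration = config$dt, dt = config$dt,
                       cs_times = numeric(0), us_times = numeric(0),
                       method = .method_code(config),
                       newton_tol = config$newton_tol,
                       newton_max_iter = config$newton_max_iter,
                       record_stride = 1L,
                       t_since_cs0 = .timer(state, "t_since_cs"),
                       t_since_us0 = .timer(state, "t_since_us"),
                       t0 = 0)
  .state_from_core(res)
}

.timer <- function(state, which) {
  v <- attr(state, which)
  if (is.null(v)) NA_real_ else v
}

.state_from_core <- function(res) {
  s <- res$state
  names(s) <- c("x", "y", "AC", "cAMP", "PKA", "PDE", "RGS", "z")
  attr(s, "t_since_cs") <- res$t_since_cs
  attr(s, "t_since_us") <- res$t_since_us
  class(s) <- "pt_state"
  s
}

#' Integrate the model over a stimulus schedule
#'
#' Advances the state for `duration` seconds, injecting CS events (pool
#' calcium reset to `x_init_on_CS`, cytosolic calcium to its resting value,
#' CS timer restarted) and US events (US timer restarted) exactly at their
#' scheduled times, which must fall on the step grid. Samples are recorded
#' every `record_stride` steps.
#'
#' @param state starting `pt_state`.
#' @param params a `pt_params` object.
#' @param config a `pt_config`.
#' @param duration simulated time (s); must be a multiple of `config$dt`.
#' @param cs_times,us_times event times (s) relative to the segment start.
#' @param t0 absolute time of the segment start (for trace time stamps).
#' @return A list with `trace` (a `pt_trace` data frame with columns
#'   `time`, the eleven species/input series `x, y, Ca, Gi, Gs, AC, cAMP,
#'   PKA, PDE, RGS, z`, and `event` of `""`, `"CS"`, `"US"` or `"CS+US"`)
#'   and `state` (the final `pt_state`).
#' @export
integrate_model <- function(state, params, config = integrator_config(),
                            duration, cs_times = numeric(0),
                            us_times = numeric(0), t0 = 0) {
  if (duration <= 0) stop("duration must be positive")
  res <- cpp_integrate(as.numeric(state), param_vector(params),
                       duration = duration, dt = config$dt,
                       cs_times = sort(as.numeric(cs_times)) + t0,
                       us_times = sort(as.numeric(us_times)) + t0,
                       method = .method_code(config),
                       newton_tol = config$newton_tol,
                       newton_max_iter = config$newton_max_iter,
                       record_stride = config$record_stride,
                       t_since_cs0 = .timer(state, "t_since_cs"),
                       t_since_us0 = .timer(state, "t_since_us"),
                       t0 = t0)
  rec <- res$rec
  colnames(rec) <- c("x", "y", "Ca", "Gi", "Gs", "AC", "cAMP", "PKA",
                     "PDE", "RGS", "z")
  trace <- data.frame(time = res$time, rec,
                      event = c("", "CS", "US", "CS+US")[res$event + 1L])
  attr(trace, "params_hash") <- param_hash(params)
  attr(trace, "dt") <- config$dt
  attr(trace, "method") <- config$method
  class(trace) <- c("pt_trace", "data.frame")
  list(trace = trace, state = .state_from_core(res))
}

#' Compiled right-hand side (internal cross-check hook)
#'
#' Evaluates the compiled core's derivative at a given state and stimulus
#' timers; used to verify that the integration core and the reference R
#' kinetics agree.
#'
#' @param state a `pt_state`.
#' @param params a `pt_params` object.
#' @return Named derivative vector in state order.
#' @export
compiled_rhs <- function(state, params) {
  out <- cpp_model_rhs(as.numeric(state), .timer(state, "t_since_cs"),
                       .timer(state, "t_since_us"), param_vector(params))
  names(out) <- c("x", "y", "AC", "cAMP", "PKA", "PDE", "RGS", "z")
  out
}
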