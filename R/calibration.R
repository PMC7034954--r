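#' Calibration specification
#'
#' Describes a constraint-guided search for a working parameter set: which
#' parameters are free (with positive finite bounds), which behavioral
#' constraints score a candidate, and the search budget. Used when no
#' authoritative parameter table is available; the shipped defaults were
#' produced this way.
#'
#' @param free_parameters named list of `c(lower, upper)` bounds; names
#'   must be [model_parameters()] fields.
#' @param constraints list of constraints as built by
#'   [default_constraints()]; each is a list with `name`, `weight` and a
#'   function `fn(params, ctrl)` returning a non-negative violation
#'   (0 = satisfied).
#' @param budget maximum number of score evaluations (>= 1).
#' @param seed RNG seed for the Latin-hypercube sampler.
#' @param dt integration step used during scoring (s). Coarser than the
#'   production 25 us step; the scheme's step-size robustness keeps the
#'   scored observables within a percent of the fine-step values.
#' @param isis_ms interval grid used by the sweep constraints.
#' @param max_pairings training cap used by the learning constraints.
#' @return A list of class `"pt_calspec"`.
#' @export
calibration_spec <- function(free_parameters,
                             constraints = default_constraints(),
                             budget = 100, seed = 1, dt = 1e-4,
                             isis_ms = c(150, 300, 500, 750, 1000),
                             max_pairings = 70) {
  if (!length(free_parameters) || is.null(names(free_parameters)))
    stop("free_parameters must be a named list of bounds")
  known <- names(.default_param_values())
  unknown <- setdiff(names(free_parameters), known)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in names(free_parameters)) {
    b <- free_parameters[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
      stop("bounds for ", nm, " must be finite, positive and increasing")
  }
  if (budget < 1) stop("budget must be >= 1")
  stride <- max(1L, as.integer(round(1e-3 / dt)))
  structure(list(free_parameters = free_parameters,
                 constraints = constraints, budget = as.integer(budget),
                 seed = as.integer(seed), dt = dt, isis_ms = isis_ms,
                 max_pairings = as.integer(max_pairings),
                 config = integrator_config(dt = dt,
                                            record_stride = stride)),
            class = "pt_calspec")
}

#' Default calibration constraints
#'
#' The paper-level behaviors a working parameter set must reproduce:
#' \itemize{
#'   \item resting stationarity: 30 s without stimulation leaves PKA low
#'     and the RGS switch disengaged;
#'   \item no timed response of the naive model to a CS alone;
#'   \item first-pairing RGS activation about 1 s after the US at a 150 ms
#'     inter-stimulus interval;
#'   \item about 100% more calcium release on the second of two pairings;
#'   \item anticipation at 150 ms after 11 pairings;
#'   \item every interval on the grid learned within the training cap,
#'     with pairings-to-learn non-decreasing in the interval and the final
#'     activation latency inside (ISI/2, ISI).
#' }
#'
#' @param sweep include the (expensive) interval-sweep constraint.
#' @return A list of constraint definitions for [calibration_spec()].
#' @export
default_constraints <- function(sweep = TRUE) {
  cons <- list(
    list(name = "resting_stationarity", weight = 4, fn = .con_resting),
    list(name = "cs_alone_silent", weight = 4, fn = .con_cs_alone),
    list(name = "first_pairing_delay_1s", weight = 2, fn = .con_first_delay),
    list(name = "second_pairing_amplification_100", weight = 2,
         fn = .con_amplification),
    list(name = "pairings_to_learn_150ms_11", weight = 3, fn = .con_p150)
  )
  if (sweep)
    cons <- c(cons, list(list(name = "isi_sweep_learnable_monotone",
                              weight = 3, fn = .con_sweep)))
  cons
}

.con_resting <- function(params, ctrl) {
  res <- integrate_model(initial_state(params), params, ctrl$config,
                         duration = 30)
  z_max <- max(res$trace$z)
  pka_end <- res$trace$PKA[nrow(res$trace)]
  max(0, (z_max - 0.9 * params$z_threshold) / params$z_threshold) +
    max(0, (pka_end - 0.05) / 0.05)
}

.con_cs_alone <- function(params, ctrl) {
  probe <- conditioning_trial(us_onset = NA)
  res <- run_trial(initial_state(params), probe, params, ctrl$config)
  act <- rgs_activation_time(res$trace, params)
  if (is.na(act)) 0 else 1 + max(res$trace$z) - params$z_threshold
}

# First-pairing RGS activation about 1 s after the US (+/- 0.25 s band).
.con_first_delay <- function(params, ctrl) {
  proto <- training_protocol(1, 150)
  res <- run_training(proto, params, ctrl$config)
  act <- res$rgs_activation_time[1]
  if (is.na(act)) return(2)
  max(0, abs(act - (0.15 + 1.0)) - 0.25) / 0.5
}

# Second-pairing calcium release about 100% above the first (+/- 20 points).
.con_amplification <- function(params, ctrl) {
  proto <- training_protocol(2, 150)
  res <- run_training(proto, params, ctrl$config)
  max(0, abs(calcium_amplification(res) - 100) - 20) / 25
}

.con_p150 <- function(params, ctrl) {
  n <- pairings_to_learn(150, params, ctrl$config,
                         max_pairings = ctrl$max_pairings)
  if (is.na(n)) return(4)
  abs(n - 11) / 2
}

.con_sweep <- function(params, ctrl) {
  sw <- isi_sweep(ctrl$isis_ms, params, ctrl$config,
                  max_pairings = ctrl$max_pairings)
  v <- sum(is.na(sw$pairings_to_learn))
  p <- sw$pairings_to_learn
  if (sum(!is.na(p)) >= 2)
    v <- v + sum(diff(p[!is.na(p)]) < 0)
  isi_s <- sw$isi_ms / 1000
  act <- sw$final_activation_time
  ok <- !is.na(act)
  v + sum(pmax(0, (0.5 * isi_s[ok] - act[ok]) / (0.5 * isi_s[ok]))) +
    sum(pmax(0, (act[ok] - isi_s[ok]) / (0.5 * isi_s[ok]))) +
    sum(!ok)
}

#' Score a parameter set against calibration constraints
#'
#' Runs every constraint protocol and returns the weighted sum of
#' violations; 0 if and only if all constraints are satisfied. Simulation
#' failures contribute a large finite penalty instead of raising.
#'
#' @param params a `pt_params` object.
#' @param spec a `pt_calspec`.
#' @return The penalty, with a per-constraint data frame attached as
#'   attribute `"report"`.
#' @export
score_parameters <- function(params, spec) {
  ctrl <- list(config = spec$config, max_pairings = spec$max_pairings,
               isis_ms = spec$isis_ms)
  rows <- lapply(spec$constraints, function(con) {
    v <- tryCatch(con$fn(params, ctrl), error = function(e) {
      warning("constraint '", con$name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      100
    })
    data.frame(constraint = con$name, weight = con$weight, violation = v)
  })
  report <- do.call(rbind, rows)
  penalty <- sum(report$weight * report$violation)
  attr(penalty, "report") <- report
  penalty
}

#' Calibrate model parameters
#'
#' Seeded Latin-hypercube sampling over the free-parameter bounds
#' (log-scale, since rate constants span decades) followed by local
#' coordinate refinement, minimizing [score_parameters()]. Deterministic
#' given the spec's seed; if the starting point already satisfies every
#' constraint it is returned unchanged.
#'
#' @param spec a `pt_calspec`.
#' @param base_params starting parameter set; defaults to the shipped
#'   defaults.
#' @return A list with `params` (best set), `penalty`, `report`
#'   (per-constraint violations at the optimum), `converged`
#'   (`penalty == 0`), and `history` (best penalty after each evaluation).
#' @export
calibrate_parameters <- function(spec, base_params = default_parameters()) {
  if (!inherits(spec, "pt_calspec")) stop("spec must be a pt_calspec")
  free <- names(spec$free_parameters)
  lo <- log(vapply(spec$free_parameters, `[`, numeric(1), 1))
  hi <- log(vapply(spec$free_parameters, `[`, numeric(1), 2))

  apply_point <- function(logvals) {
    ov <- as.list(exp(logvals))
    names(ov) <- free
    do.call(model_parameters, ov_merge(base_params, ov))
  }

  evals <- 0L
  history <- numeric(0)
  best <- list(penalty = Inf, report = NULL, logvals = NULL)
  try_point <- function(logvals) {
    if (evals >= spec$budget) return(FALSE)
    evals <<- evals + 1L
    pen <- suppressWarnings(score_parameters(apply_point(logvals), spec))
    improved <- as.numeric(pen) < as.numeric(best$penalty)
    if (improved)
      best <<- list(penalty = as.numeric(pen),
                    report = attr(pen, "report"), logvals = logvals)
    history <<- c(history, as.numeric(best$penalty))
    improved
  }

  # Starting point first: idempotence at feasible points.
  start <- log(vapply(free, function(nm) base_params[[nm]], numeric(1)))
  start <- pmin(pmax(start, lo), hi)
  try_point(start)
  if (best$penalty == 0) {
    return(list(params = apply_point(best$logvals), penalty = 0,
                report = best$report, converged = TRUE, history = history))
  }

  # Latin-hypercube seeding (log-scale).
  n_lhs <- min(max(0L, spec$budget - evals - length(free) * 4L),
               max(4L, spec$budget %/% 4L))
  if (n_lhs > 0) {
    u <- withr_seed(spec$seed, function() {
      if (requireNamespace("lhs", quietly = TRUE))
        lhs::randomLHS(n_lhs, length(free))
      else
        matrix(stats::runif(n_lhs * length(free)), nrow = n_lhs)
    })
    for (i in seq_len(n_lhs)) {
      if (best$penalty == 0) break
      try_point(lo + u[i, ] * (hi - lo))
    }
  }

  # Coordinate refinement around the incumbent.
  steps <- log(c(0.8, 1.25))
  repeat {
    if (evals >= spec$budget || best$penalty == 0) break
    improved_any <- FALSE
    for (j in seq_along(free)) {
      for (st in steps) {
        if (evals >= spec$budget || best$penalty == 0) break
        cand <- best$logvals
        cand[j] <- min(max(cand[j] + st, lo[j]), hi[j])
        if (cand[j] == best$logvals[j]) next
        if (try_point(cand)) improved_any <- TRUE
      }
    }
    if (!improved_any) break
  }

  if (!is.finite(best$penalty))
    return(list(params = NULL, penalty = Inf, report = NULL,
                converged = FALSE, history = history))
  list(params = apply_point(best$logvals), penalty = best$penalty,
       report = best$report, converged = best$penalty == 0,
       history = history)
}

# Evaluate fn() under a temporary RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Merge override list into a params object, returning the argument list for
# model_parameters().
ov_merge <- function(base, overrides) {
  vals <- unclass(base)
  vals[names(overrides)] <- overrides
  vals
}
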