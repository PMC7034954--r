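#' Conditioning trial
#'
#' One CS-US pairing (or CS-alone probe when `us_onset` is `NA`). The CS
#' acts on the model only through its onset time: `cs_duration` and
#' `cs_strength` are descriptors of the parallel-fiber drive carried along
#' to document the decoupling property — they have, by construction, no
#' effect on the dynamics.
#'
#' @param cs_onset CS onset time within the trial (s).
#' @param us_onset US onset time within the trial (s), or `NA` for a
#'   CS-alone probe; must exceed `cs_onset` when present.
#' @param cs_duration,cs_strength inert stimulus descriptors.
#' @param trial_duration total simulated trial time (s); defaults to
#'   `max(onsets) + 2.5` so all stimulus windows complete within the trial.
#' @return A list of class `"pt_trial"`.
#' @export
conditioning_trial <- function(cs_onset = 0.1, us_onset = cs_onset + 0.15,
                               cs_duration = 0.02, cs_strength = 1,
                               trial_duration = NULL) {
  if (cs_onset < 0) stop("cs_onset must be non-negative")
  if (!is.na(us_onset) && us_onset <= cs_onset)
    stop("us_onset must exceed cs_onset")
  if (is.null(trial_duration))
    trial_duration <- max(cs_onset, us_onset, na.rm = TRUE) + 2.5
  if (trial_duration <= max(cs_onset, us_onset, na.rm = TRUE))
    stop("trial_duration must exceed the last stimulus onset")
  structure(list(cs_onset = cs_onset, us_onset = us_onset,
                 cs_duration = cs_duration, cs_strength = cs_strength,
                 trial_duration = trial_duration),
            class = "pt_trial")
}

#' Stimulus protocol
#'
#' An ordered series of trials with an inter-trial relaxation interval.
#' Between trials the slow species (AC, cAMP, PKA, PDE, RGS, z) persist and
#' relax without stimulation; the fast stimulus-driven quantities (pool and
#' cytosolic calcium, G-protein inputs, stimulus timers) are re-initialized
#' at each CS.
#'
#' @param trials a list of [conditioning_trial()] objects (at least one).
#' @param inter_trial_interval unstimulated relaxation time between trials
#'   (s, default 10).
#' @return A list of class `"pt_protocol"`.
#' @export
stimulus_protocol <- function(trials, inter_trial_interval = 10) {
  if (inherits(trials, "pt_trial")) trials <- list(trials)
  if (!length(trials)) stop("protocol needs at least one trial")
  if (!all(vapply(trials, inherits, logical(1), "pt_trial")))
    stop("trials must be conditioning_trial objects")
  if (inter_trial_interval < 0)
    stop("inter_trial_interval must be non-negative")
  structure(list(trials = trials,
                 inter_trial_interval = inter_trial_interval,
                 carry_over = c("AC", "cAMP", "PKA", "PDE", "RGS", "z")),
            class = "pt_protocol")
}

#' Repeated-pairing training protocol
#'
#' Convenience constructor for `n_pairings` identical CS-US trials at one
#' inter-stimulus interval.
#'
#' @param n_pairings number of CS-US pairings (>= 1).
#' @param isi_ms inter-stimulus interval, CS onset to US onset, in
#'   milliseconds.
#' @param iti_s inter-trial interval (s).
#' @param cs_onset CS onset within each trial (s).
#' @return A `"pt_protocol"`.
#' @export
training_protocol <- function(n_pairings, isi_ms, iti_s = 10,
                              cs_onset = 0.1) {
  if (n_pairings < 1) stop("n_pairings must be >= 1")
  if (isi_ms <= 0) stop("isi_ms must be positive")
  tr <- conditioning_trial(cs_onset = cs_onset,
                           us_onset = cs_onset + isi_ms / 1000)
  stimulus_protocol(rep(list(tr), n_pairings), inter_trial_interval = iti_s)
}

#' Run a single trial
#'
#' Integrates one trial from the given state: at `cs_onset` the calcium
#' pool is set to `x_init_on_CS`, the synaptic-calcium window and Gi
#' transient start; at `us_onset` the Gs window opens with its amplitude
#' gated by the instantaneous RGS level. The returned trace is identical
#' for any `cs_duration`/`cs_strength`.
#'
#' @param state starting `pt_state` (stimulus timers are cleared at trial
#'   start).
#' @param trial a `pt_trial`.
#' @param params a `pt_params` object.
#' @param config a `pt_config`.
#' @return A list with `trace` (`pt_trace`) and `state` (end-of-trial
#'   `pt_state`).
#' @export
run_trial <- function(state, trial, params, config = integrator_config()) {
  if (!inherits(trial, "pt_trial")) stop("trial must be a pt_trial")
  if (!is.na(trial$us_onset) &&
      trial$us_onset - trial$cs_onset < config$dt)
    stop("degenerate ISI: us_onset falls inside the first integration ",
         "step after cs_onset")
  attr(state, "t_since_cs") <- NA_real_
  attr(state, "t_since_us") <- NA_real_
  us <- if (is.na(trial$us_onset)) numeric(0) else trial$us_onset
  integrate_model(state, params, config, duration = trial$trial_duration,
                  cs_times = trial$cs_onset, us_times = us)
}

#' Run a training protocol
#'
#' Runs the protocol's trials in sequence with slow-species carry-over and
#' unstimulated inter-trial relaxation, collecting per-trial learning
#' summaries (see [rgs_activation_time()] and [calcium_amplification()]).
#'
#' @param protocol a `pt_protocol`.
#' @param params a `pt_params` object.
#' @param config a `pt_config`.
#' @param state starting state; defaults to [initial_state()].
#' @param keep_traces if `TRUE`, the full per-trial traces are attached.
#' @param stop_at_anticipation if `TRUE`, training stops after the first
#'   trial whose RGS activation precedes the US.
#' @return A data frame of class `"pt_training"` with one row per executed
#'   trial: `trial`, `isi` (s, `NA` for CS-alone), `rgs_activation_time`
#'   (s relative to CS onset, `NA` if the switch never engaged),
#'   `anticipated`, `peak_Ca`, `Ca_integral` (uM s over the post-CS
#'   read-out window), and end-of-trial `AC`, `PKA`, `RGS`. The final model
#'   state is attached as attribute `"state"`; traces, when kept, as
#'   attribute `"traces"`.
#' @export
run_training <- function(protocol, params, config = integrator_config(),
                         state = initial_state(params),
                         keep_traces = FALSE,
                         stop_at_anticipation = FALSE) {
  if (!inherits(protocol, "pt_protocol"))
    stop("protocol must be a pt_protocol")
  n <- length(protocol$trials)
  rows <- vector("list", n)
  traces <- if (keep_traces) vector("list", n) else NULL

  for (i in seq_len(n)) {
    trial <- protocol$trials[[i]]
    res <- run_trial(state, trial, params, config)
    state <- res$state
    summ <- .trial_summary(res$trace, trial, params)
    rows[[i]] <- cbind(data.frame(trial = i), summ)
    if (keep_traces) traces[[i]] <- res$trace

    done <- stop_at_anticipation && isTRUE(summ$anticipated)
    if (!done && protocol$inter_trial_interval > 0) {
      relax <- integrate_model(state, params, config,
                               duration = protocol$inter_trial_interval)
      state <- relax$state
    }
    if (done) { rows <- rows[seq_len(i)]; if (keep_traces) traces <- traces[seq_len(i)]; break }
  }

  out <- do.call(rbind, rows)
  attr(out, "state") <- state
  if (keep_traces) attr(out, "traces") <- traces
  class(out) <- c("pt_training", "data.frame")
  out
}

.trial_summary <- function(trace, trial, params) {
  act <- rgs_activation_time(trace, params)
  isi <- if (is.na(trial$us_onset)) NA_real_ else
    trial$us_onset - trial$cs_onset
  win <- trace$time >= trial$cs_onset &
    trace$time <= trial$cs_onset + params$ca_window
  ca <- trace$Ca[win]
  tt <- trace$time[win]
  integral <- sum(diff(tt) * (head(ca, -1) + tail(ca, -1)) / 2)
  last <- nrow(trace)
  data.frame(isi = isi,
             rgs_activation_time = act,
             anticipated = !is.na(act) && !is.na(isi) && act < isi,
             peak_Ca = max(ca),
             Ca_integral = integral,
             AC_end = trace$AC[last], PKA_end = trace$PKA[last],
             RGS_end = trace$RGS[last])
}
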