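#' RGS activation time
#'
#' First post-CS time at which the model's timed output engages. The
#' default criterion is the model's own switch — the gating variable `z`
#' exceeding `z_threshold` — because that is the quantity the negative
#' feedback actually uses. An alternative criterion, RGS crossing a fixed
#' fraction of its within-trial maximum, is provided for figure-style
#' read-outs.
#'
#' @param trace a `pt_trace` containing a CS event.
#' @param params a `pt_params` object (supplies `z_threshold`).
#' @param criterion `"switch"` (default) or `"rgs-fraction"`.
#' @param fraction fraction of the trial's RGS maximum for the
#'   `"rgs-fraction"` criterion.
#' @return Activation time in seconds relative to CS onset, or `NA` if the
#'   criterion is never met.
#' @export
rgs_activation_time <- function(trace, params,
                                criterion = c("switch", "rgs-fraction"),
                                fraction = 0.5) {
  criterion <- match.arg(criterion)
  cs_rows <- grepl("CS", trace$event)
  if (!any(cs_rows)) stop("trace contains no CS event")
  t_cs <- trace$time[which(cs_rows)[1]]
  post <- trace$time >= t_cs
  tt <- trace$time[post]
  hit <- if (criterion == "switch") {
    trace$z[post] > params$z_threshold
  } else {
    peak <- max(trace$RGS[post])
    if (peak <= 0) return(NA_real_)
    trace$RGS[post] >= fraction * peak
  }
  if (!any(hit)) return(NA_real_)
  tt[which(hit)[1]] - t_cs
}

#' Calcium-release amplification
#'
#' Percent increase of calcium release between the first two trials of a
#' training result, using the integral of the synaptic-calcium read-out
#' over the post-CS window as the release metric (the peak value is
#' reported alongside in the training table).
#'
#' @param result a `pt_training` with at least two trials.
#' @return Percent increase `100 * (Ca2 - Ca1) / Ca1`.
#' @export
calcium_amplification <- function(result) {
  if (!inherits(result, "pt_training") || nrow(result) < 2)
    stop("result must be a pt_training with at least two trials")
  m1 <- result$Ca_integral[1]
  m2 <- result$Ca_integral[2]
  if (m1 <= 0) stop("first-trial calcium release is zero; amplification undefined")
  100 * (m2 - m1) / m1
}

#' Pairings needed to learn an interval
#'
#' Trains the naive model at one inter-stimulus interval and returns the
#' first pairing on which RGS activation precedes the US, i.e. on which the
#' timed response anticipates the climbing-fiber input.
#'
#' @param isi_ms inter-stimulus interval in milliseconds.
#' @param params a `pt_params` object.
#' @param config a `pt_config`.
#' @param max_pairings cap on the number of pairings (default 70).
#' @param iti_s inter-trial interval (s).
#' @return The smallest anticipating trial index, or `NA` if the interval
#'   is not learned within `max_pairings`.
#' @export
pairings_to_learn <- function(isi_ms, params = default_parameters(),
                              config = integrator_config(),
                              max_pairings = 70, iti_s = 10) {
  if (isi_ms <= 0) stop("isi_ms must be positive")
  if (max_pairings < 1) stop("max_pairings must be >= 1")
  proto <- training_protocol(max_pairings, isi_ms, iti_s = iti_s)
  res <- run_training(proto, params, config, stop_at_anticipation = TRUE)
  if (isTRUE(res$anticipated[nrow(res)])) nrow(res) else NA_integer_
}

#' Learning curve across inter-stimulus intervals
#'
#' Trains an independent naive model at each interval and tabulates the
#' pairings needed to anticipate plus the activation latency after full
#' training.
#'
#' @param isis_ms inter-stimulus intervals in milliseconds (non-empty).
#' @param params a `pt_params` object.
#' @param config a `pt_config`.
#' @param max_pairings pairings per interval (default 70); also the cap for
#'   `pairings_to_learn`.
#' @param iti_s inter-trial interval (s).
#' @return A data frame with one row per interval: `isi_ms`,
#'   `pairings_to_learn` (`NA` if not learned), `final_activation_time` (s
#'   relative to CS after `max_pairings` pairings) and `final_anticipated`.
#' @export
isi_sweep <- function(isis_ms, params = default_parameters(),
                      config = integrator_config(), max_pairings = 70,
                      iti_s = 10) {
  if (!length(isis_ms)) stop("isis_ms must be non-empty")
  rows <- lapply(isis_ms, function(isi) {
    proto <- training_protocol(max_pairings, isi, iti_s = iti_s)
    res <- run_training(proto, params, config)
    first <- which(res$anticipated)
    data.frame(isi_ms = isi,
               pairings_to_learn = if (length(first)) first[1] else
                 NA_integer_,
               final_activation_time =
                 res$rgs_activation_time[nrow(res)],
               final_anticipated = res$anticipated[nrow(res)])
  })
  do.call(rbind, rows)
}
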