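#' Write or read a simulation trace
#'
#' Traces are written as tidy CSV (columns `time`, the species/input
#' series, `event`) with a JSON metadata sidecar (`<path>.meta.json`)
#' recording the parameter-set hash, step size, method and package
#' version, so a written trace identifies the run that produced it.
#'
#' @param trace a `pt_trace`.
#' @param path CSV output path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `pt_trace`.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "pt_trace")) stop("trace must be a pt_trace")
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(params_hash = attr(trace, "params_hash"),
               dt = attr(trace, "dt"),
               method = attr(trace, "method"),
               package_version =
                 as.character(utils::packageVersion("purkinjetimer")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$event[is.na(tr$event)] <- ""
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(tr, "params_hash") <- meta$params_hash
    attr(tr, "dt") <- meta$dt
    attr(tr, "method") <- meta$method
  }
  class(tr) <- c("pt_trace", "data.frame")
  tr
}

#' Read a protocol configuration file
#'
#' YAML with either an explicit trial list or a generator spec:
#' \preformatted{
#' # generator form:          # explicit form:
#' n_pairings: 11             # inter_trial_interval: 10
#' isi_ms: 150                # trials:
#' iti_s: 10                  #   - cs_onset: 0.1
#'                            #     us_onset: 0.25
#'                            #   - cs_onset: 0.1   (CS-alone probe)
#' }
#'
#' @param path YAML file path.
#' @return A `pt_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$trials)) {
    iti <- if (is.null(cfg$inter_trial_interval)) 10 else
      cfg$inter_trial_interval
    trials <- lapply(cfg$trials, function(tr) {
      if (is.null(tr$us_onset)) tr$us_onset <- NA_real_  # CS-alone probe
      do.call(conditioning_trial, tr)
    })
    stimulus_protocol(trials, inter_trial_interval = iti)
  } else if (!is.null(cfg$n_pairings)) {
    args <- cfg[intersect(names(cfg),
                          c("n_pairings", "isi_ms", "iti_s", "cs_onset"))]
    do.call(training_protocol, args)
  } else {
    stop("protocol file must contain either 'trials' or 'n_pairings': ",
         path)
  }
}

#' Plot a simulation trace
#'
#' Stacked base-graphics panels of the synaptic calcium, adenylyl cyclase,
#' PKA, and RGS/z series, with stimulus events marked.
#'
#' @param x a `pt_trace`.
#' @param species character vector of columns to show.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.pt_trace <- function(x, species = c("Ca", "AC", "PKA", "RGS"), ...) {
  old <- graphics::par(mfrow = c(length(species), 1),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  cs <- x$time[grepl("CS", x$event)]
  us <- x$time[grepl("US", x$event)]
  for (sp in species) {
    plot(x$time, x[[sp]], type = "l", xlab = "", ylab = sp)
    if (length(cs)) graphics::abline(v = cs, lty = 2)
    if (length(us)) graphics::abline(v = us, lty = 2, col = 2)
  }
  invisible(x)
}
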