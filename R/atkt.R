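#' Automated tourniquet configuration
#'
#' The cuff tightens in fixed pressure increments, dwelling at each, until
#' the distal pulse amplitude stays below `occlusion_pulse_epsilon` for one
#' full dwell (the pressure plateau that verifies occlusion). After
#' engagement, two loosening checks are available to the supervisor: cuff
#' air-pressure oscillations (a partially occluding cuff transmits the
#' arterial pulse, indicating a likely re-bleed), and a drop of the mean
#' cuff pressure of more than `failure_drop_fraction` (33\%) below the
#' recorded engagement pressure (suggesting mechanical failure).
#'
#' @param pressure_step tightening increment (mmHg), `> 0`.
#' @param step_dwell dwell at each increment (s).
#' @param occlusion_pulse_epsilon distal pulsatility below which flow is
#'   considered occluded (mmHg).
#' @param oscillation_threshold peak-to-peak cuff oscillation that signals a
#'   re-bleed (mmHg).
#' @param failure_drop_fraction fractional cuff-pressure drop from the
#'   engagement pressure that signals mechanical failure, in `(0, 1)`.
#' @param max_cuff_pressure hard cap on cuff inflation (mmHg).
#' @param window_s width of the cuff-sample window used by
#'   [detect_loose()] (s); must span at least two cardiac cycles.
#' @return A `tk_config` list.
#' @export
tk_config <- function(pressure_step = 25, step_dwell = 2,
                      occlusion_pulse_epsilon = 0.5,
                      oscillation_threshold = 2,
                      failure_drop_fraction = 0.33,
                      max_cuff_pressure = 300,
                      window_s = 4) {
  stopifnot(pressure_step > 0, step_dwell > 0,
            occlusion_pulse_epsilon > 0, oscillation_threshold > 0,
            failure_drop_fraction > 0, failure_drop_fraction < 1,
            max_cuff_pressure > 0, window_s > 0)
  structure(as.list(environment()), class = "tk_config")
}

#' Classify tourniquet loosening from recent cuff samples
#'
#' Mechanical failure wins over a re-bleed indication when both criteria
#' fire: a large pressure drop implicates the hardware regardless of
#' oscillation. The drop comparison uses the windowed mean cuff pressure
#' against the stored engagement pressure with strictly-greater-than
#' semantics; the re-bleed branch uses the peak-to-peak oscillation in the
#' window.
#'
#' @param cuff_window numeric vector of recent cuff pressure samples
#'   (mmHg), spanning at least two cardiac cycles.
#' @param engagement_pressure cuff pressure recorded at occlusion (mmHg),
#'   `> 0`.
#' @param cfg a [tk_config()].
#' @return One of `"ok"`, `"rebleed_oscillation"`, `"mechanical_failure"`.
#' @export
detect_loose <- function(cuff_window, engagement_pressure, cfg = tk_config()) {
  if (length(cuff_window) == 0L) {
    stop("detect_loose: empty cuff sample window")
  }
  stopifnot(engagement_pressure > 0)
  drop <- (engagement_pressure - mean(cuff_window)) / engagement_pressure
  if (drop > cfg$failure_drop_fraction) return("mechanical_failure")
  if (diff(range(cuff_window)) >= cfg$oscillation_threshold) {
    return("rebleed_oscillation")
  }
  "ok"
}

#' Engage the tourniquet on the simulated plant
#'
#' Runs the incremental tightening loop against the plant until occlusion
#' is verified (or the inflation cap is reached). Convenience wrapper for
#' standalone tourniquet experiments; inside a supervised scenario the same
#' controller is scheduled cooperatively by [run_sacm()].
#'
#' @param plant a [new_plant()].
#' @param cfg a [tk_config()].
#' @param seed optional integer seed (only consequential with measurement
#'   noise).
#' @return An `engagement_result`: list with `engagement_pressure` (mmHg,
#'   `NA` if occlusion was not achieved), `n_steps` (tightening increments
#'   applied), `occluded` (logical), `cuff_trace` (data.frame `t`,
#'   `cuff_pressure`), and the full telemetry `log`.
#' @export
tk_engage <- function(plant, cfg = tk_config(), seed = NULL) {
  stopifnot(inherits(plant, "pv_plant"), inherits(cfg, "tk_config"))
  log <- sim_engine(plant, tk_cfg = cfg, tk_autostart = TRUE, seed = seed)
  ev <- log$events
  eng <- ev$kind %in% c("atkt_engaged", "atkt_reengaged")
  occluded <- any(eng)
  res <- list(
    engagement_pressure = if (occluded) ev$value[eng][1] else NA_real_,
    n_steps = log$tk_steps,
    occluded = occluded,
    cuff_trace = data.frame(t = log$telemetry$t,
                            cuff_pressure = log$telemetry$cuff_pressure),
    log = log)
  class(res) <- "engagement_result"
  res
}

#' @export
print.engagement_result <- function(x, ...) {
  if (x$occluded) {
    cat(sprintf("<engagement_result> occluded at %.0f mmHg after %d steps\n",
                x$engagement_pressure, x$n_steps))
  } else {
    cat(sprintf("<engagement_result> NOT occluded (%d steps, cap reached)\n",
                x$n_steps))
  }
  invisible(x)
}
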