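#' Adaptive resuscitation controller configuration
#'
#' Parameters of the closed-loop infusion controller. Each cycle the
#' controller picks an intermediate mean-pressure setpoint between the
#' measured MAP and the overall target, converts the pressure gap into a
#' volume percent error through the pressure-volume curve, commands
#'
#' \deqn{Q = \mathrm{clamp}\{CF \cdot [(Q_{max}-Q_{min}) \cdot e_V + Q_{min}],\ Q_{min},\ Q_{max}\}}
#'
#' and infuses at that rate, sampling MAP at 1 Hz, until the intermediate
#' setpoint is reached. The correction factor \eqn{CF} (initially 1) then
#' updates multiplicatively from the ratio of the actual to the predicted
#' cycle time, times the user scaling factor, and a new cycle begins. The
#' run terminates when measured MAP is within `termination_fraction`
#' (99.5\%) of the target. Whenever the elapsed cycle time exceeds the
#' predicted time by `hemorrhage_error_threshold` (100\%), a
#' suspected-hemorrhage flag forces the commanded rate to `q_max`; the flag
#' clears as soon as the criterion is no longer met (at the next cycle).
#'
#' @param map_target overall target MAP (mmHg).
#' @param q_min,q_max infusion rate bounds (mL/min), `0 <= q_min < q_max`.
#' @param scaling_factor multiplier inside the correction-factor update
#'   controlling adaptation aggressiveness (dimensionless, `> 0`).
#' @param alpha_intermediate fraction of the remaining pressure gap taken by
#'   each intermediate setpoint, in `(0, 1]`.
#' @param termination_fraction fraction of the target MAP at which the run
#'   terminates.
#' @param sample_period MAP sampling/decision period (s).
#' @param hemorrhage_error_threshold fractional time-prediction error that
#'   raises the suspected-hemorrhage flag (1 = actual time twice predicted).
#' @param cf_min,cf_max clamp on the multiplicative correction factor.
#' @param cf_mode `"multiplicative"` applies the update as printed;
#'   `"deviation"` is an opt-in variant
#'   `CF' = CF * (1 + sf * (t_actual/t_predicted - 1))` for experimentation
#'   with adaptation that scales the *deviation* from unity.
#' @param max_time wall cap on a single resuscitation (simulated s).
#' @param curve the [pv_curve()] the controller was "trained" on; `NULL`
#'   (default) uses the plant's own curve, i.e. a perfectly calibrated
#'   controller. Supplying a different curve simulates plant/model mismatch.
#' @return An `arc_config` list.
#' @export
arc_config <- function(map_target = 95, q_min = 50, q_max = 1200,
                       scaling_factor = 1, alpha_intermediate = 0.5,
                       termination_fraction = 0.995, sample_period = 1,
                       hemorrhage_error_threshold = 1,
                       cf_min = 0.1, cf_max = 10,
                       cf_mode = c("multiplicative", "deviation"),
                       max_time = 1800, curve = NULL) {
  cf_mode <- match.arg(cf_mode)
  if (!is.null(curve)) stopifnot(inherits(curve, "pv_curve"))
  stopifnot(q_min >= 0, q_min < q_max,
            termination_fraction > 0, termination_fraction <= 1,
            scaling_factor > 0,
            alpha_intermediate > 0, alpha_intermediate <= 1,
            sample_period > 0, hemorrhage_error_threshold > 0,
            cf_min > 0, cf_min <= cf_max, max_time > 0)
  structure(as.list(environment()), class = "arc_config")
}

#' Intermediate MAP setpoint
#'
#' A setpoint between the currently measured MAP and the overall target,
#' `map_meas + alpha * (map_target - map_meas)`.
#'
#' @param map_meas measured MAP (mmHg), at most `map_target`.
#' @param map_target overall target MAP (mmHg).
#' @param alpha fraction in `(0, 1]`.
#' @return Setpoint (mmHg), in `[map_meas, map_target]`.
#' @export
intermediate_setpoint <- function(map_meas, map_target, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  if (map_meas > map_target) {
    stop("intermediate_setpoint: measured MAP exceeds target (target met)")
  }
  map_meas + alpha * (map_target - map_meas)
}

#' Volume percent error from a pressure setpoint
#'
#' The fluid volume deficit between the measured MAP and the setpoint,
#' normalized by the total volume at the setpoint:
#' `(V(map_set) - V(map_meas)) / (V(map_set) - v_min)`, clipped to `[0, 1]`
#' and 0 whenever the measured MAP is already at or above the setpoint.
#'
#' @param map_meas,map_set measured MAP and setpoint (mmHg), both within the
#'   curve's achievable range.
#' @param curve a [pv_curve()].
#' @return Fraction in `[0, 1]`.
#' @export
volume_percent_error <- function(map_meas, map_set, curve) {
  if (map_meas >= map_set) return(0)
  v_set <- pv_volume(map_set, curve)
  v_meas <- pv_volume(map_meas, curve)
  denom <- v_set - curve$v_min
  if (denom <= 0) return(0)
  min(max((v_set - v_meas) / denom, 0), 1)
}

#' Commanded infusion flow rate
#'
#' The rate law `(q_max - q_min) * v_err + q_min`, scaled by the adaptive
#' correction factor and clamped to the configured rate bounds.
#'
#' @param v_err volume percent error in `[0, 1]`.
#' @param cfg an [arc_config()].
#' @param correction_factor current correction factor, `> 0`.
#' @return Rate (mL/min) in `[q_min, q_max]`.
#' @export
arc_flow_rate <- function(v_err, cfg, correction_factor = 1) {
  stopifnot(v_err >= 0, v_err <= 1, correction_factor > 0)
  raw <- correction_factor * ((cfg$q_max - cfg$q_min) * v_err + cfg$q_min)
  min(max(raw, cfg$q_min), cfg$q_max)
}

#' Correction factor update
#'
#' Multiplicative adaptive-gain recursion
#' `cf * (t_actual / t_predicted) * scaling_factor`, clamped to
#' `[cf_min, cf_max]`. If `t_predicted` is not positive the update is
#' skipped with a warning (the prediction carries no information).
#'
#' @param cf current correction factor, `> 0`.
#' @param t_actual,t_predicted observed and predicted cycle durations (s).
#' @param scaling_factor adaptation multiplier.
#' @param cf_min,cf_max clamp bounds.
#' @param mode `"multiplicative"` (as defined) or the opt-in `"deviation"`
#'   variant (see [arc_config()]).
#' @return Updated correction factor.
#' @export
update_correction_factor <- function(cf, t_actual, t_predicted,
                                     scaling_factor = 1,
                                     cf_min = 0.1, cf_max = 10,
                                     mode = c("multiplicative", "deviation")) {
  mode <- match.arg(mode)
  stopifnot(cf > 0)
  if (!is.finite(t_predicted) || t_predicted <= 0) {
    warning("update_correction_factor: non-positive predicted time; ",
            "update skipped")
    return(cf)
  }
  out <- switch(mode,
    multiplicative = cf * (t_actual / t_predicted) * scaling_factor,
    deviation = cf * (1 + scaling_factor * (t_actual / t_predicted - 1)))
  min(max(out, cf_min), cf_max)
}

#' Predicted time to traverse a pressure gap at a given rate
#'
#' From the pressure-volume curve: the volume between the two pressures,
#' divided by the infusion rate, in seconds.
#'
#' @param map_from,map_to start and end MAP (mmHg), `map_to > map_from`.
#' @param rate infusion rate (mL/min), `> 0`.
#' @param curve a [pv_curve()].
#' @return Predicted duration (s).
#' @export
predicted_time <- function(map_from, map_to, rate, curve) {
  if (rate <= 0) stop("predicted_time: rate must be > 0")
  if (map_to < map_from) stop("predicted_time: map_to must be >= map_from")
  60 * (pv_volume(map_to, curve) - pv_volume(map_from, curve)) / rate
}

#' Suspected-hemorrhage criterion
#'
#' TRUE when the fractional error of the observed duration against the
#' predicted duration reaches the threshold - with the default threshold of
#' 1, when achieving a pressure increase actually took (at least) twice as
#' long as predicted. While the flag is raised the controller forces the
#' commanded rate to `q_max`.
#'
#' @param t_actual observed duration of the pressure increase (s).
#' @param t_predicted predicted duration (s), `> 0`.
#' @param threshold fractional error threshold (default 1, i.e. a 100
#'   percent error).
#' @return logical.
#' @export
check_suspected_hemorrhage <- function(t_actual, t_predicted, threshold = 1) {
  stopifnot(t_predicted > 0)
  (t_actual - t_predicted) / t_predicted >= threshold
}

#' Run a closed-loop resuscitation
#'
#' Drives the simulated plant with the adaptive controller until the
#' measured MAP is within `termination_fraction` of the target (or the time
#' cap is hit). An ongoing internal hemorrhage can be imposed to reproduce
#' resuscitation-under-hemorrhage experiments.
#'
#' @param plant a [new_plant()] (its state supplies the starting MAP).
#' @param cfg an [arc_config()].
#' @param hem_rate constant internal hemorrhage rate during the run
#'   (mL/min).
#' @param seed optional integer seed (only consequential when the plant has
#'   measurement noise).
#' @return An `arc_result`: list with `reached_target`, `final_map`
#'   (windowed MAP at termination), `total_infused` (mL), `duration` (s),
#'   `rate_trace` (1 Hz data.frame of `t`, `rate`, `flag`), `flag_intervals`
#'   (data.frame `t_start`, `t_end`), and the full telemetry `log`.
#' @export
run_resuscitation <- function(plant, cfg = arc_config(), hem_rate = 0,
                              seed = NULL) {
  stopifnot(inherits(plant, "pv_plant"), inherits(cfg, "arc_config"),
            hem_rate >= 0)
  log <- sim_engine(plant, arc_cfg = cfg, arc_autostart = TRUE,
                    hem_rate0 = hem_rate, max_time = cfg$max_time,
                    seed = seed)
  ev <- log$events
  done <- ev$kind == "arc_completed"
  reached <- any(done)
  res <- list(
    reached_target = reached,
    final_map = if (reached) ev$value[done][1] else utils::tail(log$telemetry$map_windowed, 1),
    total_infused = utils::tail(log$telemetry$cum_infused, 1),
    duration = utils::tail(log$telemetry$t, 1),
    rate_trace = log$rate_trace,
    flag_intervals = log$flag_intervals,
    log = log)
  class(res) <- "arc_result"
  res
}

#' @export
print.arc_result <- function(x, ...) {
  cat(sprintf(
    "<arc_result> %s: final MAP %.2f mmHg, %.1f mL infused in %.1f s (%d flagged intervals)\n",
    if (x$reached_target) "reached target" else "DID NOT reach target",
    x$final_map, x$total_infused, x$duration, nrow(x$flag_intervals)))
  invisible(x)
}
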