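#' Flow-loop plant configuration
#'
#' Parameters of the discrete-time simulated circulatory flow loop: a vessel
#' whose fluid column supplies pressure per a [pv_curve()], a pulsatile
#' circulatory waveform, an extremity branch with a bleed site and a
#' pneumatic cuff, and an internal hemorrhage path drawn straight from the
#' vessel.
#'
#' @param curve a [pv_curve()] for the loaded infusate.
#' @param heart_rate pulse frequency of the circulatory pump (1/min).
#' @param pulse_pressure peak-to-trough amplitude of the central pressure
#'   waveform (mmHg).
#' @param r_bleed hydraulic resistance of the open extremity bleed site
#'   (mmHg.min/mL). The default gives an open bleed at 75 mmHg distal
#'   pressure a loss rate of a few hundred mL/min, comparable to the
#'   internal-hemorrhage severities studied.
#' @param arm_pressure_drop resistive pressure drop across the arm segment
#'   (mmHg), subtracted from the occlusion-scaled central pressure to give
#'   distal pressure.
#' @param cuff_occ_start,cuff_occ_full cuff pressures (mmHg) at which
#'   arterial occlusion begins and completes; occlusion fraction ramps
#'   linearly between them (piecewise-linear saturating law).
#' @param k_transmit fraction of the transmitted arterial pulse that appears
#'   as an air-pressure oscillation in a partially occluding cuff
#'   (dimensionless).
#' @param dt simulation step (s); 0.02 s emulates 50 Hz transducer sampling.
#'   Must be positive and at most 0.1 s.
#' @param noise_sd additive Gaussian measurement noise SD (mmHg) on the
#'   sampled pressure channels; 0 disables noise. When non-zero, seed the
#'   RNG (or pass `seed` to the run functions) for reproducibility.
#' @param map_window_s width (s) of the moving-average window used to report
#'   mean arterial pressure from the instantaneous samples.
#' @return An object of class `plant_config` (a validated list).
#' @export
plant_config <- function(curve = pv_curve_default("whole_blood"),
                         heart_rate = 60,
                         pulse_pressure = 20,
                         r_bleed = 0.25,
                         arm_pressure_drop = 2,
                         cuff_occ_start = 50,
                         cuff_occ_full = 200,
                         k_transmit = 0.2,
                         dt = 0.02,
                         noise_sd = 0,
                         map_window_s = 1) {
  stopifnot(inherits(curve, "pv_curve"),
            heart_rate > 0, pulse_pressure >= 0,
            r_bleed > 0, arm_pressure_drop >= 0,
            cuff_occ_start >= 0, cuff_occ_full > cuff_occ_start,
            k_transmit >= 0, dt > 0, dt <= 0.1,
            noise_sd >= 0, map_window_s >= dt)
  structure(as.list(environment()), class = "plant_config")
}

#' Initialize plant state
#'
#' @param cfg a [plant_config()].
#' @param map_init initial central mean pressure (mmHg); defaults to the
#'   curve baseline (full vessel).
#' @return A `pv_plant`: list with `$cfg` and `$state` (a `loop_state`).
#' @export
new_plant <- function(cfg = plant_config(), map_init = NULL) {
  stopifnot(inherits(cfg, "plant_config"))
  v0 <- if (is.null(map_init)) cfg$curve$v_max else pv_volume(map_init, cfg$curve)
  state <- loop_state(t = 0, v_vessel = v0,
                      central_map = pv_pressure(v0, cfg$curve),
                      pulse_pressure = cfg$pulse_pressure,
                      cuff_pressure = 0,
                      extremity_valve_open = FALSE,
                      internal_hem_rate = 0, infusion_rate = 0,
                      occlusion_fraction = 0,
                      cum_extremity_bleed = 0, cum_internal_hem = 0,
                      cum_infused = 0)
  state$distal_map <- distal_pressure(state$central_map, 0, cfg)
  structure(list(cfg = cfg, state = state), class = "pv_plant")
}

#' Full simulated plant state
#'
#' @param t clock (s).
#' @param v_vessel vessel volume (mL).
#' @param central_map,distal_map mean pressures at the central and distal
#'   transducer sites (mmHg).
#' @param pulse_pressure central pulse amplitude (mmHg).
#' @param cuff_pressure commanded/held cuff air pressure (mmHg).
#' @param extremity_valve_open is the bleed-site valve open.
#' @param internal_hem_rate,infusion_rate current pump rates (mL/min).
#' @param occlusion_fraction arterial occlusion under the cuff, in `[0, 1]`.
#' @param cum_extremity_bleed,cum_internal_hem,cum_infused cumulative
#'   delivered/lost volumes (mL).
#' @return A `loop_state` list.
#' @export
loop_state <- function(t = 0, v_vessel, central_map = NA_real_,
                       distal_map = NA_real_, pulse_pressure = 20,
                       cuff_pressure = 0, extremity_valve_open = FALSE,
                       internal_hem_rate = 0, infusion_rate = 0,
                       occlusion_fraction = 0,
                       cum_extremity_bleed = 0, cum_internal_hem = 0,
                       cum_infused = 0) {
  stopifnot(v_vessel >= 0, internal_hem_rate >= 0, infusion_rate >= 0,
            cum_extremity_bleed >= 0, cum_internal_hem >= 0, cum_infused >= 0,
            occlusion_fraction >= 0, occlusion_fraction <= 1,
            pulse_pressure >= 0, cuff_pressure >= 0)
  structure(list(t = t, v_vessel = v_vessel, central_map = central_map,
                 distal_map = distal_map, pulse_pressure = pulse_pressure,
                 cuff_pressure = cuff_pressure,
                 extremity_valve_open = isTRUE(extremity_valve_open),
                 internal_hem_rate = internal_hem_rate,
                 infusion_rate = infusion_rate,
                 occlusion_fraction = occlusion_fraction,
                 cum_extremity_bleed = cum_extremity_bleed,
                 cum_internal_hem = cum_internal_hem,
                 cum_infused = cum_infused),
            class = "loop_state")
}

#' Actuator commands applied to the plant for one step
#'
#' Maps onto the three peristaltic pumps and the bleed valve of the physical
#' loop: the infusion pump, the internal-hemorrhage pump, the cuff inflation
#' target, and the extremity bleed valve.
#'
#' @param infusion_rate,internal_hem_rate pump rates (mL/min), `>= 0`.
#' @param cuff_pressure_target cuff air pressure to hold (mmHg).
#' @param extremity_valve_open open the bleed-site valve.
#' @return An `actuator_commands` list.
#' @export
actuator_commands <- function(infusion_rate = 0, internal_hem_rate = 0,
                              cuff_pressure_target = 0,
                              extremity_valve_open = FALSE) {
  stopifnot(infusion_rate >= 0, internal_hem_rate >= 0,
            cuff_pressure_target >= 0)
  structure(list(infusion_rate = infusion_rate,
                 internal_hem_rate = internal_hem_rate,
                 cuff_pressure_target = cuff_pressure_target,
                 extremity_valve_open = isTRUE(extremity_valve_open)),
            class = "actuator_commands")
}

#' Instantaneous pulsatile pressure
#'
#' Superimposes a zero-mean sinusoidal pulsatile component on a mean
#' pressure, so the time-average over any whole cardiac cycle equals the
#' mean.
#'
#' @param mean mean pressure (mmHg).
#' @param pulse_pressure peak-to-trough amplitude (mmHg), `>= 0`.
#' @param t time (s); vectorized.
#' @param heart_rate cycle frequency (1/min).
#' @return Instantaneous pressure (mmHg).
#' @export
instantaneous_pressure <- function(mean, pulse_pressure, t, heart_rate = 60) {
  stopifnot(pulse_pressure >= 0, heart_rate > 0)
  mean + 0.5 * pulse_pressure * sin(2 * pi * heart_rate / 60 * t)
}

#' Occlusion fraction produced by a given cuff pressure
#'
#' Piecewise-linear saturating law: no occlusion below `cuff_occ_start`,
#' full occlusion at or above `cuff_occ_full`, linear in between. This
#' reproduces the observed plateau behavior in which tightening continues
#' until transmitted flow is fully occluded.
#'
#' @param cuff_pressure cuff air pressure (mmHg); vectorized.
#' @param cfg a [plant_config()].
#' @return Occlusion fraction in `[0, 1]`.
#' @export
occlusion_fraction <- function(cuff_pressure, cfg) {
  pmin(pmax((cuff_pressure - cfg$cuff_occ_start) /
              (cfg$cuff_occ_full - cfg$cuff_occ_start), 0), 1)
}

# distal mean pressure given central mean and occlusion fraction
distal_pressure <- function(central_map, occ, cfg) {
  pmax(central_map * (1 - occ) - cfg$arm_pressure_drop, 0)
}

#' Extremity bleed outflow
#'
#' Linear pressure/resistance orifice law at the bleed site distal to the
#' cuff: flow is the distal perfusion pressure over the bleed resistance,
#' scaled by the non-occluded fraction, and zero when the valve is closed or
#' the cuff fully occludes.
#'
#' @param distal_map distal mean pressure (mmHg).
#' @param occlusion_fraction occlusion in `[0, 1]`.
#' @param valve_open is the bleed valve open.
#' @param r_bleed bleed-site resistance (mmHg.min/mL), `> 0`.
#' @return Outflow (mL/min).
#' @export
extremity_bleed_flow <- function(distal_map, occlusion_fraction, valve_open,
                                 r_bleed) {
  if (r_bleed <= 0) stop("extremity_bleed_flow: r_bleed must be > 0")
  stopifnot(occlusion_fraction >= 0, occlusion_fraction <= 1)
  if (!isTRUE(valve_open) || occlusion_fraction >= 1) return(0)
  (1 - occlusion_fraction) * max(distal_map, 0) / r_bleed
}

#' Cuff air-pressure oscillation amplitude
#'
#' A partially occluding cuff transmits a fraction of the arterial pulse
#' into its air bladder; a fully occluding cuff (or a disengaged one)
#' transmits none. This is the observable the supervisor uses to detect a
#' loosened tourniquet and likely re-bleed.
#'
#' @param occlusion_fraction occlusion in `[0, 1]`.
#' @param pulse_pressure arterial pulse amplitude (mmHg).
#' @param cuff_engaged is the cuff inflated/engaged.
#' @param k_transmit transmission coefficient (dimensionless).
#' @return Oscillation amplitude (mmHg).
#' @export
cuff_oscillation_amplitude <- function(occlusion_fraction, pulse_pressure,
                                       cuff_engaged, k_transmit = 0.2) {
  stopifnot(occlusion_fraction >= 0, occlusion_fraction <= 1,
            pulse_pressure >= 0, k_transmit >= 0)
  if (!isTRUE(cuff_engaged) || occlusion_fraction >= 1) return(0)
  (1 - occlusion_fraction) * k_transmit * pulse_pressure
}

#' Advance the plant by one step
#'
#' Explicit fixed-step update: the vessel volume integrates the net of
#' infusion, internal hemorrhage, and extremity bleed flows; pressures are
#' re-derived from the pressure-volume curve and the occlusion state; the
#' cumulative volume counters advance by the *delivered* flows. When the
#' vessel would cross its volume bounds the responsible flows are limited so
#' that the counters always reflect actually moved fluid (volume
#' conservation holds exactly even at the bounds) and the clamp is flagged.
#'
#' @param state a [loop_state()].
#' @param cmd an [actuator_commands()].
#' @param cfg a [plant_config()].
#' @param dt step (s), `0 < dt <= 0.1`; defaults to `cfg$dt`.
#' @return The next `loop_state`; attribute `"clamped"` is `TRUE` when a
#'   volume-bound limit was applied during the step.
#' @export
plant_step <- function(state, cmd, cfg, dt = cfg$dt) {
  if (!is.numeric(dt) || dt <= 0) stop("plant_step: dt must be > 0")
  if (dt > 0.1) stop("plant_step: dt must be <= 0.1 s")
  occ <- occlusion_fraction(cmd$cuff_pressure_target, cfg)
  central <- pv_pressure(state$v_vessel, cfg$curve)
  distal <- distal_pressure(central, occ, cfg)
  q_bleed <- extremity_bleed_flow(distal, occ, cmd$extremity_valve_open,
                                  cfg$r_bleed)
  d <- dt / 60
  inn <- cmd$infusion_rate * d
  out_hem <- cmd$internal_hem_rate * d
  out_bleed <- q_bleed * d
  clamped <- FALSE
  v_next <- state$v_vessel + inn - out_hem - out_bleed
  if (v_next < cfg$curve$v_min) {
    avail <- state$v_vessel + inn - cfg$curve$v_min
    f <- if (out_hem + out_bleed > 0) max(avail, 0) / (out_hem + out_bleed) else 0
    out_hem <- out_hem * f
    out_bleed <- out_bleed * f
    clamped <- TRUE
  } else if (v_next > cfg$curve$v_max) {
    inn <- max(cfg$curve$v_max - state$v_vessel + out_hem + out_bleed, 0)
    clamped <- TRUE
  }
  v_next <- state$v_vessel + inn - out_hem - out_bleed
  # guard against sub-ulp excursions past the bounds after flow limiting
  v_next <- min(max(v_next, cfg$curve$v_min), cfg$curve$v_max)
  central_next <- pv_pressure(v_next, cfg$curve)
  out <- loop_state(
    t = state$t + dt, v_vessel = v_next, central_map = central_next,
    distal_map = distal_pressure(central_next, occ, cfg),
    pulse_pressure = cfg$pulse_pressure * 1,
    cuff_pressure = cmd$cuff_pressure_target,
    extremity_valve_open = cmd$extremity_valve_open,
    internal_hem_rate = out_hem / d, infusion_rate = inn / d,
    occlusion_fraction = occ,
    cum_extremity_bleed = state$cum_extremity_bleed + out_bleed,
    cum_internal_hem = state$cum_internal_hem + out_hem,
    cum_infused = state$cum_infused + inn)
  attr(out, "clamped") <- clamped
  out
}
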