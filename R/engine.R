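# Core discrete-time co-simulation engine.
#
# One fixed-step clock advances the flow-loop physics at plant dt (50 Hz by
# default) while the controllers run cooperatively on their own cadences:
# the resuscitation controller samples MAP at 1 Hz, the tourniquet acts at
# dwell boundaries, and the supervisor checks its two monitoring conditions
# every monitoring period. Concurrency in the deployed system ("separate
# and independent processes") is modeled as cooperative scheduling inside
# this single clock; the observable contract -- monitoring never blocks
# while a sub-controller runs, and no sub-controller is started twice -- is
# preserved.
#
# The physics here is the single source of truth used by every run_*
# wrapper; plant_step() implements the identical update functionally and
# the test suite asserts the two agree.

sim_engine <- function(plant,
                       arc_cfg = arc_config(),
                       tk_cfg = tk_config(),
                       sup_cfg = supervisor_config(),
                       scenario = NULL,
                       arc_autostart = FALSE,
                       tk_autostart = FALSE,
                       sacm_autostart = FALSE,
                       hem_rate0 = 0,
                       max_time = NULL,
                       tail_s = 10,
                       seed = NULL) {
  stopifnot(inherits(plant, "pv_plant"))
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  pc <- plant$cfg
  curve <- pc$curve
  ccurve <- if (is.null(arc_cfg$curve)) curve else arc_cfg$curve
  if (is.null(max_time)) max_time <- sup_cfg$max_scenario_time
  dt <- pc$dt
  d60 <- dt / 60
  eps <- dt * 1e-3
  vmin <- curve$v_min; vmax <- curve$v_max
  co <- curve$coefficients
  vrange <- vmax - vmin
  pp <- pc$pulse_pressure
  omega <- 2 * pi * pc$heart_rate / 60
  noise <- pc$noise_sd > 0

  # --- mutable simulation state --------------------------------------------
  st <- plant$state
  v <- st$v_vessel
  cuff_cmd <- st$cuff_pressure
  valve_open <- st$extremity_valve_open
  hem_rate <- if (hem_rate0 > 0) hem_rate0 else st$internal_hem_rate

  # MAP window (running mean over the last map_window_s of 50 Hz samples)
  w <- max(1L, as.integer(round(pc$map_window_s / dt)))
  central0 <- pv_pressure(v, curve)
  wbuf <- rep(central0, w); wsum <- central0 * w; wi <- 0L
  wmap <- central0
  # cuff sample window for loosening detection
  wc <- max(2L, as.integer(round(tk_cfg$window_s / dt)))
  cbuf <- rep(cuff_cmd, wc); ci <- 0L

  # --- events ---------------------------------------------------------------
  ev_t <- numeric(0); ev_kind <- character(0)
  ev_detail <- character(0); ev_val <- numeric(0)
  ev_counts <- integer(0)
  emit <- function(t, kind, detail = "", value = NA_real_) {
    ev_t[[length(ev_t) + 1L]] <<- t
    ev_kind[[length(ev_kind) + 1L]] <<- kind
    ev_detail[[length(ev_detail) + 1L]] <<- detail
    ev_val[[length(ev_val) + 1L]] <<- value
    ev_counts[kind] <<- (if (is.na(ev_counts[kind])) 0L else ev_counts[kind]) + 1L
  }
  count_of <- function(kind) {
    n <- ev_counts[kind]
    if (is.na(n)) 0L else as.integer(n)
  }

  # --- controller state ------------------------------------------------------
  arc_active <- FALSE; arc_cf <- 1; arc_have_cycle <- FALSE
  arc_mi <- NA_real_; arc_rate_cycle <- 0; arc_tcycle <- 0
  arc_tpred <- NA_real_; arc_next <- Inf
  arc_started_at <- NA_real_
  arc_latched <- FALSE    # suspected-hemorrhage flag (held until setpoint)
  arc_vprev <- NA_real_   # volume at the previous 1 Hz sample
  arc_flagged <- FALSE

  tk_active <- FALSE; tk_next <- Inf; tk_below_prev <- FALSE
  tk_reengage <- FALSE; tk_steps <- 0L
  engagement_pressure <- NA_real_; last_engage_t <- -Inf

  stage <- "off"   # off -> tkt -> arc -> monitor
  mon_next <- Inf

  arc_start <- function(t) {
    arc_active <<- TRUE; arc_cf <<- 1; arc_have_cycle <<- FALSE
    arc_latched <<- FALSE; arc_vprev <<- NA_real_; arc_rate_cycle <<- 0
    arc_next <<- t; arc_started_at <<- t
    emit(t, "arc_started")
  }
  tk_start <- function(t, reengage) {
    tk_active <<- TRUE; tk_next <<- t; tk_below_prev <<- FALSE
    tk_reengage <<- reengage
  }
  sacm_start <- function(t) {
    stage <<- "tkt"
    emit(t, "phase_start", "active_intervention")
    tk_start(t, reengage = FALSE)
  }

  # 1 Hz rate trace and flag bookkeeping
  nrt <- as.integer(ceiling(max_time / arc_cfg$sample_period)) + 8L
  rt_t <- numeric(nrt); rt_rate <- numeric(nrt); rt_flag <- logical(nrt)
  nrt_used <- 0L
  fl_start <- numeric(0); fl_end <- numeric(0); fl_open <- NA_real_

  # --- scenario phase machine ------------------------------------------------
  phases <- if (is.null(scenario)) list() else scenario$phases
  n_ph <- length(phases)
  sc_k <- 1L; sc_started <- FALSE
  sc_action_t <- if (n_ph) phases[[1L]]$delay else Inf
  sc_t0 <- NA_real_; sc_ev_base <- 0L
  boundaries <- 0

  # --- telemetry buffers -----------------------------------------------------
  n_max <- as.integer(ceiling(max_time / dt)) + 4L
  T_ <- numeric(n_max); CEN <- numeric(n_max); DIS <- numeric(n_max)
  CUF <- numeric(n_max); WMP <- numeric(n_max); INF <- numeric(n_max)
  HEM <- numeric(n_max); BLE <- numeric(n_max); FB <- numeric(n_max)
  CIN <- numeric(n_max); CHM <- numeric(n_max); CEX <- numeric(n_max)
  VV <- numeric(n_max)
  cum_inf <- st$cum_infused; cum_hem <- st$cum_internal_hem
  cum_ext <- st$cum_extremity_bleed
  fb0 <- cum_inf - cum_hem - cum_ext
  n_clamp <- 0L; clamp_t1 <- NA_real_

  if (tk_autostart) tk_start(0, reengage = FALSE)
  if (arc_autostart) arc_start(0)
  if (sacm_autostart) sacm_start(0)

  i <- 0L
  t <- 0
  repeat {
    # --- scenario phase management ----------------------------------------
    if (sc_k <= n_ph) {
      ph <- phases[[sc_k]]
      if (!sc_started) {
        if (t >= sc_action_t - eps) {
          if (!is.na(ph$set_hem)) hem_rate <- ph$set_hem
          if (ph$open_valve) valve_open <- TRUE
          if (!is.na(ph$loosen)) {
            if (is.na(engagement_pressure)) {
              emit(t, "error", "loosen requested before any engagement")
            } else {
              cuff_cmd <- ph$loosen * engagement_pressure
            }
          }
          emit(t, "phase_start", ph$name)
          if (ph$start_sacm) sacm_start(t)
          sc_started <- TRUE; sc_t0 <- t
          if (ph$until_type == "event") sc_ev_base <- count_of(ph$until_kind)
        }
      } else {
        done <- switch(ph$until_type,
          event = count_of(ph$until_kind) > sc_ev_base,
          map_le = wmap <= ph$until_value,
          time = t - sc_t0 >= ph$until_value - eps)
        if (done) {
          if (ph$stop_hem_on_end) hem_rate <- 0
          boundaries <- c(boundaries, t)
          sc_k <- sc_k + 1L; sc_started <- FALSE
          sc_action_t <- if (sc_k <= n_ph) t + phases[[sc_k]]$delay else Inf
        }
      }
    }

    occ <- (cuff_cmd - pc$cuff_occ_start) / (pc$cuff_occ_full - pc$cuff_occ_start)
    occ <- if (occ < 0) 0 else if (occ > 1) 1 else occ

    # --- supervisor monitoring --------------------------------------------
    if (stage == "monitor" && t >= mon_next - eps) {
      status <- "ok"
      if (!is.na(engagement_pressure) && !tk_active &&
          t - last_engage_t >= tk_cfg$window_s) {
        status <- detect_loose(cbuf, engagement_pressure, tk_cfg)
      }
      running <- c(if (tk_active) "atkt", if (arc_active) "arc")
      acts <- monitoring_step(wmap, status, running, sup_cfg)
      if ("reengage_tourniquet" %in% acts) {
        emit(t, "loose_detected", status)
        tk_start(t, reengage = TRUE)
      }
      if ("start_resuscitation" %in% acts) {
        emit(t, "low_map_detected", value = wmap)
        arc_start(t)
      }
      mon_next <- mon_next + sup_cfg$monitoring_period
    }

    # --- tourniquet controller --------------------------------------------
    if (tk_active && t >= tk_next - eps) {
      pulse_distal <- pp * (1 - occ)
      if (pulse_distal < tk_cfg$occlusion_pulse_epsilon) {
        if (tk_below_prev) {
          tk_active <- FALSE
          engagement_pressure <- cuff_cmd
          last_engage_t <- t
          emit(t, if (tk_reengage) "atkt_reengaged" else "atkt_engaged",
               value = cuff_cmd)
          if (stage == "tkt") {
            stage <- "arc"
            arc_start(t)
          }
        } else {
          tk_below_prev <- TRUE
          tk_next <- t + tk_cfg$step_dwell
        }
      } else {
        tk_below_prev <- FALSE
        if (cuff_cmd + tk_cfg$pressure_step > tk_cfg$max_cuff_pressure + eps) {
          tk_active <- FALSE
          emit(t, "error", "max cuff pressure reached without occlusion")
          if (stage == "tkt") stage <- "off"
        } else {
          cuff_cmd <- cuff_cmd + tk_cfg$pressure_step
          tk_steps <- tk_steps + 1L
          tk_next <- t + tk_cfg$step_dwell
          occ <- (cuff_cmd - pc$cuff_occ_start) /
            (pc$cuff_occ_full - pc$cuff_occ_start)
          occ <- if (occ < 0) 0 else if (occ > 1) 1 else occ
        }
      }
    }

    # --- resuscitation controller (1 Hz samples) --------------------------
    if (arc_active && t >= arc_next - eps) {
      v_meas <- pv_volume(min(max(wmap, pv_pressure(ccurve$v_min, ccurve)),
                              ccurve$p_baseline), ccurve)
      if (wmap >= arc_cfg$termination_fraction * arc_cfg$map_target) {
        arc_active <- FALSE
        arc_rate_cycle <- 0; arc_latched <- FALSE
        emit(t, "arc_completed", value = wmap)
        if (stage == "arc") {
          stage <- "monitor"
          mon_next <- t + sup_cfg$monitoring_period
        }
      } else if (t - arc_started_at > arc_cfg$max_time) {
        arc_active <- FALSE
        arc_rate_cycle <- 0; arc_latched <- FALSE
        emit(t, "error", "resuscitation time cap exceeded", value = wmap)
        if (stage == "arc") {
          stage <- "monitor"
          mon_next <- t + sup_cfg$monitoring_period
        }
      } else {
        if (!arc_have_cycle || wmap >= arc_mi) {
          # intermediate setpoint reached: adapt the correction factor from
          # the cycle's actual vs predicted duration, re-plan, clear flag
          if (arc_have_cycle && !is.na(arc_tpred) && arc_tpred > 0) {
            arc_cf <- update_correction_factor(
              arc_cf, t - arc_tcycle, arc_tpred, arc_cfg$scaling_factor,
              arc_cfg$cf_min, arc_cfg$cf_max, arc_cfg$cf_mode)
          }
          arc_latched <- FALSE
          arc_mi <- wmap +
            arc_cfg$alpha_intermediate * (arc_cfg$map_target - wmap)
          v_set <- pv_volume(arc_mi, ccurve)
          denom <- v_set - ccurve$v_min
          verr <- if (denom > 0) (v_set - v_meas) / denom else 0
          verr <- if (verr < 0) 0 else if (verr > 1) 1 else verr
          raw <- arc_cf * ((arc_cfg$q_max - arc_cfg$q_min) * verr + arc_cfg$q_min)
          arc_rate_cycle <- min(max(raw, arc_cfg$q_min), arc_cfg$q_max)
          arc_tpred <- 60 * (v_set - v_meas) / arc_rate_cycle
          arc_tcycle <- t
          arc_have_cycle <- TRUE
        } else if (!arc_latched && !is.na(arc_vprev) &&
                   t - arc_tcycle >= 2 * arc_cfg$sample_period - eps) {
          # suspected-hemorrhage check: time actually taken for the most
          # recent measured volume increment vs the time predicted for it
          # at the commanded rate; once raised, the flag (and the maximum-
          # rate override) holds until the intermediate setpoint is reached.
          # The first sample after a re-plan is skipped so the windowed MAP
          # reflects only the current commanded rate.
          dv <- v_meas - arc_vprev
          if (dv <= 0) {
            arc_latched <- TRUE
          } else {
            t_pred_inc <- 60 * dv / arc_rate_cycle
            arc_latched <- check_suspected_hemorrhage(
              arc_cfg$sample_period, t_pred_inc,
              arc_cfg$hemorrhage_error_threshold)
          }
        }
        arc_next <- arc_next + arc_cfg$sample_period
      }
      arc_vprev <- v_meas
      nrt_used <- nrt_used + 1L
      rt_t[nrt_used] <- t
      rt_flag[nrt_used] <- arc_active && arc_latched
      rt_rate[nrt_used] <- if (!arc_active) 0 else
        if (arc_latched) arc_cfg$q_max else arc_rate_cycle
    }

    # flag interval bookkeeping
    flagged_now <- arc_active && arc_latched
    if (flagged_now && !arc_flagged) fl_open <- t
    if (!flagged_now && arc_flagged) {
      fl_start <- c(fl_start, fl_open); fl_end <- c(fl_end, t)
      fl_open <- NA_real_
    }
    arc_flagged <- flagged_now

    # --- plant physics -----------------------------------------------------
    inf_rate <- if (!arc_active) 0 else
      if (arc_flagged) arc_cfg$q_max else arc_rate_cycle
    central <- ((co[4] * ((v - vmin) / vrange) + co[3]) *
                  ((v - vmin) / vrange) + co[2]) * ((v - vmin) / vrange) + co[1]
    distal <- central * (1 - occ) - pc$arm_pressure_drop
    if (distal < 0) distal <- 0
    q_bleed <- if (valve_open && occ < 1) (1 - occ) * distal / pc$r_bleed else 0

    inn <- inf_rate * d60
    out_h <- hem_rate * d60
    out_b <- q_bleed * d60
    v_next <- v + inn - out_h - out_b
    if (v_next < vmin) {
      avail <- v + inn - vmin
      f <- if (out_h + out_b > 0) max(avail, 0) / (out_h + out_b) else 0
      out_h <- out_h * f; out_b <- out_b * f
      n_clamp <- n_clamp + 1L
      if (is.na(clamp_t1)) clamp_t1 <- t
      v_next <- v + inn - out_h - out_b
    } else if (v_next > vmax) {
      inn <- max(vmax - v + out_h + out_b, 0)
      n_clamp <- n_clamp + 1L
      if (is.na(clamp_t1)) clamp_t1 <- t
      v_next <- v + inn - out_h - out_b
    }
    v <- v_next
    cum_inf <- cum_inf + inn
    cum_hem <- cum_hem + out_h
    cum_ext <- cum_ext + out_b
    central <- ((co[4] * ((v - vmin) / vrange) + co[3]) *
                  ((v - vmin) / vrange) + co[2]) * ((v - vmin) / vrange) + co[1]
    distal <- central * (1 - occ) - pc$arm_pressure_drop
    if (distal < 0) distal <- 0

    # --- measurement waveforms and windows --------------------------------
    t <- t + dt
    i <- i + 1L
    s <- sin(omega * t)
    central_inst <- central + 0.5 * pp * s
    distal_inst <- distal + 0.5 * pp * (1 - occ) * s
    osc <- if (cuff_cmd > 0 && occ < 1) (1 - occ) * pc$k_transmit * pp else 0
    cuff_inst <- cuff_cmd + osc * s
    if (noise) {
      central_inst <- central_inst + stats::rnorm(1, 0, pc$noise_sd)
      distal_inst <- distal_inst + stats::rnorm(1, 0, pc$noise_sd)
      cuff_inst <- cuff_inst + stats::rnorm(1, 0, pc$noise_sd)
    }
    wi <- wi %% w + 1L
    wsum <- wsum - wbuf[wi] + central_inst
    wbuf[wi] <- central_inst
    wmap <- wsum / w
    ci <- ci %% wc + 1L
    cbuf[ci] <- cuff_inst

    # --- telemetry ---------------------------------------------------------
    T_[i] <- t; CEN[i] <- central; DIS[i] <- distal; CUF[i] <- cuff_inst
    WMP[i] <- wmap; INF[i] <- inn / d60; HEM[i] <- out_h / d60
    BLE[i] <- out_b / d60; CIN[i] <- cum_inf; CHM[i] <- cum_hem
    CEX[i] <- cum_ext; FB[i] <- cum_inf - cum_hem - cum_ext - fb0
    VV[i] <- v

    # --- stop conditions ---------------------------------------------------
    if (t >= max_time - eps) break
    if (n_ph > 0L) {
      if (sc_k > n_ph && t >= boundaries[length(boundaries)] + tail_s - eps &&
          !arc_active && !tk_active) break
    } else {
      if (sacm_autostart) {
        if (stage %in% c("monitor", "off")) break
      } else if (arc_autostart || tk_autostart) {
        if (!arc_active && !tk_active) break
      }
    }
  }

  if (arc_flagged && !is.na(fl_open)) {
    fl_start <- c(fl_start, fl_open); fl_end <- c(fl_end, t)
  }

  idx <- seq_len(i)
  log <- list(
    telemetry = data.frame(
      t = T_[idx], central_map = CEN[idx], distal_map = DIS[idx],
      cuff_pressure = CUF[idx], map_windowed = WMP[idx],
      infusion_rate = INF[idx], internal_hem_rate = HEM[idx],
      extremity_bleed_rate = BLE[idx], fluid_balance = FB[idx],
      cum_infused = CIN[idx], cum_internal = CHM[idx],
      cum_extremity = CEX[idx], v_vessel = VV[idx]),
    events = data.frame(t = ev_t, kind = ev_kind, detail = ev_detail,
                        value = ev_val, stringsAsFactors = FALSE),
    intervals = boundaries,
    rate_trace = data.frame(t = rt_t[seq_len(nrt_used)],
                            rate = rt_rate[seq_len(nrt_used)],
                            flag = rt_flag[seq_len(nrt_used)]),
    flag_intervals = data.frame(t_start = fl_start, t_end = fl_end),
    tk_steps = tk_steps,
    engagement_pressure = engagement_pressure,
    clamps = list(n = n_clamp, first_t = clamp_t1),
    scenario_name = if (is.null(scenario)) NA_character_ else scenario$name,
    config = list(plant = pc, arc = arc_cfg, tk = tk_cfg, sup = sup_cfg))
  class(log) <- "sacm_log"
  log
}

#' @export
print.sacm_log <- function(x, ...) {
  tel <- x$telemetry
  cat(sprintf("<sacm_log> %s: %.1f s simulated, %d telemetry rows, %d events\n",
              if (is.na(x$scenario_name)) "(ad hoc run)" else x$scenario_name,
              utils::tail(tel$t, 1), nrow(tel), nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%.1fs", x$events$kind, x$events$t),
                      collapse = ", ")))
  }
  cat(sprintf("  final central MAP %.2f mmHg, fluid balance %+.1f mL\n",
              utils::tail(tel$central_map, 1),
              utils::tail(tel$fluid_balance, 1)))
  invisible(x)
}
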