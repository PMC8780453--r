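#' Supervisor configuration
#'
#' The supervisory controller proceeds in two stages. During *active
#' intervention* it sequentially engages the tourniquet (stopping the
#' extremity bleed) and then hands control to the resuscitation controller
#' until the target MAP is reached. It then enters *monitoring*, checking
#' two logical conditions every `monitoring_period` seconds: whether the
#' tourniquet has become loose (via [detect_loose()]) and whether the
#' central MAP has dropped below `map_intervention_threshold`. Each check
#' can dispatch its sub-controller; both can fire in the same period, and a
#' sub-controller that is already running is never started twice.
#'
#' @param monitoring_period spacing of the monitoring checks (s).
#' @param map_intervention_threshold MAP (mmHg) below which a resuscitation
#'   is dispatched.
#' @param reentrancy_policy only `"skip_if_running"` is defined: a check
#'   whose sub-controller is already active is skipped for that period.
#' @param max_scenario_time hard cap on simulated scenario time (s).
#' @return A `supervisor_config` list.
#' @export
supervisor_config <- function(monitoring_period = 15,
                              map_intervention_threshold = 85,
                              reentrancy_policy = "skip_if_running",
                              max_scenario_time = 1800) {
  reentrancy_policy <- match.arg(reentrancy_policy, "skip_if_running")
  stopifnot(monitoring_period > 0, map_intervention_threshold > 0,
            max_scenario_time > 0)
  structure(as.list(environment()), class = "supervisor_config")
}

#' One supervisory monitoring check
#'
#' Pure decision function evaluated once per monitoring period: given the
#' current windowed central MAP, the tourniquet loosening status, and the
#' set of currently running sub-controllers, returns the actions to
#' dispatch. A loose tourniquet (any status other than `"ok"`) requests
#' re-engagement unless the tourniquet controller is already running; a MAP
#' below the intervention threshold requests a resuscitation unless one is
#' already running. The two checks are independent, so both actions may be
#' returned together.
#'
#' @param central_map windowed central MAP at the check instant (mmHg).
#' @param tk_status a [detect_loose()] status string.
#' @param running character vector naming active sub-controllers, a subset
#'   of `c("atkt", "arc")`.
#' @param cfg a [supervisor_config()].
#' @return Character vector, subset of
#'   `c("reengage_tourniquet", "start_resuscitation")`.
#' @export
monitoring_step <- function(central_map, tk_status = "ok",
                            running = character(), cfg = supervisor_config()) {
  stopifnot(tk_status %in% c("ok", "rebleed_oscillation", "mechanical_failure"),
            all(running %in% c("atkt", "arc")))
  acts <- character(0)
  if (tk_status != "ok" && !("atkt" %in% running)) {
    acts <- c(acts, "reengage_tourniquet")
  }
  if (central_map < cfg$map_intervention_threshold && !("arc" %in% running)) {
    acts <- c(acts, "start_resuscitation")
  }
  acts
}

#' Run the active-intervention stage
#'
#' Engages the tourniquet to completion, then runs the resuscitation
#' controller to its termination criterion, starting from the plant's
#' current state. This is the sequence the supervisor executes when it is
#' first started on a casualty with a bleeding extremity entering
#' hemorrhagic shock.
#'
#' @param plant a [new_plant()]; open its extremity valve beforehand to
#'   model an ongoing extremity bleed.
#' @param tk_cfg a [tk_config()].
#' @param arc_cfg an [arc_config()].
#' @param sup_cfg a [supervisor_config()].
#' @param seed optional seed.
#' @return The supervisor event stream (a data.frame with `t`, `kind`,
#'   `detail`, `value`); the full telemetry log is attached as attribute
#'   `"log"`.
#' @export
run_active_intervention <- function(plant, tk_cfg = tk_config(),
                                    arc_cfg = arc_config(),
                                    sup_cfg = supervisor_config(),
                                    seed = NULL) {
  log <- sim_engine(plant, arc_cfg = arc_cfg, tk_cfg = tk_cfg,
                    sup_cfg = sup_cfg, sacm_autostart = TRUE, seed = seed)
  ev <- log$events
  attr(ev, "log") <- log
  ev
}

#' Run a full supervised trauma scenario
#'
#' Executes a scenario under the supervisory controller: the scenario
#' schedule destabilizes the plant and injects complications (extremity
#' bleed, internal hemorrhage, tourniquet loosening); the supervisor runs
#' its active-intervention stage when the scenario starts it, then monitors
#' every `monitoring_period` seconds and dispatches the sub-controllers as
#' needed, concurrently with each other.
#'
#' @param plant a [new_plant()].
#' @param scenario a [scenario_spec()] (e.g. from [load_scenario()] or
#'   [bundled_scenario()]).
#' @param arc_cfg,tk_cfg,sup_cfg controller configurations.
#' @param seed integer seed; fixes measurement noise (if enabled) so a
#'   scenario run is exactly reproducible.
#' @return A `sacm_log`: per-tick telemetry (the five reported channels
#'   plus cumulative volumes), the supervisor event stream, and the
#'   recorded interval boundary times.
#' @export
run_sacm <- function(plant, scenario, arc_cfg = arc_config(),
                     tk_cfg = tk_config(), sup_cfg = supervisor_config(),
                     seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(seed)) seed <- scenario$seed
  sim_engine(plant, arc_cfg = arc_cfg, tk_cfg = tk_cfg, sup_cfg = sup_cfg,
             scenario = scenario, seed = seed)
}
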