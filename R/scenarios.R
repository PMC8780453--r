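#' Build a scenario phase
#'
#' A scenario is an ordered list of phases. Each phase applies its injected
#' events when it starts (after `delay` seconds from the end of the
#' previous phase) and ends when its `until` trigger fires; phase end times
#' are recorded as the scenario's interval boundaries.
#'
#' @param name phase label.
#' @param until trigger ending the phase: a one-element named list, one of
#'   `list(map_le = <mmHg>)` (windowed central MAP falls to the value),
#'   `list(event = <kind>)` (a supervisor event of that kind is emitted
#'   after the phase starts), or `list(time = <s>)` (fixed duration).
#' @param delay seconds to wait after the previous phase ends before
#'   applying this phase's events.
#' @param internal_hemorrhage if non-`NA`, set the internal hemorrhage pump
#'   to this rate (mL/min) at phase start.
#' @param stop_hemorrhage_at_end stop the internal hemorrhage when the
#'   phase ends.
#' @param open_extremity_valve open the extremity bleed valve at phase
#'   start.
#' @param loosen_tourniquet if non-`NA`, drop the cuff pressure to this
#'   fraction of the recorded engagement pressure at phase start (manual
#'   loosening).
#' @param start_sacm start the supervisor's active-intervention stage at
#'   phase start.
#' @return A `scenario_phase` list in canonical form.
#' @export
scenario_phase <- function(name, until, delay = 0,
                           internal_hemorrhage = NA_real_,
                           stop_hemorrhage_at_end = FALSE,
                           open_extremity_valve = FALSE,
                           loosen_tourniquet = NA_real_,
                           start_sacm = FALSE) {
  if (!is.list(until) || length(until) != 1L || is.null(names(until)) ||
      !names(until) %in% c("map_le", "event", "time")) {
    stop("scenario_phase '", name, "': 'until' must be a one-element named ",
         "list with key map_le, event, or time")
  }
  kinds <- c("phase_start", "atkt_engaged", "arc_started", "arc_completed",
             "loose_detected", "low_map_detected", "atkt_reengaged", "error")
  ut <- names(until)
  uv <- until[[1L]]
  if (ut == "event") {
    if (!uv %in% kinds) stop("scenario_phase '", name, "': unknown event kind '",
                             uv, "'")
  } else {
    if (!is.numeric(uv) || length(uv) != 1L || !is.finite(uv) ||
        (ut == "time" && uv <= 0)) {
      stop("scenario_phase '", name, "': '", ut, "' trigger needs one finite ",
           "numeric value")
    }
  }
  stopifnot(delay >= 0,
            is.na(internal_hemorrhage) || internal_hemorrhage >= 0,
            is.na(loosen_tourniquet) ||
              (loosen_tourniquet >= 0 && loosen_tourniquet <= 1))
  structure(list(name = as.character(name), delay = as.numeric(delay),
                 set_hem = as.numeric(internal_hemorrhage),
                 stop_hem_on_end = isTRUE(stop_hemorrhage_at_end),
                 open_valve = isTRUE(open_extremity_valve),
                 loosen = as.numeric(loosen_tourniquet),
                 start_sacm = isTRUE(start_sacm),
                 until_type = ut,
                 until_kind = if (ut == "event") uv else NA_character_,
                 until_value = if (ut == "event") NA_real_ else as.numeric(uv)),
            class = "scenario_phase")
}

#' Assemble a scenario specification
#'
#' @param name scenario label.
#' @param phases list of [scenario_phase()] objects, in order.
#' @param infusate `"whole_blood"` or `"crystalloid"`; selects the default
#'   pressure-volume curve when [run_scenario()] builds the plant.
#' @param seed default seed for runs of this scenario.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, phases,
                          infusate = c("whole_blood", "crystalloid"),
                          seed = 1L) {
  infusate <- match.arg(infusate)
  stopifnot(length(phases) >= 1L,
            all(vapply(phases, inherits, logical(1), "scenario_phase")))
  structure(list(name = as.character(name), phases = phases,
                 infusate = infusate, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s (%s, %d intervals)\n",
              x$name, x$infusate, length(x$phases)))
  for (k in seq_along(x$phases)) {
    ph <- x$phases[[k]]
    acts <- c(
      if (!is.na(ph$set_hem)) sprintf("hem=%g", ph$set_hem),
      if (ph$open_valve) "open_valve",
      if (!is.na(ph$loosen)) sprintf("loosen=%g", ph$loosen),
      if (ph$start_sacm) "start_sacm",
      if (ph$stop_hem_on_end) "stop_hem_at_end")
    until <- if (ph$until_type == "event") ph$until_kind
             else sprintf("%s %g", ph$until_type, ph$until_value)
    cat(sprintf("  [%d-%d] %s: %s; until %s\n", k - 1L, k, ph$name,
                if (length(acts)) paste(acts, collapse = ", ") else "-",
                until))
  }
  invisible(x)
}

#' Load a scenario from a structured-text (YAML) file
#'
#' The schema has top-level keys `name`, `infusate`, `seed` (optional), and
#' `phases`; each phase accepts the arguments of [scenario_phase()] (with
#' `until` as a one-key mapping). Unknown keys are rejected by name.
#'
#' @param path path to a YAML scenario file.
#' @return A [scenario_spec()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("load_scenario: no such file: ", path)
  raw <- yaml::read_yaml(path)
  top_allowed <- c("name", "infusate", "seed", "phases")
  bad <- setdiff(names(raw), top_allowed)
  if (length(bad)) {
    stop("load_scenario: unknown top-level key(s): ",
         paste(bad, collapse = ", "))
  }
  for (key in c("name", "infusate", "phases")) {
    if (is.null(raw[[key]])) stop("load_scenario: missing required key '",
                                  key, "'")
  }
  ph_allowed <- c("name", "delay", "internal_hemorrhage",
                  "stop_hemorrhage_at_end", "open_extremity_valve",
                  "loosen_tourniquet", "start_sacm", "until")
  phases <- lapply(seq_along(raw$phases), function(k) {
    p <- raw$phases[[k]]
    bad <- setdiff(names(p), ph_allowed)
    if (length(bad)) {
      stop("load_scenario: phase ", k, ": unknown key(s): ",
           paste(bad, collapse = ", "))
    }
    if (is.null(p$until)) stop("load_scenario: phase ", k, ": missing 'until'")
    scenario_phase(
      name = if (is.null(p$name)) sprintf("phase_%d", k) else p$name,
      until = p$until,
      delay = if (is.null(p$delay)) 0 else p$delay,
      internal_hemorrhage = if (is.null(p$internal_hemorrhage)) NA_real_
                            else p$internal_hemorrhage,
      stop_hemorrhage_at_end = isTRUE(p$stop_hemorrhage_at_end),
      open_extremity_valve = isTRUE(p$open_extremity_valve),
      loosen_tourniquet = if (is.null(p$loosen_tourniquet)) NA_real_
                          else p$loosen_tourniquet,
      start_sacm = isTRUE(p$start_sacm))
  })
  scenario_spec(name = raw$name, phases = phases, infusate = raw$infusate,
                seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Bundled trauma scenarios
#'
#' The five supervised trauma scenarios shipped with the package: all open
#' with an initial hemorrhage down to 75 mmHg, an extremity bleed stopped by
#' the tourniquet, and a resuscitation back to 95 mmHg; scenarios 2-5 then
#' inject tourniquet loosenings and/or 240 mL/min internal hemorrhages in
#' all pairwise combinations, with scenario 5 running both complications
#' simultaneously.
#'
#' @param which integer 1 to 5.
#' @return A [scenario_spec()].
#' @export
bundled_scenario <- function(which) {
  stopifnot(length(which) == 1L, which %in% 1:5)
  path <- system.file("extdata", sprintf("scenario_%d.yaml", which),
                      package = "sacmsim")
  if (!nzchar(path)) stop("bundled scenario file not found; reinstall package")
  load_scenario(path)
}

#' Run a scenario end-to-end
#'
#' Builds a fresh plant for the scenario's infusate (full vessel, 95 mmHg
#' baseline) and drives it through the scenario under the supervisor.
#'
#' @param spec a [scenario_spec()].
#' @param plant_cfg optional [plant_config()]; by default the infusate's
#'   default curve with no measurement noise.
#' @param arc_cfg,tk_cfg,sup_cfg controller configurations.
#' @param seed integer seed (defaults to the spec's seed).
#' @return A `sacm_log` (see [run_sacm()]).
#' @export
run_scenario <- function(spec, plant_cfg = NULL, arc_cfg = arc_config(),
                         tk_cfg = tk_config(), sup_cfg = supervisor_config(),
                         seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(plant_cfg)) {
    plant_cfg <- plant_config(curve = pv_curve_default(spec$infusate))
  }
  plant <- new_plant(plant_cfg)
  run_sacm(plant, spec, arc_cfg = arc_cfg, tk_cfg = tk_cfg,
           sup_cfg = sup_cfg, seed = if (is.null(seed)) spec$seed else seed)
}
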