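# shared fixtures: all built in code at test time

wb_curve <- pv_curve_default("whole_blood")
cr_curve <- pv_curve_default("crystalloid")

# a hypotensive whole-blood plant, the standard starting point
hypo_plant <- function(map_init = 75, ...) {
  new_plant(plant_config(...), map_init = map_init)
}

# independent bisection inversion of a pv_curve, used as the oracle for
# pv_volume(); deliberately shares no code with the package implementation
bisect_volume <- function(p, curve, tol = 1e-9) {
  lo <- curve$v_min
  hi <- curve$v_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pv_pressure(mid, curve) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# count how often consecutive starts of a controller overlap (a start
# before the previous instance completed); used for re-entrancy checks
n_overlapping_instances <- function(events, start_kinds, end_kinds) {
  open <- 0L
  bad <- 0L
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k %in% start_kinds) {
      if (open > 0L) bad <- bad + 1L
      open <- open + 1L
    } else if (k %in% end_kinds && open > 0L) {
      open <- open - 1L
    }
  }
  bad
}
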