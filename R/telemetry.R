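#' Fluid balance time series
#'
#' Total infused volume minus total hemorrhage (internal plus extremity) at
#' every tick, relative to the start of the log; zero means the system has
#' returned to its initial volume.
#'
#' @param log a `sacm_log`.
#' @return data.frame with `t` (s) and `fluid_balance` (mL).
#' @export
fluid_balance <- function(log) {
  stopifnot(inherits(log, "sacm_log"))
  tel <- log$telemetry
  # recompute from the cumulative counters; offset so the series is
  # relative to the state at the start of the run (first row includes the
  # first step's flows, so subtract the pre-step baseline, not row 1)
  fb <- tel$cum_infused - tel$cum_internal - tel$cum_extremity
  base <- fb[1] - tel$fluid_balance[1]
  data.frame(t = tel$t, fluid_balance = fb - base)
}

#' Map telemetry onto normalized scenario intervals
#'
#' Each recorded interval `n` of the scenario is mapped to the normalized
#' time range `[n - 1, n]`, so replicate runs with different wall durations
#' align bin-by-bin (three bins for the minimal scenario, five for the
#' rest).
#'
#' @param log a `sacm_log` with recorded interval boundaries.
#' @param n_bins expected number of bins; must match the recorded
#'   boundaries.
#' @return list with `data` (telemetry plus `interval` and normalized time
#'   `tau`), `edges` (boundary times, s), and `summary` (per-bin means of
#'   the five reported channels).
#' @export
bin_intervals <- function(log, n_bins = length(log$intervals) - 1L) {
  stopifnot(inherits(log, "sacm_log"))
  edges <- log$intervals
  if (length(edges) < 2L) stop("bin_intervals: log has no interval boundaries")
  if (n_bins != length(edges) - 1L) {
    stop(sprintf("bin_intervals: log records %d intervals, not %d",
                 length(edges) - 1L, n_bins))
  }
  tel <- log$telemetry
  # the log runs a settling tail past the last boundary; fold it into the
  # last bin so the bins cover the whole record
  top <- max(edges[length(edges)], tel$t[nrow(tel)])
  cut_edges <- c(edges[-length(edges)], top + 1e-9)
  k <- findInterval(tel$t, cut_edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  width <- cut_edges[k + 1L] - cut_edges[k]
  tau <- (k - 1L) + (tel$t - cut_edges[k]) / width
  dat <- cbind(data.frame(interval = k, tau = tau), tel)
  chans <- c("distal_map", "cuff_pressure", "central_map", "infusion_rate",
             "fluid_balance")
  summ <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    rows <- dat$interval == b
    out <- as.data.frame(as.list(colMeans(tel[rows, chans, drop = FALSE])))
    cbind(data.frame(interval = b, t_start = cut_edges[b],
                     t_end = cut_edges[b + 1L]), out)
  }))
  list(data = dat, edges = edges, summary = summ)
}

#' Export infusion-rate heatmap matrix
#'
#' Stacks replicate 1 Hz infusion-rate traces into a matrix (one row per
#' replicate), padded to the longest duration, and normalizes values to
#' `[0, 1]` by the reference maximum infusion rate so that all heatmaps
#' share one scale. `value * q_ref` recovers the rate in mL/min.
#'
#' @param rate_traces list of numeric rate vectors (mL/min at 1 Hz), or of
#'   `rate_trace` data.frames from [run_resuscitation()].
#' @param q_ref normalizing maximum rate (mL/min), default 1200.
#' @param path optional basename; writes `<path>.csv` (the matrix) and
#'   `<path>.json` (scaling metadata).
#' @return list with `matrix` (replicates x time, normalized; `NA` pads
#'   shorter runs) and `meta` (`q_ref`, `n_replicates`, `t_max_s`,
#'   `durations_s`).
#' @export
export_heatmap <- function(rate_traces, q_ref = 1200, path = NULL) {
  if (length(rate_traces) == 0L) stop("export_heatmap: no traces supplied")
  rates <- lapply(rate_traces, function(x) {
    if (is.data.frame(x)) x$rate else as.numeric(x)
  })
  if (any(!vapply(rates, length, 1L))) {
    stop("export_heatmap: empty trace supplied")
  }
  n <- max(vapply(rates, length, 1L))
  m <- t(vapply(rates, function(r) c(r, rep(NA_real_, n - length(r))) / q_ref,
                numeric(n)))
  dimnames(m) <- list(sprintf("replicate_%d", seq_along(rates)), NULL)
  meta <- list(q_ref = q_ref, n_replicates = length(rates), t_max_s = n - 1L,
               durations_s = unname(vapply(rates, length, 1L)) - 1L)
  if (!is.null(path)) {
    utils::write.csv(m, paste0(path, ".csv"), row.names = TRUE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(matrix = m, meta = meta)
}

#' The resuscitation-controller test matrix
#'
#' The eight benchmark conditions for exercising the controller: three
#' scaling factors (0.5, 1, 2) and three ongoing internal hemorrhage rates
#' (120, 240, 360 mL/min) on the whole-blood vessel, plus baseline and a
#' 240 mL/min hemorrhage on the crystalloid vessel.
#'
#' @return data.frame with `condition`, `infusate`, `scaling_factor`,
#'   `hem_rate`.
#' @export
arc_test_matrix <- function() {
  data.frame(
    condition = c("wb_scale_0.5", "wb_scale_1", "wb_scale_2",
                  "wb_hem_120", "wb_hem_240", "wb_hem_360",
                  "cryst_baseline", "cryst_hem_240"),
    infusate = c(rep("whole_blood", 6), rep("crystalloid", 2)),
    scaling_factor = c(0.5, 1, 2, 1, 1, 1, 1, 1),
    hem_rate = c(0, 0, 0, 120, 240, 360, 0, 240),
    stringsAsFactors = FALSE)
}

#' Run resuscitation benchmark conditions in replicate
#'
#' Runs [run_resuscitation()] from a 75 mmHg hypotensive start toward the
#' 95 mmHg target for each requested condition of [arc_test_matrix()], in
#' replicate with per-replicate seeds.
#'
#' @param conditions character vector of condition keys; default all eight.
#' @param replicates replicates per condition.
#' @param seed base integer seed; replicate `r` of condition `i` uses
#'   `seed + 1000 * i + r`.
#' @param map_start starting MAP (mmHg).
#' @param noise_sd measurement noise SD passed to the plant (mmHg).
#' @return list with `results` (one row per run: final MAP, duration, total
#'   infused volume, fraction of 1 Hz samples with the suspected-hemorrhage
#'   flag raised) and `rate_traces` (named list of 1 Hz traces, for
#'   [export_heatmap()]).
#' @export
run_arc_matrix <- function(conditions = NULL, replicates = 3, seed = 1,
                           map_start = 75, noise_sd = 0) {
  tab <- arc_test_matrix()
  if (!is.null(conditions)) {
    bad <- setdiff(conditions, tab$condition)
    if (length(bad)) stop("run_arc_matrix: unknown condition(s): ",
                          paste(bad, collapse = ", "))
    tab <- tab[tab$condition %in% conditions, , drop = FALSE]
  }
  rows <- list(); traces <- list()
  for (i in seq_len(nrow(tab))) {
    for (r in seq_len(replicates)) {
      run_seed <- (seed + 1000 * i + r) %% .Machine$integer.max
      pcfg <- plant_config(curve = pv_curve_default(tab$infusate[i]),
                           noise_sd = noise_sd)
      plant <- new_plant(pcfg, map_init = map_start)
      acfg <- arc_config(scaling_factor = tab$scaling_factor[i])
      res <- run_resuscitation(plant, acfg, hem_rate = tab$hem_rate[i],
                               seed = run_seed)
      rt <- res$rate_trace
      key <- sprintf("%s_rep%d", tab$condition[i], r)
      traces[[key]] <- rt
      rows[[key]] <- data.frame(
        condition = tab$condition[i], replicate = r, seed = run_seed,
        reached_target = res$reached_target, final_map = res$final_map,
        duration_s = res$duration, total_infused_mL = res$total_infused,
        flag_fraction = if (nrow(rt)) mean(rt$flag) else 0,
        stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       rate_traces = traces)
}
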