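#' Normalized pressure-volume curve of the simulated vessel
#'
#' A `pv_curve` maps vessel volume to the mean pressure the fluid column
#' supplies to the flow loop. The map is a cubic polynomial in the
#' *normalized* volume `u = (v - v_min) / (v_max - v_min)`, anchored so that
#' the full vessel (`u = 1`) produces `p_baseline`. One curve is defined per
#' infusate because whole blood and crystalloid restore pressure with very
#' different volume efficiency.
#'
#' The polynomial must be strictly increasing on `[0, 1]`; this is checked on
#' construction so that the inverse map [pv_volume()] is well defined.
#'
#' @param coefficients numeric length 4: polynomial coefficients
#'   `c0 + c1*u + c2*u^2 + c3*u^3` (mmHg as a function of normalized volume).
#' @param v_min,v_max volume range of the vessel (mL), `v_min < v_max`.
#' @param infusate_kind `"whole_blood"` or `"crystalloid"`.
#' @return An object of class `pv_curve`.
#' @seealso [pv_curve_default()], [pv_pressure()], [pv_volume()]
#' @examples
#' wb <- pv_curve_default("whole_blood")
#' pv_pressure(wb$v_max, wb)          # 95 mmHg at the full vessel
#' pv_volume(75, wb)                  # volume at 75 mmHg
#' @export
pv_curve <- function(coefficients, v_min, v_max,
                     infusate_kind = c("whole_blood", "crystalloid")) {
  infusate_kind <- match.arg(infusate_kind)
  stopifnot(is.numeric(coefficients), length(coefficients) == 4L,
            all(is.finite(coefficients)),
            is.numeric(v_min), is.numeric(v_max), length(v_min) == 1L,
            length(v_max) == 1L, v_min < v_max)
  # strict monotonicity of c1 + 2*c2*u + 3*c3*u^2 on [0, 1]
  u <- seq(0, 1, length.out = 513L)
  slope <- coefficients[2] + 2 * coefficients[3] * u + 3 * coefficients[4] * u^2
  if (any(slope <= 0)) {
    stop("pv_curve: pressure must be strictly increasing in volume over ",
         "[v_min, v_max]; derivative is non-positive somewhere on the range")
  }
  structure(
    list(coefficients = as.numeric(coefficients),
         v_min = as.numeric(v_min), v_max = as.numeric(v_max),
         p_baseline = sum(coefficients),
         infusate_kind = infusate_kind),
    class = "pv_curve")
}

#' Default pressure-volume curves for the two infusates
#'
#' Synthetic stand-ins for porcine-derived normalized pressure-volume
#' relationships (the source coefficients are not publicly printed). Both
#' are anchored at 95 mmHg at the full vessel. The crystalloid vessel holds
#' 2.5x the whole-blood volume and is flatter near the top, so the volume
#' needed to traverse 75 to 95 mmHg is more than twice the whole-blood
#' volume, reflecting the poor volume efficiency of crystalloid
#' resuscitation.
#'
#' @param infusate_kind `"whole_blood"` or `"crystalloid"`.
#' @return A [pv_curve()].
#' @export
pv_curve_default <- function(infusate_kind = c("whole_blood", "crystalloid")) {
  infusate_kind <- match.arg(infusate_kind)
  switch(infusate_kind,
    whole_blood = pv_curve(c(30, 80, -25, 10), v_min = 0, v_max = 1000,
                           infusate_kind = "whole_blood"),
    crystalloid = pv_curve(c(30, 90, -45, 20), v_min = 0, v_max = 2500,
                           infusate_kind = "crystalloid"))
}

#' Random strictly monotone cubic pressure-volume curve
#'
#' Draws a monotone cubic curve anchored at `p_baseline` at the full vessel,
#' with a hypotensive floor pressure between 20 and 60 mmHg and a total
#' vessel volume between 600 and 2000 mL. Used for property-style testing of
#' the controllers across plant variation.
#'
#' @param p_baseline pressure at the full vessel (mmHg).
#' @param infusate_kind passed to [pv_curve()].
#' @return A [pv_curve()]. Uses the current RNG state; call `set.seed()`
#'   first for reproducibility.
#' @export
random_pv_curve <- function(p_baseline = 95,
                            infusate_kind = c("whole_blood", "crystalloid")) {
  infusate_kind <- match.arg(infusate_kind)
  repeat {
    c1 <- stats::runif(1, 40, 100)
    c2 <- stats::runif(1, -40, 40)
    c3 <- stats::runif(1, 0, 40)
    c0 <- p_baseline - (c1 + c2 + c3)
    if (c0 < 20 || c0 > 60) next
    u <- seq(0, 1, length.out = 257L)
    if (any(c1 + 2 * c2 * u + 3 * c3 * u^2 <= 0)) next
    v_max <- stats::runif(1, 600, 2000)
    return(pv_curve(c(c0, c1, c2, c3), v_min = 0, v_max = v_max,
                    infusate_kind = infusate_kind))
  }
}

#' @export
print.pv_curve <- function(x, ...) {
  cat(sprintf("<pv_curve> %s: p(u) = %.4g + %.4g u + %.4g u^2 + %.4g u^3\n",
              x$infusate_kind, x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$coefficients[4]))
  cat(sprintf("  volume range [%.6g, %.6g] mL, baseline %.6g mmHg\n",
              x$v_min, x$v_max, x$p_baseline))
  invisible(x)
}

#' Pressure supplied by the vessel at a given volume
#'
#' @param v vessel volume (mL), within `[v_min, v_max]`; vectorized.
#' @param curve a [pv_curve()].
#' @return Mean pressure (mmHg).
#' @export
pv_pressure <- function(v, curve) {
  stopifnot(inherits(curve, "pv_curve"))
  tol <- 1e-9 * (curve$v_max - curve$v_min)
  if (any(v < curve$v_min - tol | v > curve$v_max + tol)) {
    stop(sprintf("pv_pressure: volume outside [%g, %g] mL",
                 curve$v_min, curve$v_max))
  }
  u <- (pmin(pmax(v, curve$v_min), curve$v_max) - curve$v_min) /
    (curve$v_max - curve$v_min)
  cf <- curve$coefficients
  ((cf[4] * u + cf[3]) * u + cf[2]) * u + cf[1]
}

#' Volume deficit lookup: invert the pressure-volume curve
#'
#' Numerically inverts the monotone curve so the controller can estimate the
#' fluid volume associated with a measured mean arterial pressure.
#'
#' @param p pressure (mmHg), within the achievable range of the curve;
#'   vectorized.
#' @param curve a [pv_curve()].
#' @return Volume (mL) such that `pv_pressure(volume, curve) == p`.
#' @export
pv_volume <- function(p, curve) {
  stopifnot(inherits(curve, "pv_curve"))
  p_lo <- pv_pressure(curve$v_min, curve)
  p_hi <- curve$p_baseline
  if (any(p < p_lo - 1e-9 | p > p_hi + 1e-9)) {
    stop(sprintf("pv_volume: pressure outside achievable range [%g, %g] mmHg",
                 p_lo, p_hi))
  }
  cf <- curve$coefficients
  vapply(pmin(pmax(p, p_lo), p_hi), function(pi) {
    if (pi <= p_lo) return(curve$v_min)
    if (pi >= p_hi) return(curve$v_max)
    u <- stats::uniroot(
      function(u) ((cf[4] * u + cf[3]) * u + cf[2]) * u + cf[1] - pi,
      lower = 0, upper = 1, tol = 1e-12)$root
    curve$v_min + u * (curve$v_max - curve$v_min)
  }, numeric(1))
}
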