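#' Mitral-outlet velocity waveform
#'
#' Pulsatile plug velocity imposed at the mitral orifice. One cardiac cycle of
#' period `T` starts with atrial diastole (mitral valve closed, the atrium
#' fills from the pulmonary veins) lasting `diastole_fraction * T`; the
#' remaining atrial-emptying window carries the early filling wave (E) and
#' the atrial-contraction wave (A), modelled as smooth raised-cosine pulses.
#' Defaults give a 0.8 s cycle with a 37.5% diastolic fraction and a peak
#' velocity of 0.32 m/s (the E-wave peak); the A-wave peaks at t = 0.75 s.
#' Under atrial fibrillation the atrial contraction is absent, so the A-wave
#' contribution is removed (`a_peak = 0`) while the E branch is unchanged.
#'
#' @param condition `"healthy"` or `"af"`.
#' @param T cycle period (s).
#' @param diastole_fraction fraction of the cycle with the mitral valve
#'   closed.
#' @param e_peak E-wave peak velocity (m/s); this is the cycle maximum.
#' @param a_ratio A-wave peak as a fraction of `e_peak` (healthy only).
#' @param e_center,e_width centre and full width (s) of the E pulse.
#' @param a_center,a_width centre and full width (s) of the A pulse.
#' @return an object of class `laa_waveform`.
#' @export
mitral_waveform <- function(condition = c("healthy", "af"),
                            T = 0.8, diastole_fraction = 0.375,
                            e_peak = 0.32, a_ratio = 0.75,
                            e_center = 0.45, e_width = 0.30,
                            a_center = 0.75, a_width = 0.10) {
  condition <- match.arg(condition)
  stopifnot(T > 0, diastole_fraction > 0, diastole_fraction < 1,
            e_peak > 0, a_ratio >= 0, a_ratio < 1,
            e_width > 0, a_width > 0)
  t_open <- diastole_fraction * T
  if (e_center - e_width / 2 < t_open - 1e-12 || e_center + e_width / 2 > T + 1e-12)
    stop("argument error: E pulse must lie inside the atrial-emptying window")
  if (a_center - a_width / 2 < t_open - 1e-12 || a_center + a_width / 2 > T + 1e-12)
    stop("argument error: A pulse must lie inside the atrial-emptying window")
  a_peak <- if (condition == "af") 0 else a_ratio * e_peak
  wf <- list(T = T, diastole_fraction = diastole_fraction,
             E_peak = e_peak, A_peak = a_peak,
             E_timing = c(center = e_center, width = e_width),
             A_timing = c(center = a_center, width = a_width),
             condition = condition)
  class(wf) <- "laa_waveform"
  wf
}

.cos_pulse <- function(t, center, width) {
  z <- (t - center) / width
  ifelse(abs(z) <= 0.5, cos(pi * z)^2, 0)
}

#' Evaluate the mitral velocity at given times
#'
#' Periodic in the cycle period (times wrap modulo `T`), nonnegative, zero
#' while the mitral valve is closed.
#'
#' @param t times (s); any real values, wrapped into `[0, T)`.
#' @param wf an [mitral_waveform()].
#' @return velocities (m/s), same length as `t`.
#' @export
mitral_velocity <- function(t, wf) {
  stopifnot(inherits(wf, "laa_waveform"))
  if (any(!is.finite(t))) stop("argument error: non-finite time")
  tm <- t %% wf$T
  wf$E_peak * .cos_pulse(tm, wf$E_timing["center"], wf$E_timing["width"]) +
    wf$A_peak * .cos_pulse(tm, wf$A_timing["center"], wf$A_timing["width"])
}

#' Tabulate a waveform for export or plotting
#'
#' @param wf an [mitral_waveform()].
#' @param dt sampling interval (s).
#' @return data.frame with columns `t` and `v` over one cycle.
#' @export
waveform_table <- function(wf, dt = 5e-4) {
  t <- seq(0, wf$T, by = dt)
  data.frame(t = t, v = mitral_velocity(t, wf))
}

#' @export
print.laa_waveform <- function(x, ...) {
  cat(sprintf("laa_waveform [%s]: T = %.3g s, diastole %.1f%%, E peak %.3g m/s, A peak %.3g m/s\n",
              x$condition, x$T, 100 * x$diastole_fraction, x$E_peak, x$A_peak))
  invisible(x)
}

#' Blood properties
#'
#' Density and dynamic viscosity of the working fluid; defaults are
#' representative of normal blood treated as incompressible and Newtonian.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @return an object of class `laa_fluid`.
#' @export
fluid_properties <- function(rho = 1060, mu = 0.0035) {
  if (!is.numeric(rho) || rho <= 0 || !is.numeric(mu) || mu <= 0)
    stop("argument error: rho and mu must be positive")
  structure(list(rho = rho, mu = mu, nu = mu / rho), class = "laa_fluid")
}

#' Reynolds number of the mitral jet
#'
#' `Re = rho * v * D / mu`, evaluated with the peak mitral velocity and the
#' mitral orifice diameter; the laminar flow model assumes this stays below
#' 3000.
#'
#' @param v_peak peak velocity (m/s, >= 0).
#' @param D diameter (m, > 0).
#' @param props a [fluid_properties()].
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(v_peak, D, props = fluid_properties()) {
  if (!is.numeric(D) || any(D <= 0))
    stop("argument error: D must be positive")
  if (!is.numeric(v_peak) || any(v_peak < 0))
    stop("argument error: v_peak must be nonnegative")
  props$rho * v_peak * D / props$mu
}
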