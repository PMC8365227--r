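#' Fluid property presets
#'
#' `"blood"` is the standard Newtonian blood approximation (density 1055
#' kg/m3, viscosity 0.004 Pa s) used for all stented runs; `"validation"` is
#' the benchtop working-fluid preset (1200 kg/m3, 0.0038 Pa s) retained as a
#' named fixture for solver-validation cases.
#'
#' @param name Preset name, or pass `density` / `viscosity` directly.
#' @param density kg/m3. @param viscosity Pa s.
#' @return A `fluid_properties` list with `density`, `viscosity`.
#' @export
fluid_properties <- function(name = c("blood", "validation", "custom"),
                             density = NULL, viscosity = NULL) {
  name <- match.arg(name)
  vals <- switch(name,
                 blood = c(1055, 0.004),
                 validation = c(1200, 0.0038),
                 custom = c(density, viscosity))
  stopifnot(length(vals) == 2, all(vals > 0))
  structure(list(density = vals[1], viscosity = vals[2]),
            class = "fluid_properties")
}

#' Construct a pulsatile inlet waveform
#'
#' The inlet section-mean velocity is a truncated Fourier series,
#' \deqn{U(t) = U_0\Big(1 + \sum_k a_k \cos(k\omega t + \phi_k)\Big),}
#' with \eqn{\omega = 2\pi/T}. The default is an internal-carotid-like shape:
#' period 1 s, mean 0.25 m/s, two harmonics with relative amplitudes 0.4 and
#' 0.1 and phases 0 and pi/2 (velocity stays positive over the whole cycle).
#'
#' @param period Cardiac period, s.
#' @param mean_velocity Cycle-mean section-mean velocity U0, m/s.
#' @param harmonics Two-column matrix or data.frame with columns `amplitude`
#'   (m/s, absolute) and `phase` (rad); row k is mode k.
#' @return A `pulsatile_waveform` list.
#' @export
pulsatile_waveform <- function(period = 1.0, mean_velocity = 0.25,
                               harmonics = NULL) {
  stopifnot(period > 0, mean_velocity > 0)
  if (is.null(harmonics)) {
    harmonics <- data.frame(amplitude = c(0.4, 0.1) * mean_velocity,
                            phase = c(0, pi / 2))
  }
  harmonics <- as.data.frame(harmonics)
  names(harmonics) <- c("amplitude", "phase")
  stopifnot(nrow(harmonics) >= 1)
  structure(list(period = period, mean_velocity = mean_velocity,
                 harmonics = harmonics),
            class = "pulsatile_waveform")
}

#' Womersley number of a waveform in a vessel
#'
#' \eqn{\alpha = (D/2)\sqrt{2\pi\rho/(T\mu)}}, with D the vessel diameter and
#' T the cardiac period (fundamental mode).
#'
#' @param waveform A `pulsatile_waveform`. @param fluid A `fluid_properties`.
#' @param diameter Vessel diameter, m.
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(waveform, fluid, diameter) {
  (diameter / 2) * sqrt(2 * pi * fluid$density /
                          (waveform$period * fluid$viscosity))
}

#' Instantaneous section-mean inlet velocity
#'
#' @param waveform A `pulsatile_waveform`. @param t Time(s), s.
#' @return U(t), m/s (vectorized over `t`).
#' @export
waveform_mean_velocity <- function(waveform, t) {
  om <- 2 * pi / waveform$period
  h <- waveform$harmonics
  out <- rep(waveform$mean_velocity, length(t))
  for (k in seq_len(nrow(h))) {
    out <- out + h$amplitude[k] * cos(k * om * t + h$phase[k])
  }
  out
}

#' Time of peak inlet velocity (systole) within a given cycle
#'
#' Systole is defined as the argmax of the section-mean inlet velocity;
#' located by dense sampling plus local refinement with [stats::optimize()].
#'
#' @param waveform A `pulsatile_waveform`.
#' @param cycle Cycle index (1-based); default 3, the sampling cycle.
#' @return Time of peak velocity, s.
#' @export
systole_time <- function(waveform, cycle = 3L) {
  t0 <- (cycle - 1) * waveform$period
  ts <- seq(t0, t0 + waveform$period, length.out = 2001)
  tbest <- ts[which.max(waveform_mean_velocity(waveform, ts))]
  w <- waveform$period / 1000
  opt <- stats::optimize(function(t) waveform_mean_velocity(waveform, t),
                         lower = max(t0, tbest - w), upper = tbest + w,
                         maximum = TRUE)
  opt$maximum
}

# complex shape function of one oscillatory channel mode:
# g(Y) = (1 - cosh(l Y)/cosh(l a)) / (1 - tanh(l a)/(l a)),  l = sqrt(i k w / nu)
# normalized so that the section average of g over [-a, a] is exactly 1.
womersley_mode_shape <- function(y_centered, half_height, k, omega, nu) {
  lam <- sqrt(complex(real = 0, imaginary = k * omega / nu))
  la <- lam * half_height
  denom <- 1 - tanh(la) / la
  (1 - cosh(lam * y_centered) / cosh(la)) / denom
}

#' Analytic oscillatory-channel (planar Womersley) inlet profile
#'
#' Exact closed-form velocity profile of fully developed pulsatile flow
#' between parallel plates a distance `channel_height` apart, the planar
#' analogue of Womersley pipe flow. The steady component is the plane
#' Poiseuille parabola with section mean `mean_velocity`; each harmonic k
#' contributes
#' \deqn{u_k(y,t) = \Re\!\left[A_k e^{i\phi_k}\,
#'   \frac{1 - \cosh(\lambda_k \tilde y)/\cosh(\lambda_k a)}
#'        {1 - \tanh(\lambda_k a)/(\lambda_k a)}\, e^{ik\omega t}\right],
#'   \qquad \lambda_k = \sqrt{i k \omega/\nu},}
#' with \eqn{a} the half-height and \eqn{\tilde y} the wall-normal coordinate
#' measured from the centerline. Each mode is normalized so its section
#' average equals its share of the waveform: the section average of the full
#' profile equals `waveform_mean_velocity(waveform, t)` exactly.
#'
#' @param waveform A `pulsatile_waveform`. @param fluid A `fluid_properties`.
#' @param channel_height Channel height (vessel diameter in 2D), m.
#' @param t Time, s (scalar).
#' @param y Wall-normal positions in `[0, channel_height]` (m) at which to
#'   evaluate; defaults to 64 interior points.
#' @return Numeric vector of axial velocities, m/s.
#' @export
womersley_inlet_profile <- function(waveform, fluid, channel_height, t,
                                    y = NULL) {
  stopifnot(t >= 0, channel_height > 0)
  if (is.null(y)) y <- (seq_len(64) - 0.5) / 64 * channel_height
  a <- channel_height / 2
  yc <- y - a
  nu <- fluid$viscosity / fluid$density
  om <- 2 * pi / waveform$period
  u <- 1.5 * waveform$mean_velocity * (1 - (yc / a)^2)
  h <- waveform$harmonics
  for (k in seq_len(nrow(h))) {
    g <- womersley_mode_shape(yc, a, k, om, nu)
    u <- u + Re(h$amplitude[k] * exp(1i * h$phase[k]) * g *
                  exp(1i * k * om * t))
  }
  u
}
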