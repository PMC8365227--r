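#' Screen loss coefficients
#'
#' Homogenized porous-screen closure standing in for resolved stent struts:
#' across a screened neck face the device exerts the pressure jump
#' \deqn{\Delta p = \frac{\mu\,w}{\kappa(s)} u_n
#'       + \tfrac12 \rho K(s)\,|u_n|\,u_n,}
#' with solidity \eqn{s}, wire diameter \eqn{w}, inertial loss coefficient
#' \eqn{K(s) = c_1\, s/(1-s)^2} (screen-drag form) and Kozeny-type
#' permeability \eqn{\kappa(s) = c_2\, w^2 (1-s)^3/s^2}. Both terms vanish at
#' `s = 0` and diverge as `s -> 1`; `K(s)` is strictly increasing on
#' `[0, 1)`.
#'
#' @param s Solidity in \[0, 1).
#' @param c1,c2 Dimensionless scale factors (defaults 1).
#' @param w Screen wire diameter / thickness, m.
#' @param mu Dynamic viscosity, Pa s.
#' @return List with `K` (inertial loss coefficient) and `a_visc`
#'   (`mu * w / kappa`, Pa s/m), vectorized over `s`.
#' @export
screen_loss <- function(s, c1 = 1, c2 = 1, w = 1e-4, mu = 0.004) {
  stopifnot(all(s >= 0), all(s < 1))
  list(K = c1 * s / (1 - s)^2,
       a_visc = ifelse(s > 0, mu * s^2 / (c2 * w * (1 - s)^3), 0))
}

#' Build a plain rectangular channel grid (no sac)
#'
#' Validation-fixture geometry: a straight channel, i.e. the parent vessel
#' with a zero-width neck. All cells are `fluid_parent`; there are no neck
#' faces.
#'
#' @param length Channel length, m. @param height Channel height, m.
#' @param spacing Grid spacing, m.
#' @return A `flow_grid`.
#' @export
channel_grid <- function(length, height, spacing) {
  stopifnot(length > 0, height > 0, spacing > 0)
  nx <- as.integer(round(length / spacing))
  ny <- as.integer(round(height / spacing))
  structure(
    list(spacing = spacing, nx = nx, ny = ny, ny_parent = ny,
         cell_mask = matrix(MASK_PARENT, nx, ny), neck_faces = integer(0),
         geom = NULL, plane_indices = NULL, v_m = NULL),
    class = "flow_grid")
}

# inlet boundary arrays for the C++ core: steady parabola + complex
# coefficients of each Womersley mode at the inlet u-face heights
inlet_arrays <- function(grid, fluid, waveform) {
  h <- grid$spacing
  ny <- grid$ny
  H <- grid$ny_parent * h
  a <- H / 2
  j_in <- which(grid$cell_mask[1, ] != MASK_SOLID & seq_len(ny) <= grid$ny_parent)
  yc <- (j_in - 0.5) * h - a
  steady <- numeric(ny)
  steady[j_in] <- 1.5 * waveform$mean_velocity * (1 - (yc / a)^2)
  K <- nrow(waveform$harmonics)
  re <- matrix(0, ny, K)
  im <- matrix(0, ny, K)
  nu <- fluid$viscosity / fluid$density
  om <- 2 * pi / waveform$period
  for (k in seq_len(K)) {
    g <- womersley_mode_shape(yc, a, k, om, nu)
    coefk <- waveform$harmonics$amplitude[k] *
      exp(1i * waveform$harmonics$phase[k]) * g
    re[j_in, k] <- Re(coefk)
    im[j_in, k] <- Im(coefk)
  }
  list(steady = steady, re = re, im = im, omega = om)
}

#' Run a pulsatile simulation over whole cardiac cycles
#'
#' Integrates the 2D incompressible Navier-Stokes equations from rest over
#' `cycles` cardiac periods with a Womersley inlet, zero-pressure outlet and
#' rigid no-slip walls, using an explicit upwind/projection scheme
#' (time step `cfl_safety * min(advective, diffusive)` limit, recomputed
#' every step; 5-point pressure Poisson solved by preconditioned conjugate
#' gradients to relative residual `cg_tol`). If the grid has neck faces and
#' a screen is given, an MCR-dependent momentum sink acts on those faces
#' (see [screen_loss()]). There is no randomness anywhere: identical
#' configurations give identical output.
#'
#' The systolic snapshot is the state at the time of peak inlet section-mean
#' velocity within the *last* cycle; the same phase of the previous cycle is
#' also recorded for periodicity checks.
#'
#' @param grid A `flow_grid` (from [rasterize()] / [place_planes()] or
#'   [channel_grid()]).
#' @param fluid A `fluid_properties`.
#' @param waveform A `pulsatile_waveform`.
#' @param screen `NULL` for no device, a single solidity in \[0, 1) applied
#'   uniformly over the neck faces, or a numeric vector with one solidity
#'   per neck face.
#' @param cycles Number of cardiac periods to integrate (default 3).
#' @param record_times Extra times (s) at which to store snapshots; the two
#'   systolic phases and the end time are always recorded.
#' @param c1,c2 Screen loss-coefficient scales. @param w_screen Screen wire
#'   diameter, m.
#' @param cfl_safety,cg_tol,cg_maxit Numerical controls.
#' @return A `flow_run`: list with `snapshots` (each `t`, `u`, `v`, `p`),
#'   `systolic` (snapshot at systole of the last cycle),
#'   `systolic_previous`, `t_systole`, flux/divergence diagnostics and the
#'   full configuration manifest.
#' @export
run_cycles <- function(grid, fluid, waveform, screen = NULL, cycles = 3L,
                       record_times = NULL, c1 = 1, c2 = 1,
                       w_screen = 1e-4, cfl_safety = 0.4, cg_tol = 1e-8,
                       cg_maxit = 50000L) {
  stopifnot(inherits(grid, "flow_grid"), inherits(fluid, "fluid_properties"),
            inherits(waveform, "pulsatile_waveform"), cycles >= 1)
  t_sys <- systole_time(waveform, cycle = cycles)
  t_end <- cycles * waveform$period
  rec <- sort(unique(c(record_times,
                       if (cycles >= 2) t_sys - waveform$period,
                       t_sys, t_end)))
  stopifnot(all(rec >= 0), all(rec <= t_end + 1e-12))

  screen_i <- grid$neck_faces
  screen_s <- numeric(length(screen_i))
  if (!is.null(screen) && length(screen_i)) {
    if (length(screen) == 1) screen_s[] <- screen
    else {
      stopifnot(length(screen) == length(screen_i))
      screen_s <- as.numeric(screen)
    }
    stopifnot(all(screen_s >= 0), all(screen_s < 1))
  }

  inl <- inlet_arrays(grid, fluid, waveform)
  res <- .ns_run_cpp(grid$cell_mask, grid$spacing, grid$ny_parent,
                     fluid$density, fluid$viscosity,
                     inl$steady, inl$re, inl$im, inl$omega,
                     as.integer(screen_i), screen_s, c1, c2, w_screen,
                     rec, cfl_safety, cg_tol, as.integer(cg_maxit))

  snaps <- res$snapshots
  ts <- vapply(snaps, function(s) s$t, numeric(1))
  pick <- function(t0) snaps[[which.min(abs(ts - t0))]]
  structure(
    list(snapshots = snaps,
         record_t = res$record_t,
         systolic = pick(t_sys),
         systolic_previous = if (cycles >= 2) pick(t_sys - waveform$period),
         t_systole = t_sys,
         inlet_flux = res$inlet_flux,
         outlet_flux = res$outlet_flux,
         max_divergence = res$max_divergence,
         steps = res$steps, cg_it_max = res$cg_it_max,
         cg_it_total = res$cg_it_total,
         grid = grid, fluid = fluid, waveform = waveform,
         manifest = list(
           cycles = cycles, screen = screen, c1 = c1, c2 = c2,
           w_screen = w_screen, cfl_safety = cfl_safety, cg_tol = cg_tol,
           spacing = grid$spacing, t_systole = t_sys,
           fluid = unclass(fluid),
           waveform = list(period = waveform$period,
                           mean_velocity = waveform$mean_velocity,
                           harmonics = waveform$harmonics),
           depth_convention = "unit depth = parent diameter")),
    class = "flow_run")
}

#' @export
print.flow_run <- function(x, ...) {
  cat(sprintf(
    "flow_run: %d steps, systole at t = %.4g s, %d snapshots\n",
    as.integer(x$steps), x$t_systole, length(x$snapshots)))
  n <- length(x$inlet_flux)
  cat(sprintf("  inlet flux %.4g m^2/s, |in-out|/in = %.2g, max div %.2g\n",
              x$inlet_flux[n],
              abs(x$inlet_flux[n] - x$outlet_flux[n]) /
                max(abs(x$inlet_flux[n]), 1e-300),
              x$max_divergence[n]))
  invisible(x)
}

#' Interpolated cell-centered velocity magnitude of a snapshot
#'
#' @param snapshot One element of a `flow_run`'s `snapshots`.
#' @param grid The matching `flow_grid`.
#' @return nx x ny matrix of speeds (m/s), `NA` on solid cells.
#' @export
speed_field <- function(snapshot, grid) {
  u <- snapshot$u; v <- snapshot$v
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (u[seq_len(nx), , drop = FALSE] +
                 u[seq_len(nx) + 1L, , drop = FALSE])
  vc <- 0.5 * (v[, seq_len(ny), drop = FALSE] +
                 v[, seq_len(ny) + 1L, drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  sp[grid$cell_mask == MASK_SOLID] <- NA_real_
  sp
}

#' Export a snapshot as a legacy-ASCII VTK file
#'
#' Writes cell-centered speed and pressure as `STRUCTURED_POINTS` scalars.
#'
#' @param snapshot A snapshot. @param grid The `flow_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(snapshot, grid, path) {
  sp <- speed_field(snapshot, grid)
  sp[is.na(sp)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("aneuflow snapshot t=%g", snapshot$t), "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", grid$spacing, grid$spacing),
               sprintf("POINT_DATA %d", grid$nx * grid$ny),
               "SCALARS speed double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.vector(sp), digits = 8), collapse = " "), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.vector(snapshot$p), digits = 8),
                   collapse = " "), con)
  invisible(path)
}
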