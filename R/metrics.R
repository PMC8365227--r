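#' Area-averaged summary of a measurement plane
#'
#' For planes A (inlet side) and B (outlet side): area-averaged normal
#' velocity and pressure over the parent-lumen cross-section at the plane's
#' face column. Pressures are averaged over the two cell columns adjacent to
#' the face. Areas use the package's unit-depth convention (depth = parent
#' diameter).
#'
#' @param snapshot A `flow_run` snapshot. @param grid A `flow_grid` with
#'   planes placed (see [place_planes()]).
#' @param plane `"A"` or `"B"`.
#' @return A `plane_summary`: list with `v_avg` (m/s), `p_avg` (Pa), `area`
#'   (m^2), `plane_id`.
#' @export
plane_summary <- function(snapshot, grid, plane = c("A", "B")) {
  plane <- match.arg(plane)
  if (is.null(grid$plane_indices)) {
    stop("configuration error: planes not placed on this grid",
         call. = FALSE)
  }
  i_face <- if (plane == "A") grid$plane_indices$a else grid$plane_indices$b
  h <- grid$spacing
  depth <- grid$geom$parent_diameter
  j <- seq_len(grid$ny_parent)
  u_face <- snapshot$u[i_face + 1L, j]      # face column, R 1-based
  cols <- unique(pmin(pmax(c(i_face, i_face + 1L), 1L), grid$nx))
  p_face <- rowMeans(cbind(snapshot$p[cols[1], j],
                           snapshot$p[cols[length(cols)], j]))
  structure(list(v_avg = mean(u_face), p_avg = mean(p_face),
                 area = grid$ny_parent * h * depth, plane_id = plane),
            class = "plane_summary")
}

#' Energy loss between the inlet and outlet planes
#'
#' Volumetric rate of mechanical-energy loss of the flow between plane A and
#' plane B,
#' \deqn{EL = \frac{v_{in} A \left[(\tfrac12\rho v_{in}^2 + P_{in}) -
#'   (\tfrac12\rho v_{out}^2 + P_{out})\right]}{V_m},}
#' where \eqn{V_m} is the fluid volume of the model between the planes
#' (including the sac), \eqn{A} the inlet-plane area, and velocities and
#' pressures are the area-averaged plane values. Units W/m3.
#'
#' @param inlet,outlet `plane_summary` objects for planes A and B.
#' @param rho Fluid density, kg/m3.
#' @param v_m Inter-plane fluid volume, m^3 (must be positive).
#' @return Energy loss, W/m3.
#' @export
energy_loss <- function(inlet, outlet, rho, v_m) {
  if (!is.numeric(v_m) || v_m <= 0) {
    stop("domain error: V_m must be positive", call. = FALSE)
  }
  stopifnot(inlet$area > 0)
  head_in <- 0.5 * rho * inlet$v_avg^2 + inlet$p_avg
  head_out <- 0.5 * rho * outlet$v_avg^2 + outlet$p_avg
  inlet$v_avg * inlet$area * (head_in - head_out) / v_m
}

#' Inflow rate into the aneurysm through plane C
#'
#' Integrates only the sac-directed (positive into the sac) normal velocity
#' over the neck faces, times face length and the unit-depth convention
#' (depth = parent diameter); outflow faces are excluded. Net flux through a
#' closed sac is ~0 by incompressibility, so the one-sided flux is the
#' meaningful "inflow rate". Reported in mm3/s.
#'
#' @param snapshot A snapshot. @param grid A `flow_grid` with planes placed.
#' @return Inflow rate, mm3/s.
#' @export
neck_inflow_rate <- function(snapshot, grid) {
  pc <- plane_c_faces(grid)
  vn <- snapshot$v[pc$i + 1L, pc$j + 1L]     # v stored on (ny+1) face rows
  depth <- grid$geom$parent_diameter
  sum(pmax(vn, 0)) * grid$spacing * depth * 1e9
}

#' Area-averaged velocity magnitude on plane C
#'
#' Velocity magnitude (normal component plus interpolated tangential
#' component) averaged over the open neck faces.
#'
#' @param snapshot A snapshot. @param grid A `flow_grid` with planes placed.
#' @return Average speed, m/s.
#' @export
neck_average_velocity <- function(snapshot, grid) {
  pc <- plane_c_faces(grid)
  vn <- snapshot$v[pc$i + 1L, pc$j + 1L]
  # tangential (axial) component interpolated to the v-face centers
  ut <- 0.25 * (snapshot$u[pc$i + 1L, pc$j] + snapshot$u[pc$i + 2L, pc$j] +
                snapshot$u[pc$i + 1L, pc$j + 1L] +
                snapshot$u[pc$i + 2L, pc$j + 1L])
  mean(sqrt(vn^2 + ut^2))
}

plane_c_faces <- function(grid) {
  if (is.null(grid$plane_indices) || !length(grid$plane_indices$c$i_faces)) {
    stop("configuration error: plane C (neck) not defined on this grid",
         call. = FALSE)
  }
  list(i = grid$plane_indices$c$i_faces, j = grid$plane_indices$c$j)
}

#' Reduction rate of a hemodynamic parameter versus the unstented control
#'
#' `100 * (control - device) / control`, in percent.
#'
#' @param control_value Unstented control value (> 0).
#' @param device_value Stented value.
#' @return Percent reduction (vectorized over `device_value`).
#' @export
reduction_rate <- function(control_value, device_value) {
  if (!is.numeric(control_value) || any(control_value <= 0)) {
    stop("domain error: control value must be positive", call. = FALSE)
  }
  100 * (control_value - device_value) / control_value
}

#' Ratio of sac-interior to neck-plane speed
#'
#' Scalar summary of the qualitative "separation of dome and neck
#' hemodynamics": the mean speed over sac-interior cells divided by the mean
#' speed on plane C. Small values indicate a quiescent dome decoupled from
#' the neck flow.
#'
#' @param snapshot A snapshot. @param grid A `flow_grid` with planes placed.
#' @return Dimensionless ratio.
#' @export
sac_to_neck_speed_ratio <- function(snapshot, grid) {
  sp <- speed_field(snapshot, grid)
  sac_mean <- mean(sp[grid$cell_mask == MASK_SAC], na.rm = TRUE)
  vneck <- neck_average_velocity(snapshot, grid)
  sac_mean / vneck
}

#' Hemodynamic summary of one systolic flow field
#'
#' Computes the three study metrics (energy loss, average neck velocity,
#' inflow rate) from the systolic snapshot of a run. Reduction rates are
#' filled in by [run_study()] once the control row is known.
#'
#' @param run A `flow_run` on a grid with planes placed.
#' @param mcr Metal coverage rate of the configuration (fraction).
#' @param config_label Row label.
#' @return A one-row `data.frame` (class `hemodynamic_summary`).
#' @export
hemodynamic_summary <- function(run, mcr = 0, config_label = "control") {
  stopifnot(inherits(run, "flow_run"))
  grid <- run$grid
  snap <- run$systolic
  pa <- plane_summary(snap, grid, "A")
  pb <- plane_summary(snap, grid, "B")
  out <- data.frame(
    config_label = config_label,
    mcr = mcr,
    energy_loss = energy_loss(pa, pb, run$fluid$density, grid$v_m),
    avg_velocity = neck_average_velocity(snap, grid),
    inflow_rate = neck_inflow_rate(snap, grid),
    sac_neck_ratio = sac_to_neck_speed_ratio(snap, grid),
    el_reduction_pct = NA_real_,
    vel_reduction_pct = NA_real_,
    inflow_reduction_pct = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("hemodynamic_summary", class(out))
  out
}
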