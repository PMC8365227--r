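# shared test helpers: small independent oracles and field utilities

l2_rel <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# shoelace area of a polygon given as x/y vectors
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# polygonized fluid region of the idealized geometry between two axial
# stations: parent strip plus the sac boundary arc above the wall line
fluid_polygon_between <- function(geom, xa, xb, n_arc = 4000) {
  D <- geom$parent_diameter
  cx <- geom$neck_axial_position
  cy <- D + geom$sac_center_offset
  R <- geom$sac_radius
  # arc above the wall line, traversed from downstream to upstream edge
  th0 <- atan2(D - cy, (cx + geom$neck_width / 2) - cx)
  th1 <- atan2(D - cy, (cx - geom$neck_width / 2) - cx)
  th <- seq(th0, th1 + 2 * pi, length.out = n_arc) # go the long way (above)
  ax <- cx + R * cos(th)
  ay <- cy + R * sin(th)
  keep <- ay >= D - 1e-12
  # wall segments between plane stations and neck edges close the polygon
  x <- c(xa, xb, cx + geom$neck_width / 2, ax[keep], cx - geom$neck_width / 2,
         xa)
  y <- c(0, 0, D, ay[keep], D, 0)
  list(x = x, y = y)
}

# tiny synthetic grid + snapshot builder for metric tests: a channel with a
# rectangular "sac" notch so that plane C exists
toy_neck_grid <- function(nx = 50, ny_parent = 8, ny_sac = 6,
                          neck_cells = 6, h = 1e-4) {
  ny <- ny_parent + ny_sac
  mask <- matrix(0L, nx, ny)
  mask[, seq_len(ny_parent)] <- 1L
  i0 <- (nx - neck_cells) %/% 2
  sac_cols <- (i0 + 1):(i0 + neck_cells)
  mask[sac_cols, (ny_parent + 1):ny] <- 2L
  mask[sac_cols, ny_parent] <- 3L
  geom <- build_sidewall_aneurysm(parent_diameter = ny_parent * h,
                                  sac_radius = 10 * h,
                                  neck_width = neck_cells * h,
                                  parent_length = nx * h,
                                  neck_axial_position = (i0 + neck_cells / 2) * h)
  grid <- structure(
    list(spacing = h, nx = nx, ny = ny, ny_parent = ny_parent,
         cell_mask = mask, neck_faces = as.integer(sac_cols - 1L),
         geom = geom,
         plane_indices = list(a = 2L, b = nx - 2L,
                              c = list(j = ny_parent,
                                       i_faces = as.integer(sac_cols - 1L))),
         v_m = sum(mask != 0L) * h^2 * geom$parent_diameter),
    class = "flow_grid")
  grid
}

zero_snapshot <- function(grid) {
  list(t = 0,
       u = matrix(0, grid$nx + 1, grid$ny),
       v = matrix(0, grid$nx, grid$ny + 1),
       p = matrix(0, grid$nx, grid$ny))
}

# fast waveform for cheap solver plumbing tests (not the study waveform)
fast_waveform <- function() {
  pulsatile_waveform(period = 0.25, mean_velocity = 0.25,
                     harmonics = data.frame(amplitude = 0.1, phase = 0))
}
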