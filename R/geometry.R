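#' Build an idealized sidewall saccular aneurysm geometry
#'
#' Constructs the planar (2D) idealization used throughout the package: a
#' straight parent channel of height `parent_diameter` with a circular sac of
#' radius `sac_radius` sitting on the upper wall, communicating with the lumen
#' through a neck of width `neck_width`. The perpendicular distance of the sac
#' center from the wall line (`sac_center_offset`) is not free: it is solved
#' from the circle-chord relation so that the sac circle intersects the wall
#' in a chord of exactly `neck_width`,
#' \deqn{d = \sqrt{R^2 - (W/2)^2},}
#' where \eqn{R} is the sac radius and \eqn{W} the neck width.
#'
#' All lengths are in meters. The default dimensions correspond to a large
#' internal-carotid-artery aneurysm: sac radius 5 mm, neck 5.27 mm, parent
#' artery 4 mm.
#'
#' @param parent_diameter Parent vessel diameter (channel height), m.
#' @param sac_radius Sac radius, m.
#' @param neck_width Neck (chord) width, m. Must satisfy
#'   `neck_width <= 2 * sac_radius`; equality gives the hemispherical-cap
#'   limit with the sac center on the wall.
#' @param parent_length Axial length of the parent channel, m. Must be at
#'   least `5 * parent_diameter` (entrance-length allowance).
#' @param neck_axial_position Axial position of the neck midpoint measured
#'   from the inlet, m. Defaults to mid-channel, which makes the geometry
#'   axially symmetric about the neck.
#'
#' @return An object of class `aneurysm_geometry`: a list with fields
#'   `parent_diameter`, `sac_radius`, `neck_width`, `sac_center_offset`,
#'   `parent_length`, `neck_axial_position`.
#' @examples
#' geom <- build_sidewall_aneurysm(4e-3, 5e-3, 5.27e-3, 40e-3)
#' geom$sac_center_offset * 1e3  # ~4.249 mm
#' @export
build_sidewall_aneurysm <- function(parent_diameter = 4e-3,
                                    sac_radius = 5e-3,
                                    neck_width = 5.27e-3,
                                    parent_length = 40e-3,
                                    neck_axial_position = parent_length / 2) {
  stopifnot(parent_diameter > 0, sac_radius > 0, neck_width > 0,
            parent_length > 0)
  if (neck_width > 2 * sac_radius) {
    stop("geometry infeasible: neck_width exceeds the sac diameter, ",
         "no chord of that width exists", call. = FALSE)
  }
  if (parent_length < 5 * parent_diameter) {
    stop("parent_length must be at least 5 parent diameters ",
         "(entrance-length allowance)", call. = FALSE)
  }
  half_neck <- neck_width / 2
  if (neck_axial_position - half_neck <= 0 ||
      neck_axial_position + half_neck >= parent_length) {
    stop("neck does not fit inside the parent segment", call. = FALSE)
  }
  offset <- sqrt(max(sac_radius^2 - half_neck^2, 0))
  structure(
    list(parent_diameter = parent_diameter,
         sac_radius = sac_radius,
         neck_width = neck_width,
         sac_center_offset = offset,
         parent_length = parent_length,
         neck_axial_position = neck_axial_position),
    class = "aneurysm_geometry")
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat("Idealized sidewall aneurysm (2D planar section)\n")
  cat(sprintf("  parent artery : %.3g mm diameter x %.3g mm length\n",
              x$parent_diameter * 1e3, x$parent_length * 1e3))
  cat(sprintf("  sac           : radius %.3g mm, center %.4g mm above wall\n",
              x$sac_radius * 1e3, x$sac_center_offset * 1e3))
  cat(sprintf("  neck          : %.3g mm chord at x = %.3g mm\n",
              x$neck_width * 1e3, x$neck_axial_position * 1e3))
  invisible(x)
}

#' Analytic fluid areas of the idealized geometry
#'
#' Closed forms used as oracles for the raster: the parent channel is a
#' rectangle, and the sac contributes the major circular segment above the
#' wall chord, \eqn{\pi R^2 - (R^2 \arccos(d/R) - d\,W/2)} with \eqn{d} the
#' sac center offset.
#'
#' @param geom An `aneurysm_geometry`.
#' @return List with `parent_area`, `sac_area`, `total_area` (m^2).
#' @export
analytic_fluid_areas <- function(geom) {
  stopifnot(inherits(geom, "aneurysm_geometry"))
  R <- geom$sac_radius
  d <- geom$sac_center_offset
  minor_segment <- R^2 * acos(min(d / R, 1)) - d * geom$neck_width / 2
  sac <- pi * R^2 - minor_segment
  parent <- geom$parent_length * geom$parent_diameter
  list(parent_area = parent, sac_area = sac, total_area = parent + sac)
}

# cell_mask codes shared with the C++ solver
MASK_SOLID <- 0L
MASK_PARENT <- 1L
MASK_SAC <- 2L
MASK_NECK <- 3L

#' Rasterize an aneurysm geometry onto a staggered computational grid
#'
#' Builds the cell-centered mask used by the flow solver. Coordinates: x
#' axial (flow direction), y cross-stream, origin at the inlet/lower wall.
#' The parent channel occupies cell rows below the wall line `y = D` (D =
#' parent diameter, snapped to the nearest grid line); the sac occupies cells
#' above that line whose centers fall inside the sac circle. The open neck is
#' the set of vertical faces on the wall line lying under the chord. Parent
#' cells immediately below an open neck face are labeled `neck_interface`;
#' they behave as ordinary fluid but mark where the porous screen acts.
#'
#' @param geom An `aneurysm_geometry`.
#' @param spacing Grid spacing, m. Must be at most `parent_diameter / 20`
#'   (resolution floor) and divide the parent diameter to within 1%.
#' @return An object of class `flow_grid`: list with `spacing`, `nx`, `ny`,
#'   `ny_parent` (index of the wall-line face row), `cell_mask` (nx x ny
#'   integer matrix, codes 0 solid / 1 fluid_parent / 2 fluid_sac /
#'   3 neck_interface), `neck_faces` (0-based i indices of open vertical
#'   faces on the wall line), `geom`, and (after [place_planes()])
#'   `plane_indices` and `v_m`.
#' @export
rasterize <- function(geom, spacing) {
  stopifnot(inherits(geom, "aneurysm_geometry"), spacing > 0)
  if (spacing > geom$parent_diameter / 20 + 1e-12) {
    stop("resolution error: spacing must be <= parent_diameter / 20",
         call. = FALSE)
  }
  h <- spacing
  ny_parent <- as.integer(round(geom$parent_diameter / h))
  if (abs(ny_parent * h - geom$parent_diameter) > 0.01 * geom$parent_diameter) {
    stop("spacing must divide the parent diameter (within 1%)", call. = FALSE)
  }
  nx <- as.integer(round(geom$parent_length / h))
  y_top <- geom$parent_diameter + geom$sac_center_offset + geom$sac_radius
  ny <- as.integer(ceiling(y_top / h))

  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  y_wall <- ny_parent * h
  cx <- geom$neck_axial_position
  cy <- y_wall + geom$sac_center_offset
  R2 <- geom$sac_radius^2

  mask <- matrix(MASK_SOLID, nrow = nx, ncol = ny)
  mask[, seq_len(ny_parent)] <- MASK_PARENT
  if (ny > ny_parent) {
    above <- (ny_parent + 1):ny
    in_sac <- outer(xc, yc[above],
                    function(x, y) (x - cx)^2 + (y - cy)^2 < R2)
    mask[, above][in_sac] <- MASK_SAC
  }

  # open neck faces: vertical faces on the wall line with fluid on both sides
  neck_faces <- integer(0)
  if (ny > ny_parent) {
    open <- which(mask[, ny_parent] != MASK_SOLID &
                  mask[, ny_parent + 1] == MASK_SAC)
    neck_faces <- open - 1L           # 0-based for the solver
    mask[open, ny_parent] <- MASK_NECK
  }

  structure(
    list(spacing = h, nx = nx, ny = ny, ny_parent = ny_parent,
         cell_mask = mask, neck_faces = neck_faces, geom = geom,
         plane_indices = NULL, v_m = NULL),
    class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("flow_grid: %d x %d cells at %.3g mm (%d fluid, %d neck faces)\n",
              x$nx, x$ny, x$spacing * 1e3, sum(x$cell_mask != MASK_SOLID),
              length(x$neck_faces)))
  if (!is.null(x$plane_indices)) {
    cat(sprintf("  planes A/B at columns %d/%d, V_m = %.4g mm^3\n",
                x$plane_indices$a, x$plane_indices$b, x$v_m * 1e9))
  }
  invisible(x)
}

#' Raster fluid area by mask label
#'
#' @param grid A `flow_grid`.
#' @return List with `parent_area`, `sac_area`, `total_area` (m^2);
#'   `neck_interface` cells count toward the parent (they are parent fluid).
#' @export
raster_fluid_areas <- function(grid) {
  stopifnot(inherits(grid, "flow_grid"))
  a <- grid$spacing^2
  parent <- sum(grid$cell_mask == MASK_PARENT | grid$cell_mask == MASK_NECK) * a
  sac <- sum(grid$cell_mask == MASK_SAC) * a
  list(parent_area = parent, sac_area = sac, total_area = parent + sac)
}

#' Place the measurement planes A, B and C
#'
#' Plane A is an upstream cross-section of the parent channel, plane B a
#' downstream one, plane C the neck chord itself. Offsets are measured from
#' the neck *edges* (not the midpoint); the defaults put each plane one
#' parent diameter away from its neck edge. The inter-plane fluid volume
#' `V_m` (fluid area between the A and B stations times the unit-depth
#' convention, depth = parent diameter) is stored on the grid; it includes
#' the sac.
#'
#' @param grid A `flow_grid`.
#' @param a_offset Distance of plane A upstream of the upstream neck edge, m.
#' @param b_offset Distance of plane B downstream of the downstream neck
#'   edge, m.
#' @return The grid with `plane_indices` (1-based face-column indices `a`,
#'   `b`, and `c = list(j, i_faces)`) and `v_m` (m^3) filled in.
#' @export
place_planes <- function(grid,
                         a_offset = grid$geom$parent_diameter,
                         b_offset = grid$geom$parent_diameter) {
  stopifnot(inherits(grid, "flow_grid"))
  g <- grid$geom
  h <- grid$spacing
  xa <- g$neck_axial_position - g$neck_width / 2 - a_offset
  xb <- g$neck_axial_position + g$neck_width / 2 + b_offset
  if (xa < 0 || xb > g$parent_length) {
    stop("plane placement error: plane A or B falls outside the domain",
         call. = FALSE)
  }
  ia <- as.integer(round(xa / h))  # face column index, 0..nx
  ib <- as.integer(round(xb / h))
  if (ia >= ib) stop("plane placement error: A must lie upstream of B",
                     call. = FALSE)
  # planes A/B must cross pure parent lumen, outside the neck opening
  if (a_offset < 0 || b_offset < 0) {
    stop("plane placement error: plane intersects the sac/neck opening",
         call. = FALSE)
  }

  cols <- (ia + 1L):ib               # cells with centers between the planes
  fluid_cells <- sum(grid$cell_mask[cols, ] != MASK_SOLID)
  depth <- g$parent_diameter         # unit-depth reporting convention
  v_m <- fluid_cells * h^2 * depth

  grid$plane_indices <- list(
    a = ia, b = ib,
    c = list(j = grid$ny_parent, i_faces = grid$neck_faces))
  grid$v_m <- v_m
  grid
}

#' Export a grid mask as a legacy-ASCII VTK structured-points file
#'
#' Writes the cell mask as a `STRUCTURED_POINTS` dataset for inspection in
#' ParaView or similar. Plain text; meters as native units.
#'
#' @param grid A `flow_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_mask <- function(grid, path) {
  stopifnot(inherits(grid, "flow_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuflow cell mask", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", grid$spacing, grid$spacing),
               sprintf("POINT_DATA %d", grid$nx * grid$ny),
               "SCALARS mask int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$cell_mask), collapse = " "), con)
  invisible(path)
}
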