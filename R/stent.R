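#' Low-level stripe-lattice pattern constructor
#'
#' A stent pattern is represented as a union of periodic *stripe families* on
#' the unrolled neck rectangle (x axial, y circumferential): family k covers
#' all points whose signed distance along its unit normal, taken modulo the
#' perpendicular spacing, falls within half the stripe width of a lattice
#' line. Struts of a laser-cut cell lattice and wires of a braid are both
#' stripe families; overlapping layers concatenates families with shifted
#' phases.
#'
#' This constructor performs no device-level validation and is mainly useful
#' for tests and custom lattices; see [generate_pattern()] for the validated
#' device entry point.
#'
#' @param normals Two-column matrix of unit normals (one row per family).
#' @param spacings Perpendicular spacing of each family, m.
#' @param widths Stripe width of each family, m.
#' @param phases Phase offset of each family along its normal, m.
#' @param device_class Label, e.g. `"custom"`.
#' @param ... Extra fields stored on the object (device parameters).
#' @return A `stent_pattern` object.
#' @export
stripe_pattern <- function(normals, spacings, widths, phases = NULL,
                           device_class = "custom", ...) {
  normals <- matrix(as.numeric(normals), ncol = 2)
  nf <- nrow(normals)
  if (is.null(phases)) phases <- numeric(nf)
  stopifnot(length(spacings) == nf, length(widths) == nf,
            length(phases) == nf, all(spacings > 0), all(widths >= 0))
  nrm <- sqrt(rowSums(normals^2))
  normals <- normals / nrm
  structure(
    c(list(device_class = device_class,
           families = data.frame(nx = normals[, 1], ny = normals[, 2],
                                 spacing = spacings, width = widths,
                                 phase = phases),
           layers = 1L,
           layer_offsets = matrix(0, 1, 2),
           compaction_factor = 1),
      list(...)),
    class = "stent_pattern")
}

#' Pattern with no metal (unstented control)
#' @return A `stent_pattern` with zero families.
#' @export
empty_pattern <- function() {
  p <- stripe_pattern(matrix(numeric(0), 0, 2), numeric(0), numeric(0),
                      device_class = "none")
  p
}

braid_families <- function(wire_diameter, n_wires, braid_angle_deg,
                           circumference) {
  beta <- braid_angle_deg * pi / 180
  s_c <- circumference / (n_wires / 2)   # circumferential spacing per family
  d <- s_c * cos(beta)                   # perpendicular spacing
  list(normals = rbind(c(-sin(beta), cos(beta)), c(sin(beta), cos(beta))),
       spacing = c(d, d),
       axial_pitch = s_c / tan(beta))
}

#' Generate a single-layer parametric stent pattern
#'
#' Two device classes are supported. `laser_cut` is a closed-cell diamond
#' lattice: two stripe families along the cell diagonals of an
#' `axial_pitch` x `circumferential_pitch` cell, strut width `strut_width`.
#' `braided` is two counter-wound wire families at `+/- braid_angle` degrees
#' from the stent axis: `n_wires` wires in total (half per winding sense)
#' distributed over the unrolled `circumference`, wire diameter
#' `wire_diameter`.
#'
#' @param device_class `"laser_cut"` or `"braided"`.
#' @param params Named list of class-specific parameters (see Details).
#' @return A `stent_pattern` (single layer).
#' @examples
#' p <- generate_pattern("braided", list(wire_diameter = 0.05e-3,
#'   n_wires = 16, braid_angle_deg = 75, circumference = pi * 4e-3))
#' @export
generate_pattern <- function(device_class = c("laser_cut", "braided"),
                             params) {
  device_class <- match.arg(device_class)
  if (device_class == "laser_cut") {
    w <- params$strut_width
    pa <- params$axial_pitch
    pc <- params$circumferential_pitch
    stopifnot(w > 0, pa > 0, pc > 0)
    # diamond lattice: lines x/pa + y/pc = n and x/pa - y/pc = n
    d <- pa * pc / sqrt(pa^2 + pc^2)
    if (w >= d) stop("degenerate pattern: strut width >= strut spacing",
                     call. = FALSE)
    pat <- stripe_pattern(rbind(c(1 / pa, 1 / pc), c(1 / pa, -1 / pc)),
                          spacings = c(d, d), widths = c(w, w),
                          device_class = "laser_cut",
                          strut_width = w, axial_pitch = pa,
                          circumferential_pitch = pc)
  } else {
    w <- params$wire_diameter
    n <- params$n_wires
    beta_deg <- params$braid_angle_deg
    circ <- params$circumference
    stopifnot(w > 0, n >= 2, n %% 2 == 0, beta_deg > 0, beta_deg < 90,
              circ > 0)
    fam <- braid_families(w, n, beta_deg, circ)
    if (w >= fam$spacing[1]) {
      stop("degenerate pattern: wire diameter >= wire spacing", call. = FALSE)
    }
    pat <- stripe_pattern(fam$normals, fam$spacing, widths = c(w, w),
                          device_class = "braided",
                          wire_diameter = w, n_wires = n,
                          braid_angle_deg = beta_deg, circumference = circ,
                          axial_pitch = fam$axial_pitch)
  }
  pat
}

#' @export
print.stent_pattern <- function(x, ...) {
  cat(sprintf("stent_pattern [%s]: %d stripe families, %d layer(s)",
              x$device_class, nrow(x$families), x$layers))
  if (!is.null(x$compaction_factor) && x$compaction_factor != 1) {
    cat(sprintf(", compaction %.3g", x$compaction_factor))
  }
  cat("\n")
  invisible(x)
}

#' Overlap several stent patterns into one multi-layer pattern
#'
#' The metal of the result is the set union of the layer masks, each layer
#' shifted by its offset. The default offsets realize an idealized "constant
#' gap" deployment: layer k is shifted axially by
#' `(k - 1) * axial_pitch / (2 * n_layers)`.
#'
#' @param patterns List of `stent_pattern`s sharing a `device_class`.
#' @param offsets Optional matrix (one row per pattern) of (axial,
#'   transverse) shifts in m; row 1 must be (0, 0).
#' @return A multi-layer `stent_pattern`.
#' @export
overlap <- function(patterns, offsets = NULL) {
  stopifnot(is.list(patterns), length(patterns) >= 1,
            all(vapply(patterns, inherits, TRUE, "stent_pattern")))
  cls <- unique(vapply(patterns, function(p) p$device_class, ""))
  if (length(cls) != 1) {
    stop("incompatible patterns: layers must share a device class",
         call. = FALSE)
  }
  L <- length(patterns)
  if (is.null(offsets)) {
    pitch <- patterns[[1]]$axial_pitch
    if (is.null(pitch)) pitch <- 0
    offsets <- cbind((seq_len(L) - 1) * pitch / (2 * L), 0)
  }
  offsets <- matrix(as.numeric(offsets), ncol = 2)
  stopifnot(nrow(offsets) == L)
  fams <- lapply(seq_len(L), function(k) {
    f <- patterns[[k]]$families
    if (nrow(f)) {
      f$phase <- f$phase + f$nx * offsets[k, 1] + f$ny * offsets[k, 2]
    }
    f
  })
  out <- patterns[[1]]
  out$families <- do.call(rbind, fams)
  out$layers <- sum(vapply(patterns, function(p) p$layers, 1L))
  out$layer_offsets <- offsets
  out
}

#' Axially compact a braided stent pattern
#'
#' Push-pull compaction compresses the braid axially by `factor` while the
#' circumference (and hence the circumferential wire spacing) is fixed; the
#' braid angle steepens to conserve wire length per cell,
#' `tan(beta') = factor * tan(beta)`. The perpendicular wire spacing shrinks
#' by `cos(beta') / cos(beta)`, so local coverage increases monotonically
#' with `factor` and saturates at full coverage. Laser-cut devices cannot be
#' compacted and are rejected.
#'
#' @param pattern A single-layer braided `stent_pattern`.
#' @param factor Compaction factor, `>= 1` (1 = nominal).
#' @return The compacted `stent_pattern`.
#' @export
compact <- function(pattern, factor) {
  stopifnot(inherits(pattern, "stent_pattern"))
  if (pattern$device_class != "braided") {
    stop("unsupported operation: only braided devices can be compacted",
         call. = FALSE)
  }
  if (!is.numeric(factor) || factor < 1) {
    stop("compaction factor must be >= 1", call. = FALSE)
  }
  if (pattern$layers != 1L) {
    stop("compact single layers before overlapping them", call. = FALSE)
  }
  if (factor == 1) return(pattern)
  beta_new <- atan(tan(pattern$braid_angle_deg * pi / 180) * factor)
  # rebuild at the nominal parameters with the steepened angle
  out <- generate_pattern("braided", list(
    wire_diameter = pattern$wire_diameter, n_wires = pattern$n_wires,
    braid_angle_deg = beta_new * 180 / pi,
    circumference = pattern$circumference))
  out$compaction_factor <- pattern$compaction_factor * factor
  out$families$phase <- pattern$families$phase
  out
}

#' Metal coverage rate of a pattern over the neck rectangle
#'
#' Rasters the pattern over the unrolled neck rectangle (neck width x vessel
#' circumference) by center-point sampling and returns the exact mask
#' fraction. The raster spacing must resolve the thinnest stripe (at most a
#' quarter of its width); the default is one eighth.
#'
#' @param pattern A `stent_pattern`.
#' @param neck_rect Numeric length-2, c(axial extent, circumferential
#'   extent) in m.
#' @param raster_spacing Raster spacing in m, default `min(width) / 8`.
#' @return An `mcr_result`: list with `mcr` (fraction in \[0, 1\]),
#'   `metal_mask` (logical matrix, x by y) and `raster_spacing`.
#' @export
compute_mcr <- function(pattern, neck_rect, raster_spacing = NULL) {
  stopifnot(inherits(pattern, "stent_pattern"),
            length(neck_rect) == 2, all(neck_rect > 0))
  fam <- pattern$families
  if (nrow(fam) == 0) {
    mask <- matrix(FALSE, 16L, 16L)
    return(structure(list(mcr = 0, metal_mask = mask,
                          raster_spacing = min(neck_rect) / 16),
                     class = "mcr_result"))
  }
  wmin <- min(fam$width[fam$width > 0])
  if (is.null(raster_spacing)) raster_spacing <- wmin / 8
  if (raster_spacing > wmin / 4) {
    stop("resolution error: raster_spacing must be <= min stripe width / 4",
         call. = FALSE)
  }
  # tolerant ceiling: float noise must not add a phantom row/column when the
  # window is an exact multiple of the spacing
  nxr <- max(2L, as.integer(ceiling(neck_rect[1] / raster_spacing - 1e-9)))
  nyr <- max(2L, as.integer(ceiling(neck_rect[2] / raster_spacing - 1e-9)))
  xs <- (seq_len(nxr) - 0.5) * (neck_rect[1] / nxr)
  ys <- (seq_len(nyr) - 0.5) * (neck_rect[2] / nyr)
  mask <- matrix(FALSE, nxr, nyr)
  for (k in seq_len(nrow(fam))) {
    eta <- outer(xs * fam$nx[k], ys * fam$ny[k], "+") - fam$phase[k]
    fr <- eta / fam$spacing[k]
    fr <- fr - floor(fr)
    dist <- pmin(fr, 1 - fr) * fam$spacing[k]
    mask <- mask | (dist < fam$width[k] / 2)
  }
  structure(list(mcr = mean(mask), metal_mask = mask,
                 raster_spacing = raster_spacing),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("MCR = %.2f%% (raster %d x %d at %.3g um)\n", 100 * x$mcr,
              nrow(x$metal_mask), ncol(x$metal_mask),
              x$raster_spacing * 1e6))
  invisible(x)
}

#' Analytic coverage of a pattern with pairwise non-parallel families
#'
#' For stripe families that cross at nonzero angles the covered fraction is
#' exactly the inclusion-exclusion product `1 - prod(1 - w_k / d_k)`: the
#' overlap fraction of two crossing stripe families equals the product of
#' their individual fractions regardless of crossing angle. Not valid for
#' multi-layer unions of *parallel* families (same orientation, shifted
#' phases); use the raster for those.
#'
#' @param pattern A `stent_pattern`.
#' @return Covered fraction in \[0, 1\].
#' @export
coverage_analytic <- function(pattern) {
  fam <- pattern$families
  if (nrow(fam) == 0) return(0)
  1 - prod(pmax(0, 1 - fam$width / fam$spacing))
}

#' Column-averaged solidity profile along the neck chord
#'
#' Averages the metal mask over the circumferential direction at given axial
#' stations; this is the local blocked fraction seen by the 2D flow solver's
#' screen faces. The mean of the profile equals the MCR up to raster
#' tolerance.
#'
#' @param pattern A `stent_pattern`.
#' @param neck_rect As in [compute_mcr()].
#' @param x_stations Axial positions (m, in `[0, neck_rect[1]]`) at which to
#'   sample; defaults to 32 uniform stations.
#' @param raster_spacing Circumferential sampling step, default
#'   `min(width) / 8`.
#' @param station_width Axial extent over which each station averages
#'   (e.g. the flow grid's face width); 0 for point sampling. Multi-family
#'   unions oscillate column-wise (the crossing overlap varies along the
#'   axis), and a flow face sees the average over its own extent.
#' @return Numeric vector of solidities in \[0, 1\], one per station.
#' @export
solidity_profile <- function(pattern, neck_rect, x_stations = NULL,
                             raster_spacing = NULL, station_width = 0) {
  stopifnot(inherits(pattern, "stent_pattern"))
  if (is.null(x_stations)) {
    x_stations <- (seq_len(32) - 0.5) / 32 * neck_rect[1]
  }
  fam <- pattern$families
  if (nrow(fam) == 0) return(numeric(length(x_stations)) * 0)
  wmin <- min(fam$width[fam$width > 0])
  if (is.null(raster_spacing)) raster_spacing <- wmin / 8
  nyr <- max(2L, as.integer(ceiling(neck_rect[2] / raster_spacing - 1e-9)))
  ys <- (seq_len(nyr) - 0.5) * (neck_rect[2] / nyr)
  xsub <- if (station_width > 0) {
    ((seq_len(9) - 5) / 9) * station_width   # 9-point average over the face
  } else 0
  vapply(x_stations, function(x0) {
    mean(vapply(x0 + xsub, function(x) {
      covered <- rep(FALSE, nyr)
      for (k in seq_len(nrow(fam))) {
        eta <- x * fam$nx[k] + ys * fam$ny[k] - fam$phase[k]
        fr <- eta / fam$spacing[k]
        fr <- fr - floor(fr)
        dist <- pmin(fr, 1 - fr) * fam$spacing[k]
        covered <- covered | (dist < fam$width[k] / 2)
      }
      mean(covered)
    }, numeric(1)))
  }, numeric(1))
}

#' Export a metal mask as PNG and a JSON summary
#'
#' @param mcr_result An `mcr_result`.
#' @param png_path,json_path Output paths (either may be `NULL` to skip).
#' @param params Optional named list echoed into the JSON summary.
#' @return Invisibly, the summary list.
#' @export
export_mcr <- function(mcr_result, png_path = NULL, json_path = NULL,
                       params = list()) {
  stopifnot(inherits(mcr_result, "mcr_result"))
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = nrow(mcr_result$metal_mask),
                   height = ncol(mcr_result$metal_mask))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(mcr_result$metal_mask * 1L, col = c("white", "black"),
                    axes = FALSE, useRaster = TRUE)
    grDevices::dev.off()
  }
  summ <- list(mcr = mcr_result$mcr,
               raster_spacing_m = mcr_result$raster_spacing,
               params = params)
  if (!is.null(json_path)) {
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
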