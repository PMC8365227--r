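#' Calibrated device presets
#'
#' Returns the parameter set of one of the three packaged virtual devices:
#' `"enterprise"` (laser-cut closed-cell stent), `"lvis"` (braided stent) or
#' `"pipeline"` (braided flow diverter). Strut/wire widths are plausible
#' published-order dimensions; pitch, braid angle and maximum compaction
#' factor were calibrated once, in closed form, so that the single-device
#' MCR over the unrolled neck of the default 4 mm parent artery matches the
#' study targets (7.0%, 20.4%, 26.8%; 35.4% / 47.8% at maximum compaction
#' for the braided devices). See `scripts/calibrate_devices.R` in the source
#' repository.
#'
#' @param name Preset name.
#' @return Named list of device parameters (lengths in m).
#' @export
device_preset <- function(name = c("enterprise", "lvis", "pipeline")) {
  name <- match.arg(name)
  reg <- yaml::read_yaml(system.file("extdata", "devices.yaml",
                                     package = "aneuflow", mustWork = TRUE))
  reg[[name]]
}

#' Build a deployed device pattern from a preset
#'
#' Convenience wrapper used by the study pipeline: instantiates the preset's
#' single-layer pattern, optionally compacts it (braided devices only, at
#' the preset's calibrated maximum compaction factor unless a factor is
#' given), and overlaps `layers` copies with the default constant-gap
#' offsets.
#'
#' @param device Preset name (see [device_preset()]).
#' @param layers Number of overlapped devices (>= 1).
#' @param compaction `FALSE`/1 for nominal, `TRUE` for the preset's maximum
#'   compaction factor, or a numeric factor >= 1.
#' @return A `stent_pattern`.
#' @export
build_device_pattern <- function(device, layers = 1L, compaction = FALSE) {
  preset <- device_preset(device)
  single <- if (preset$device_class == "laser_cut") {
    generate_pattern("laser_cut", list(
      strut_width = preset$strut_width_m,
      axial_pitch = preset$axial_pitch_m,
      circumferential_pitch = preset$circumferential_pitch_m))
  } else {
    generate_pattern("braided", list(
      wire_diameter = preset$wire_diameter_m,
      n_wires = preset$n_wires,
      braid_angle_deg = preset$braid_angle_deg,
      circumference = preset$circumference_m))
  }
  factor <- if (isTRUE(compaction)) preset$max_compaction_factor
            else if (is.numeric(compaction)) compaction else 1
  if (factor > 1) single <- compact(single, factor)
  if (layers > 1L) {
    single <- overlap(rep(list(single), layers))
  }
  single
}

#' Default unrolled neck rectangle for a geometry
#'
#' The MCR is measured over the aneurysm neck unrolled around the parent
#' vessel: axial extent = neck width, circumferential extent = parent
#' circumference.
#'
#' @param geom An `aneurysm_geometry` (default: the study geometry).
#' @return Numeric length-2 c(axial, circumferential) in m.
#' @export
neck_rect <- function(geom = build_sidewall_aneurysm()) {
  c(geom$neck_width, pi * geom$parent_diameter)
}
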