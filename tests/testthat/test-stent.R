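nr <- c(5.27e-3, pi * 4e-3)   # study neck rectangle

test_that("braided raster MCR matches the analytic coverage", {
  p <- generate_pattern("braided", list(
    wire_diameter = 0.05e-3, n_wires = 16, braid_angle_deg = 75,
    circumference = pi * 4e-3))
  m <- compute_mcr(p, nr)
  expect_lt(abs(m$mcr - coverage_analytic(p)), 0.01)
  # analytic formula for two equal families: 1 - (1 - w/d)^2
  d <- p$families$spacing[1]
  expect_equal(coverage_analytic(p), 1 - (1 - 0.05e-3 / d)^2,
               tolerance = 1e-12)
})

test_that("laser-cut coverage approaches 1 as strut width approaches pitch", {
  pa <- 1e-3
  d <- pa / sqrt(2)
  p <- generate_pattern("laser_cut", list(
    strut_width = d * 0.999, axial_pitch = pa, circumferential_pitch = pa))
  expect_gt(compute_mcr(p, nr)$mcr, 0.995)
  expect_error(generate_pattern("laser_cut", list(
    strut_width = d * 1.01, axial_pitch = pa, circumferential_pitch = pa)),
    "degenerate")
})

test_that("compute_mcr handles degenerate masks and resolution", {
  expect_equal(compute_mcr(empty_pattern(), nr)$mcr, 0)
  # solid sheet: stripe width equals spacing
  solid <- stripe_pattern(rbind(c(1, 0)), spacings = 1e-3, widths = 1e-3)
  expect_equal(compute_mcr(solid, nr)$mcr, 1)
  # orthogonal grid with width 0.1 pitch in both directions: 1 - 0.9^2
  # (window commensurate with the pitch so edge stripes do not bias the
  # fraction; fine raster since center sampling quantizes at spacing/pitch)
  g <- stripe_pattern(rbind(c(1, 0), c(0, 1)), spacings = c(1e-3, 1e-3),
                      widths = c(1e-4, 1e-4))
  expect_lt(abs(compute_mcr(g, c(5e-3, 12e-3), raster_spacing = 4e-6)$mcr -
                  0.19), 0.19 * 0.01)
  expect_error(compute_mcr(g, nr, raster_spacing = 1e-4), "resolution")
  # refinement stability: halving spacing moves MCR < 0.5 points
  m1 <- compute_mcr(g, nr, raster_spacing = 2.5e-5)$mcr
  m2 <- compute_mcr(g, nr, raster_spacing = 1.25e-5)$mcr
  expect_lt(abs(m1 - m2), 0.005)
})

test_that("overlap obeys union bounds and the independent-offset oracle", {
  p <- generate_pattern("braided", list(
    wire_diameter = 0.06e-3, n_wires = 16, braid_angle_deg = 70,
    circumference = pi * 4e-3))
  m1 <- compute_mcr(p, nr)$mcr

  # identical layers, zero offset: union is idempotent
  same <- overlap(list(p, p), offsets = rbind(c(0, 0), c(0, 0)))
  expect_equal(compute_mcr(same, nr)$mcr, m1, tolerance = 1e-12)

  # default half-pitch offsets: bounded by single and sum
  two <- overlap(list(p, p))
  m2 <- compute_mcr(two, nr)$mcr
  expect_gte(m2, m1)
  expect_lte(m2, min(1, 2 * m1) + 1e-9)

  # averaging the union over a sweep of offsets reproduces the
  # independent-position expectation 1 - (1 - m)^2
  offs <- seq(0, p$axial_pitch, length.out = 12)[-12]
  ms <- vapply(offs, function(dx) {
    compute_mcr(overlap(list(p, p), offsets = rbind(c(0, 0), c(dx, 0))),
                nr, raster_spacing = 1.2e-5)$mcr
  }, numeric(1))
  expect_equal(mean(ms), 1 - (1 - m1)^2, tolerance = 0.01)

  expect_error(overlap(list(p, generate_pattern("laser_cut", list(
    strut_width = 1e-4, axial_pitch = 1e-3, circumferential_pitch = 1e-3)))),
    "incompatible")
})

test_that("compaction is identity at 1, monotone in factor, braided-only", {
  p <- generate_pattern("braided", list(
    wire_diameter = 0.061e-3, n_wires = 16, braid_angle_deg = 60,
    circumference = pi * 4e-3))
  expect_identical(compact(p, 1), p)
  ms <- vapply(c(1, 1.25, 1.5, 1.75, 2), function(f) {
    compute_mcr(compact(p, f), nr)$mcr
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  lc <- generate_pattern("laser_cut", list(
    strut_width = 1e-4, axial_pitch = 1e-3, circumferential_pitch = 1e-3))
  expect_error(compact(lc, 1.5), "braided")
  expect_error(compact(p, 0.8), ">= 1")
})

test_that("solidity profile is periodic-uniform and averages to the MCR", {
  # a single wire family has exactly constant column coverage w/d; choose
  # the spacing so a whole number of wires crosses the circumference
  # (otherwise the +-1 partial wire at the window edge adds a real, not
  # numerical, percent-level column variation)
  d_comm <- nr[2] / 12 * cos(1.2)
  fam <- stripe_pattern(rbind(c(-sin(1.2), cos(1.2))), spacings = d_comm,
                        widths = 6e-5)
  prof1 <- solidity_profile(fam, nr,
                            x_stations = (seq_len(64) - 0.5) / 64 * nr[1],
                            raster_spacing = 6e-5 / 16)
  expect_lt((max(prof1) - min(prof1)) / mean(prof1), 0.05)
  expect_lt(abs(mean(prof1) - 6e-5 / d_comm), 0.005)

  # two-family union: columns oscillate (crossing overlap varies along the
  # axis) but the mean over stations still equals the MCR
  p <- build_device_pattern("lvis")
  mcr <- compute_mcr(p, nr)$mcr
  prof <- solidity_profile(p, nr, x_stations = (seq_len(64) - 0.5) / 64 * nr[1])
  expect_lt(abs(mean(prof) - mcr), 0.005)
  # face-width averaging smooths the oscillation
  prof_w <- solidity_profile(p, nr,
                             x_stations = (seq_len(64) - 0.5) / 64 * nr[1],
                             station_width = 2e-4)
  expect_lt(max(prof_w) - min(prof_w), max(prof) - min(prof))
  expect_lt(abs(mean(prof_w) - mcr), 0.005)

  expect_equal(solidity_profile(empty_pattern(), nr), numeric(32))
})

test_that("patterns and masks are deterministic", {
  p1 <- build_device_pattern("pipeline", layers = 2)
  p2 <- build_device_pattern("pipeline", layers = 2)
  expect_identical(compute_mcr(p1, nr)$metal_mask,
                   compute_mcr(p2, nr)$metal_mask)
})
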