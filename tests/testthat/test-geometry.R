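test_that("sac center offset satisfies the chord relation", {
  g <- build_sidewall_aneurysm(4e-3, 5e-3, 5.27e-3, 40e-3)
  expect_equal(g$sac_center_offset, sqrt(5e-3^2 - (5.27e-3 / 2)^2),
               tolerance = 1e-12)
  # brute-force oracle: sample the circle densely and measure the chord the
  # circle cuts on the wall line
  th <- seq(0, 2 * pi, length.out = 2e5)
  cx <- g$neck_axial_position
  cy <- g$parent_diameter + g$sac_center_offset
  px <- cx + g$sac_radius * cos(th)
  py <- cy + g$sac_radius * sin(th)
  near <- abs(py - g$parent_diameter) < 2e-6
  chord <- diff(range(px[near]))
  expect_equal(chord, g$neck_width, tolerance = 5e-3)
})

test_that("geometry construction handles limits and rejects infeasible necks", {
  # hemispherical cap limit: chord equals the sac diameter
  g <- build_sidewall_aneurysm(4e-3, 5e-3, 10e-3, 60e-3)
  expect_equal(g$sac_center_offset, 0)
  expect_error(build_sidewall_aneurysm(4e-3, 5e-3, 10.5e-3, 40e-3),
               "infeasible")
  expect_error(build_sidewall_aneurysm(4e-3, 5e-3, 5.27e-3, 15e-3),
               "entrance-length")
  # study configuration accepted without error
  expect_s3_class(build_sidewall_aneurysm(4e-3, 5e-3, 5.27e-3, 40e-3),
                  "aneurysm_geometry")
})

test_that("raster areas converge to the analytic circle-segment area", {
  g <- build_sidewall_aneurysm()
  an <- analytic_fluid_areas(g)
  errs <- vapply(c(2e-4, 1e-4, 5e-5), function(h) {
    ar <- raster_fluid_areas(rasterize(g, h))
    abs(ar$sac_area - an$sac_area)
  }, numeric(1))
  expect_lt(errs[2] / an$sac_area, 0.02)  # 2% at 0.1 mm
  expect_true(all(diff(errs) < 0))        # monotone refinement
})

test_that("rasterization enforces the resolution floor and is deterministic", {
  g <- build_sidewall_aneurysm()
  expect_error(rasterize(g, 0.5e-3), "resolution")
  g1 <- rasterize(g, 2e-4)
  g2 <- rasterize(g, 2e-4)
  expect_identical(g1$cell_mask, g2$cell_mask)
})

test_that("mask labels satisfy the neck-interface adjacency invariant", {
  g <- build_sidewall_aneurysm()
  gr <- rasterize(g, 2e-4)
  m <- gr$cell_mask
  neck <- which(m == 3L, arr.ind = TRUE)
  expect_gt(nrow(neck), 0)
  for (k in seq_len(nrow(neck))) {
    i <- neck[k, 1]; j <- neck[k, 2]
    expect_equal(m[i, j + 1], 2L)              # sac above
    expect_true(m[i, j - 1] %in% c(1L, 3L))    # parent below
  }
  # plane C length equals the neck width within one spacing
  expect_equal(length(gr$neck_faces) * gr$spacing, g$neck_width,
               tolerance = gr$spacing / g$neck_width)
  # a pure channel has no sac cells and no neck faces
  ch <- channel_grid(20e-3, 4e-3, 2e-4)
  expect_equal(sum(ch$cell_mask == 2L), 0)
  expect_length(ch$neck_faces, 0)
})

test_that("plane placement and the inter-plane volume V_m", {
  g <- build_sidewall_aneurysm()
  gr <- rasterize(g, 1e-4)
  depth <- g$parent_diameter

  # planes at the domain faces: V_m equals the total fluid volume
  half_w <- g$neck_width / 2
  g_all <- place_planes(gr, a_offset = g$neck_axial_position - half_w,
                        b_offset = g$parent_length - g$neck_axial_position -
                          half_w)
  ar <- raster_fluid_areas(gr)
  expect_equal(g_all$v_m, ar$total_area * depth, tolerance = 1e-12)

  # default stations: V_m matches the shoelace-polygon oracle within 1%
  g_def <- place_planes(gr)
  xa <- g_def$plane_indices$a * gr$spacing
  xb <- g_def$plane_indices$b * gr$spacing
  poly <- fluid_polygon_between(g, xa, xb)
  v_oracle <- shoelace_area(poly$x, poly$y) * depth
  expect_equal(g_def$v_m, v_oracle, tolerance = 0.01)

  # V_m additivity: full-domain volume exceeds default inter-plane volume
  expect_gt(g_all$v_m, g_def$v_m)

  expect_error(place_planes(gr, a_offset = 1), "outside")
  expect_error(place_planes(gr, a_offset = -1e-3), "intersects")
})
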