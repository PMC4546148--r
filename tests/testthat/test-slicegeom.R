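# direct re-implementation used by the chord-fallback test
point_line_distance_test <- function(pts, a, b) {
  d <- b - a
  abs((pts[, 1L] - a[1L]) * d[2L] - (pts[, 2L] - a[2L]) * d[1L]) /
    sqrt(sum(d^2))
}

test_that("defect detection finds dips and ignores convex contours", {
  th <- seq(0.5, pi - 0.5, length.out = 200)
  convex <- slice_contour(0, cbind(20 * cos(th), -20 * sin(th)), 1)
  expect_null(detect_defect_interval(convex))

  ct <- straight_dip_contour(dip_from = 12, dip_width = 6, dip_depth = 2)
  mark <- detect_defect_interval(ct)
  expect_s3_class(mark, "defect_mark")
  # bounds within one vertex of the dip edges at y = 12 and y = 18
  expect_lte(abs(ct$points[mark$start_index, 1L] - 12), 1)
  expect_lte(abs(ct$points[mark$end_index, 1L] - 18), 1)

  # sub-threshold dip is not marked
  shallow <- straight_dip_contour(dip_depth = 0.2)
  expect_null(detect_defect_interval(shallow, deviation_threshold = 0.3))
})

test_that("detection reproduces the phantom's annotated interval", {
  ph <- fine_phantom()
  xs <- vapply(ph$slices, function(s) s$x_ml_mm, numeric(1L))
  center <- ph$slices[[which.min(abs(xs))]]
  found <- detect_defect_interval(center)
  step <- ph$spec$in_plane_step_mm
  for (side in c("start_index", "end_index")) {
    d <- sqrt(sum((center$points[found[[side]], ] -
                   center$points[center$mark[[side]], ])^2))
    expect_lte(d, step + 1e-9)
  }
})

test_that("bridging falls back to the chord over collinear flanks", {
  ct <- straight_dip_contour()
  br <- bridge_defect(ct, detect_defect_interval(ct))
  a <- ct$points[br$mark$start_index, ]
  b <- ct$points[br$mark$end_index, ]
  expect_lt(max(point_line_distance_test(br$bridge_points, a, b)), 1e-6)
  expect_equal(br$bridge_points[1L, ], a)
  expect_equal(br$bridge_points[nrow(br$bridge_points), ], b)
})

test_that("the spline bridge recovers a circular arc within 0.1 mm", {
  ph <- fine_phantom()
  xs <- vapply(ph$slices, function(s) s$x_ml_mm, numeric(1L))
  center <- ph$slices[[which.min(abs(xs))]]
  br <- bridge_defect(center)
  # the intact contour is a circle of radius 20 about the origin
  radii <- sqrt(rowSums(br$bridge_points^2))
  expect_lt(max(abs(radii - 20)), 0.1)
})

test_that("degenerate marks yield zero gap area", {
  ct <- straight_dip_contour()
  br <- bridge_defect(ct, defect_mark(2L, 3L))
  expect_lt(slice_gap_area(br), 1e-9)
})

test_that("per-slice depth matches constructed dips", {
  rect <- bridge_defect(straight_dip_contour(dip_depth = 2))
  expect_equal(slice_defect_depth(rect), 2.0, tolerance = 1e-9)

  tri <- triangular_dip_contour(dip_depth = 3)
  expect_equal(slice_defect_depth(bridge_defect(tri)), 3.0,
               tolerance = 1e-9)

  ph <- fine_phantom()
  xs <- vapply(ph$slices, function(s) s$x_ml_mm, numeric(1L))
  center <- bridge_defect(ph$slices[[which.min(abs(xs))]])
  expect_equal(slice_defect_depth(center), 3.0,
               tolerance = ph$spec$in_plane_step_mm)
})

test_that("gap areas match closed forms and the shoelace oracle", {
  rect <- bridge_defect(straight_dip_contour(dip_width = 6, dip_depth = 2))
  expect_equal(slice_gap_area(rect), 12.0, tolerance = 1e-9)

  tri <- bridge_defect(triangular_dip_contour(dip_width = 6, dip_depth = 3))
  expect_equal(slice_gap_area(tri), 9.0, tolerance = 1e-9)

  # circular-segment dip: compare against a direct shoelace evaluation on
  # the densified bridge + depressed polygon
  ph <- fine_phantom()
  xs <- vapply(ph$slices, function(s) s$x_ml_mm, numeric(1L))
  br <- bridge_defect(ph$slices[[which.min(abs(xs))]])
  nd <- nrow(br$depressed_points)
  poly <- rbind(br$bridge_points, br$depressed_points[(nd - 1L):2L, ])
  expect_equal(slice_gap_area(br), shoelace_area(poly),
               tolerance = 1e-6)
})

test_that("gap area and depth are invariant under in-plane rigid motion", {
  ct <- fine_phantom()$slices[[31L]]
  base <- bridge_defect(ct)
  for (theta in c(0.4, -1.1, 2.2)) {
    rot <- bridge_defect(rotate_contour(ct, theta, shift = c(3, -8)))
    expect_equal(slice_gap_area(rot), slice_gap_area(base),
                 tolerance = 1e-9)
    expect_equal(slice_defect_depth(rot), slice_defect_depth(base),
                 tolerance = 1e-9)
  }
})

test_that("nested dips give monotone depth and area", {
  shallow <- bridge_defect(straight_dip_contour(dip_width = 4,
                                                dip_depth = 1))
  deep <- bridge_defect(straight_dip_contour(dip_width = 6, dip_depth = 2))
  expect_lt(slice_gap_area(shallow), slice_gap_area(deep))
  expect_lt(slice_defect_depth(shallow), slice_defect_depth(deep))
})

test_that("zero gap area occurs exactly when the curves coincide", {
  ct <- straight_dip_contour(dip_depth = 2)
  marked <- bridge_defect(ct)
  expect_gt(slice_gap_area(marked), 0)
  flat <- straight_dip_contour(dip_depth = 0.0001)
  # mark a flat stretch: bridge and depressed curve coincide on the chord
  br <- bridge_defect(flat, defect_mark(3L, 7L))
  expect_lt(slice_gap_area(br), 1e-6)
})

test_that("bridging errors are informative", {
  ct <- straight_dip_contour()
  expect_error(bridge_defect(ct, NULL), "no defect mark")
  expect_error(bridge_defect(ct, defect_mark(1L, 10L)),
               "insufficient flank")
  expect_error(bridge_defect(ct, defect_mark(5L, 500L)), "invalid")
})

test_that("crossing bridge and depressed curves are rejected", {
  fake <- structure(list(
    contour = straight_dip_contour(),
    mark = defect_mark(1L, 4L),
    bridge_points = rbind(c(0, 0), c(10, 0), c(4, 3), c(12, 3)),
    depressed_points = rbind(c(0, 0), c(6, 1), c(12, 3))),
    class = "bridged_slice")
  expect_error(slice_gap_area(fake), "cross")
})
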