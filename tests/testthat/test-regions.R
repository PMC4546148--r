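# phantom with the indent aimed into the central-external octant: the
# footprint stays strictly lateral of the split and between the planes
ce_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      u <- c(0.35, 0.45, -0.85)
      cache <<- generate_phantom(phantom_spec(indent_direction = u,
                                              slice_spacing_mm = 0.5,
                                              in_plane_step_mm = 0.2))
    }
    cache
  }
})

test_that("the partition planes follow the 60 % and 50 % rules", {
  lm <- landmarks(trochlear_notch_point = c(0, 40, 0),
                  posterior_point_medial = c(-10, 0, 0),
                  posterior_point_lateral = c(10, 0, 0),
                  shaft_axis_direction = c(0, 0, 1))
  slices <- lapply(seq(0, 30, by = 3), function(x)
    slice_contour(x, cbind(seq(40, 0, by = -10), -5), 3))
  p <- build_partition(slices, lm)
  # plane 2 sits at world coordinate 40 - 0.6 * 40 = 16 along y
  expect_equal(p$plane_origin[2L] +
                 p$plane2_offset * p$plane_normal[2L] * 1, 16)
  expect_equal(abs(p$plane_normal), c(0, 1, 0))
  expect_equal(p$ml_split, 15)   # midpoint of x in [0, 30]

  bad <- landmarks(c(0, 40, 0), c(-10, 0, 0), c(10, 0, 0), c(1, 0, 0))
  expect_error(build_partition(slices, bad), "degenerate")
})

test_that("the six segments tile the surface and sums are conserved", {
  ph <- ce_phantom()
  knee <- measure_knee(ph$slices, ph$landmarks)
  seg <- knee$segments
  expect_setequal(seg$region, c("AI", "AE", "CI", "CE", "PI", "PE"))
  expect_equal(sum(seg$region_surface_cm2), knee$total$total_area_cm2,
               tolerance = 1e-9)
  expect_equal(sum(seg$affected_area_cm2), knee$metrics$primary_area_cm2,
               tolerance = 1e-9)
  expect_equal(sum(seg$concave_area_cm2), knee$metrics$concave_area_cm2,
               tolerance = 1e-9)
  expect_equal(sum(seg$volume_mm3), knee$metrics$volume_mm3,
               tolerance = 1e-9)
})

test_that("an octant-aimed defect lands entirely in CE", {
  ph <- ce_phantom()
  knee <- measure_knee(ph$slices, ph$landmarks)
  seg <- knee$segments
  ce <- seg[seg$region == "CE", ]
  expect_equal(100 * ce$affected_area_cm2, ph$truth$primary_area_mm2,
               tolerance = 0.05)
  others <- seg[seg$region != "CE", ]
  expect_true(all(others$affected_area_cm2 < 1e-9))
  expect_true(all(others$volume_mm3 < 1e-9))
  expect_identical(knee$location, "CE")
  expect_gt(ce$percent_of_region, 0)
})

test_that("weight-bearing segments are exactly the slab between the planes", {
  ph <- ce_phantom()
  part <- build_partition(ph$slices, ph$landmarks)
  mesh <- reconstruct_surface(lapply(bridge_all(ph$slices),
                                     notchmorph:::substituted_contour))
  cent <- notchmorph:::triangle_centroids(mesh)
  labs <- notchmorph:::segment_label(part, cent)
  s <- (cent[, 2L] - part$plane_origin[2L]) * part$plane_normal[2L] +
       (cent[, 1L] - part$plane_origin[1L]) * part$plane_normal[1L] +
       (cent[, 3L] - part$plane_origin[3L]) * part$plane_normal[3L]
  central <- labs %in% c("CI", "CE")
  expect_identical(central, s <= 0 & s > part$plane2_offset)
})

test_that("segment assignment is invariant under rigid motion", {
  ph <- generate_phantom(phantom_spec(indent_direction = c(0.35, 0.45, -0.85),
                                      slice_spacing_mm = 1,
                                      in_plane_step_mm = 0.4))
  base <- measure_knee(ph$slices, ph$landmarks)
  theta <- 0.8; shift <- c(0, 5, -3)
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  rot3 <- function(p) c(p[1L], Rm %*% p[2:3] + shift[2:3])
  moved <- lapply(ph$slices, rotate_contour, theta = theta,
                  shift = shift[2:3])
  lm <- ph$landmarks
  lm2 <- landmarks(rot3(lm$trochlear_notch_point),
                   rot3(lm$posterior_point_medial),
                   rot3(lm$posterior_point_lateral),
                   c(lm$shaft_axis_direction[1L],
                     Rm %*% lm$shaft_axis_direction[2:3]))
  got <- measure_knee(moved, lm2)
  expect_identical(got$location, base$location)
  expect_equal(got$segments$region_surface_cm2,
               base$segments$region_surface_cm2, tolerance = 1e-9)
  expect_equal(got$segments$affected_area_cm2,
               base$segments$affected_area_cm2, tolerance = 1e-9)
})

test_that("primary-location calls follow area share and the tie order", {
  seg <- data.frame(region = c("AI", "AE", "CI", "CE", "PI", "PE"),
                    affected_area_cm2 = c(0, 0, 1, 0, 0, 0))
  expect_identical(classify_primary_location(seg), "CI")
  seg$affected_area_cm2 <- c(0, 0, 0.5, 0.5, 0, 0)
  expect_identical(classify_primary_location(seg), "CE")  # documented tie
  seg$affected_area_cm2 <- rep(0, 6)
  expect_identical(classify_primary_location(seg), "none")
})

test_that("a majority-lateral defect straddling the split is called external", {
  ph <- generate_phantom(phantom_spec(indent_direction = c(0.08, 0.45, -0.88),
                                      slice_spacing_mm = 0.5,
                                      in_plane_step_mm = 0.25))
  knee <- measure_knee(ph$slices, ph$landmarks)
  # direct-summation oracle for the lateral area share
  defs <- Filter(function(s) inherits(s, "bridged_slice"),
                 bridge_all(ph$slices))
  xd <- vapply(defs, function(b) b$contour$x_ml_mm, numeric(1L))
  m <- notchmorph:::defect_strip_mesh(defs, xd, "bridge_points", 200)
  cent <- notchmorph:::triangle_centroids(m)
  ar <- notchmorph:::triangle_areas(m)
  lat_share <- sum(ar[cent[, 1L] > knee$partition$ml_split]) / sum(ar)
  expect_gt(lat_share, 0.5)
  expect_identical(substr(knee$location, 2L, 2L), "E")
})

test_that("sweeping the indent across the split flips the side once", {
  sides <- vapply(c(-0.2, -0.1, 0.1, 0.2), function(ux) {
    ph <- generate_phantom(phantom_spec(
      indent_direction = c(ux, 0.45, -0.85),
      slice_spacing_mm = 1, in_plane_step_mm = 0.4))
    substr(measure_knee(ph$slices, ph$landmarks)$location, 2L, 2L)
  }, character(1L))
  expect_identical(sides, c("I", "I", "E", "E"))
})
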