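# Fixture builders and independent oracles used across the suite.

# Straight contour along y in [0, len] at z = 0 with a rectangular dip of
# given width/depth pressed toward the bone (+z), dip spanning
# y in [dip_from, dip_from + dip_width].  Vertex spacing `step`.
straight_dip_contour <- function(len = 30, dip_from = 12, dip_width = 6,
                                 dip_depth = 2, step = 1, spacing = 1) {
  y <- seq(0, len, by = step)
  z <- ifelse(y > dip_from & y < dip_from + dip_width, dip_depth, 0)
  # vertical dip walls so the dip edges are explicit vertices
  pts <- rbind(cbind(y[y <= dip_from], 0),
               c(dip_from, dip_depth),
               cbind(y[y > dip_from & y < dip_from + dip_width], dip_depth),
               c(dip_from + dip_width, dip_depth),
               cbind(y[y >= dip_from + dip_width], 0))
  # drop accidental duplicates from the wall insertion
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  ct <- slice_contour(0, pts[keep, , drop = FALSE], spacing)
  ct$mark <- detect_defect_interval(ct)
  ct
}

# Triangular dip: apex `depth` below the chord midpoint (toward +z).
triangular_dip_contour <- function(len = 30, dip_from = 12, dip_width = 6,
                                   dip_depth = 3, step = 1, spacing = 1) {
  y <- seq(0, len, by = step)
  apex <- dip_from + dip_width / 2
  z <- numeric(length(y))
  inside <- y > dip_from & y < dip_from + dip_width
  z[inside] <- dip_depth * (1 - abs(y[inside] - apex) / (dip_width / 2))
  pts <- unique(rbind(cbind(y, z), c(apex, dip_depth)))
  pts <- pts[order(pts[, 1L]), , drop = FALSE]
  ct <- slice_contour(0, pts, spacing)
  ct$mark <- detect_defect_interval(ct)
  ct
}

# Independent shoelace evaluation on a densified polygon.
shoelace_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x); j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Brute-force voxelization oracle for the sphere-sphere lens volume:
# counts grid-cell centers inside both spheres (centers distance R + r - t
# apart along the first axis).
voxel_lens_volume <- function(R, r, t, h = 0.05) {
  d <- R + r - t
  xR <- (d^2 - r^2 + R^2) / (2 * d)
  a <- sqrt(R^2 - xR^2)
  xs <- seq(d - r, R, by = h)
  ys <- seq(-a - 2 * h, a + 2 * h, by = h)
  vol <- 0
  for (x in xs) {
    rad2 <- min(R^2 - x^2, r^2 - (x - d)^2)
    if (rad2 <= 0) next
    yy <- ys[ys^2 <= rad2]
    vol <- vol + sum(2 * floor(sqrt(rad2 - yy^2) / h) + 1) * h^2
  }
  vol * h
}

# Triangulated-mesh oracle for the area of a spherical band sampled
# independently of the package's reconstruction (fine lat-long grid).
mesh_zone_area <- function(R, x_lo, x_hi, nx = 400, na = 720) {
  xs <- seq(x_lo, x_hi, length.out = nx)
  al <- seq(0, 2 * pi, length.out = na)
  area <- 0
  for (i in seq_len(nx - 1L)) {
    r1 <- sqrt(R^2 - xs[i]^2); r2 <- sqrt(R^2 - xs[i + 1L]^2)
    # frustum strip between consecutive rings, triangulated implicitly:
    # lateral area of the cone frustum spanned by the two rings
    slant <- sqrt((xs[i + 1L] - xs[i])^2 + (r2 - r1)^2)
    area <- area + pi * (r1 + r2) * slant
  }
  area
}

# In-plane rigid motion of a slice contour (rotation by `theta` about the
# slice plane origin plus translation), applied to points only.
rotate_contour <- function(ct, theta, shift = c(0, 0)) {
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  slice_contour(ct$x_ml_mm, sweep(ct$points %*% t(Rm), 2L, -shift),
                ct$slice_spacing_mm, ct$mark)
}

# Default fine phantom shared by several files (cached per session).
fine_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec())
    cache
  }
})
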