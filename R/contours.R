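#' Sagittal slice contour
#'
#' A single sagittal segmentation of the lateral femoral subchondral bone
#' surface: an ordered open polyline in the slice plane, anterior to
#' posterior, at a known medio-lateral position.  In-plane coordinates are
#' `(y, z)` with `y` pointing posterior-to-anterior and `z` distal-to-proximal;
#' the medio-lateral axis `x` is perpendicular to the slice.  All lengths in
#' millimeters.
#'
#' @param x_ml_mm Medio-lateral position of the slice plane (mm).
#' @param points Two-column numeric matrix of in-plane coordinates
#'   `(y_ap_mm, z_si_mm)`, ordered anterior to posterior.
#' @param slice_spacing_mm Distance between adjacent slice planes (mm).
#' @param mark Optional [defect_mark()] identifying the depressed interval.
#' @return An object of class `slice_contour`.
#' @seealso [defect_mark()], [bridge_defect()], [reconstruct_surface()]
#' @export
slice_contour <- function(x_ml_mm, points, slice_spacing_mm, mark = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 4L)
    stop("a slice contour needs at least 4 points, got ", nrow(points))
  dup <- rowSums((points[-1L, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE])^2) == 0
  if (any(dup))
    stop("consecutive contour points must be distinct (slice at x = ",
         x_ml_mm, " mm)")
  if (!is.numeric(slice_spacing_mm) || length(slice_spacing_mm) != 1L ||
      !is.finite(slice_spacing_mm) || slice_spacing_mm <= 0)
    stop("slice_spacing_mm must be a single positive number")
  obj <- structure(
    list(x_ml_mm = as.numeric(x_ml_mm), points = points,
         slice_spacing_mm = as.numeric(slice_spacing_mm), mark = NULL),
    class = "slice_contour")
  if (!is.null(mark)) obj$mark <- validate_mark(mark, nrow(points))
  obj
}

#' Mark the depressed interval of a slice contour
#'
#' Vertex indices (1-based, inclusive) bounding the depressed portion of a
#' contour.  By convention the bounding vertices themselves lie on intact
#' bone, so a bridge anchored at them spans the whole depression.
#'
#' @param start_index,end_index First and last vertex of the marked interval.
#' @return An object of class `defect_mark`.
#' @export
defect_mark <- function(start_index, end_index) {
  structure(list(start_index = as.integer(start_index),
                 end_index = as.integer(end_index)),
            class = "defect_mark")
}

validate_mark <- function(mark, n_points) {
  if (!inherits(mark, "defect_mark"))
    mark <- defect_mark(mark$start_index, mark$end_index)
  s <- mark$start_index; e <- mark$end_index
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e) ||
      s < 1L || e <= s || e > n_points)
    stop("invalid defect mark: need 1 <= start < end <= ", n_points,
         ", got [", s, ", ", e, "]")
  mark
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points))
    stop("points must be a numeric matrix with 2 columns")
  if (anyNA(points) || any(!is.finite(points)))
    stop("points must be finite")
  dimnames(points) <- NULL
  points
}

#' @export
print.slice_contour <- function(x, ...) {
  cat(sprintf("<slice_contour> x = %.3f mm, %d points, spacing %.3f mm%s\n",
              x$x_ml_mm, nrow(x$points), x$slice_spacing_mm,
              if (is.null(x$mark)) ""
              else sprintf(", defect mark [%d, %d]",
                           x$mark$start_index, x$mark$end_index)))
  invisible(x)
}

## ---- planar polyline utilities ----------------------------------------

cum_chord_length <- function(pts) {
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

polyline_length <- function(pts) {
  s <- cum_chord_length(pts)
  s[length(s)]
}

# Resample an open polyline to k points uniformly spaced in arc length
# (piecewise-linear interpolation; endpoints preserved exactly).
resample_polyline <- function(pts, k) {
  s <- cum_chord_length(pts)
  # collapse zero-length duplicates for interpolation
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  si <- seq(0, s[length(s)], length.out = k)
  cbind(stats::approx(s, pts[, 1L], xout = si)$y,
        stats::approx(s, pts[, 2L], xout = si)$y)
}

# Signed area of a closed polygon (shoelace); vertices need not repeat
# the first point.
polygon_area_signed <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Perpendicular distance of points to the infinite line through a, b.
point_line_distance <- function(pts, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(sqrt(rowSums(sweep(pts, 2L, a)^2)))
  abs((pts[, 1L] - a[1L]) * d[2L] - (pts[, 2L] - a[2L]) * d[1L]) / len
}

# Minimum distance from each query point to an open polyline.
point_polyline_distance <- function(pts, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  len2[len2 == 0] <- 1  # degenerate segments handled by clamping t
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    t <- ((p[1L] - a[, 1L]) * d[, 1L] + (p[2L] - a[, 2L]) * d[, 2L]) / len2
    t <- pmin(1, pmax(0, t))
    qx <- a[, 1L] + t * d[, 1L]
    qy <- a[, 2L] + t * d[, 2L]
    out[i] <- sqrt(min((p[1L] - qx)^2 + (p[2L] - qy)^2))
  }
  out
}

# Do any two non-adjacent edges of a closed polygon properly intersect?
# Bounding-box prefilter keeps the pairwise test affordable for the
# polygon sizes arising from single-slice defect cross-sections.
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  j <- c(2:n, 1L)
  ax <- pts[, 1L]; ay <- pts[, 2L]
  bx <- ax[j]; by <- ay[j]
  lox <- pmin(ax, bx); hix <- pmax(ax, bx)
  loy <- pmin(ay, by); hiy <- pmax(ay, by)
  cross2 <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]  # skip edge adjacent through closure
    ks <- ks[hix[ks] >= lox[i] & lox[ks] <= hix[i] &
             hiy[ks] >= loy[i] & loy[ks] <= hiy[i]]
    if (!length(ks)) next
    d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[ks], ay[ks])
    d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[ks], by[ks])
    d3 <- cross2(ax[ks], ay[ks], bx[ks], by[ks], ax[i], ay[i])
    d4 <- cross2(ax[ks], ay[ks], bx[ks], by[ks], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

## ---- one-sided convex hull and concavities ----------------------------

# The outer hull chain of an open curve: the subset of convex-hull
# vertices forming the chain on the declared articular (outward) side,
# returned in increasing profile-index order.  Index gaps in the chain
# bound concavities; for each gap the maximum perpendicular deviation of
# the intermediate points from the spanning chord is reported.
hull_concavities <- function(pts, outward = c(0, 1)) {
  n <- nrow(pts)
  hull <- grDevices::chull(pts)        # polygon order
  m <- length(hull)
  if (m < 2L)
    return(list(chain = seq_len(n), gaps = list()))
  lo <- hull[which.min(hull)]          # hull vertex with smallest index
  hi <- hull[which.max(hull)]          # ... and largest
  pos_lo <- match(lo, hull); pos_hi <- match(hi, hull)
  walk <- function(from, to) {
    if (from <= to) hull[from:to]
    else hull[c(from:m, 1:to)]
  }
  chain_a <- walk(pos_lo, pos_hi)
  chain_b <- rev(walk(pos_hi, pos_lo))
  score <- function(ch) mean(pts[ch, 1L] * outward[1L] +
                             pts[ch, 2L] * outward[2L])
  chain <- if (score(chain_a) >= score(chain_b)) chain_a else chain_b
  chain <- sort(unique(chain))
  gaps <- list()
  for (k in seq_len(length(chain) - 1L)) {
    i <- chain[k]; j <- chain[k + 1L]
    if (j > i + 1L) {
      dev <- point_line_distance(pts[(i + 1L):(j - 1L), , drop = FALSE],
                                 pts[i, ], pts[j, ])
      if (max(dev) <= 1e-9) next   # collinear run, not a concavity
      # chull drops vertices collinear with a hull edge; pull the gap
      # bounds inward over them so the tangent touches the concavity edge
      while (dev[1L] <= 1e-9) { i <- i + 1L; dev <- dev[-1L] }
      while (dev[length(dev)] <= 1e-9) { j <- j - 1L; dev <- dev[-length(dev)] }
      gaps[[length(gaps) + 1L]] <-
        list(start = i, end = j, max_deviation = max(dev),
             deepest = i + which.max(dev))
    }
  }
  list(chain = chain, gaps = gaps)
}
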