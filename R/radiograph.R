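#' Digitized lateral-radiograph condyle profile
#'
#' An ordered sequence of 2D points (mm) tracing the articular margin of the
#' lateral femoral condyle on a lateral knee radiograph, anterior to
#' posterior.  Because the profile is an open curve, the side away from the
#' bone must be declared: `outward` is a 2D vector pointing (on average)
#' from the bone across the articular margin; the condylopatellar sulcus
#' indents the profile against this direction.
#'
#' @param points Two-column numeric matrix of profile coordinates (mm).
#' @param outward Length-2 orientation vector pointing away from the bone;
#'   default `c(0, 1)` (bone below the profile).
#' @return An object of class `sulcus_profile`.
#' @export
sulcus_profile <- function(points, outward = c(0, 1)) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L)
    stop("a sulcus profile needs at least 3 points")
  dup <- rowSums((points[-1L, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE])^2) == 0
  if (any(dup)) stop("consecutive profile points must be distinct")
  nrm <- sqrt(sum(outward^2))
  if (length(outward) != 2L || nrm == 0)
    stop("outward must be a nonzero 2-vector")
  structure(list(points = points, outward = outward / nrm),
            class = "sulcus_profile")
}

#' Measure the depth of the lateral condylopatellar sulcus
#'
#' Implements the tangential-line technique used on lateral knee
#' radiographs: a line is drawn tangentially across the sulcus on the
#' articular surface of the condyle and the sulcus depth is the
#' perpendicular distance from that line to the deepest point of the
#' depression.  The tangent is found as the convex-hull edge (on the
#' articular side of the profile) spanning the concavity of greatest
#' perpendicular deviation; a convex profile has no concavity and measures
#' 0 mm, with the longest hull edge reported as tangent.  When several
#' concavities tie, the most anterior one is taken.
#'
#' @param profile A [sulcus_profile()] (or a two-column point matrix, taken
#'   with the default orientation).
#' @param threshold_mm Depth threshold for the notch-sign call, passed to
#'   [classify_notch_sign()].
#' @return An object of class `sulcus_measurement`: list with `depth_mm`,
#'   `tangent_segment` (2 x 2 matrix of endpoint coordinates),
#'   `deepest_point` (coordinates), and logical `notch_sign`.
#' @examples
#' th <- seq(0, pi, length.out = 181)
#' convex <- sulcus_profile(cbind(cos(th), sin(th)) * 20, outward = c(0, 1))
#' measure_sulcus_depth(convex)$depth_mm   # 0: no concavity
#' @export
measure_sulcus_depth <- function(profile, threshold_mm = 1.5) {
  if (!inherits(profile, "sulcus_profile")) profile <- sulcus_profile(profile)
  pts <- profile$points
  hc <- hull_concavities(pts, profile$outward)
  if (length(hc$gaps) == 0L) {
    ch <- hc$chain
    seg_len <- sqrt(rowSums((pts[ch[-1L], , drop = FALSE] -
                             pts[ch[-length(ch)], , drop = FALSE])^2))
    k <- which.max(seg_len)
    res <- list(depth_mm = 0,
                tangent_segment = pts[c(ch[k], ch[k + 1L]), , drop = FALSE],
                deepest_point = NULL,
                notch_sign = classify_notch_sign(0, threshold_mm))
    return(structure(res, class = "sulcus_measurement"))
  }
  devs <- vapply(hc$gaps, `[[`, numeric(1L), "max_deviation")
  starts <- vapply(hc$gaps, `[[`, numeric(1L), "start")
  best <- order(-devs, starts)[1L]          # deepest; anterior breaks ties
  g <- hc$gaps[[best]]
  res <- list(depth_mm = g$max_deviation,
              tangent_segment = pts[c(g$start, g$end), , drop = FALSE],
              deepest_point = pts[g$deepest, ],
              notch_sign = classify_notch_sign(g$max_deviation, threshold_mm))
  structure(res, class = "sulcus_measurement")
}

#' Classify the lateral femoral notch sign
#'
#' A sulcus depth of 1.5 mm or more on the lateral radiograph is the
#' conventional screening criterion for the lateral femoral notch sign
#' (about three standard deviations above the ~0.5 mm depth of the intact
#' sulcus).  The comparison is inclusive: exactly 1.5 mm is positive.
#'
#' @param depth_mm Measured sulcus depth (mm), non-negative.
#' @param threshold_mm Classification threshold (mm), default 1.5.
#' @return Logical: `TRUE` if `depth_mm >= threshold_mm`.
#' @examples
#' classify_notch_sign(1.5)    # TRUE (boundary is inclusive)
#' classify_notch_sign(0.5)    # FALSE (typical intact-sulcus depth)
#' @export
classify_notch_sign <- function(depth_mm, threshold_mm = 1.5) {
  if (any(!is.finite(depth_mm)) || any(depth_mm < 0))
    stop("depth_mm must be finite and non-negative")
  depth_mm >= threshold_mm
}

#' @export
print.sulcus_measurement <- function(x, ...) {
  cat(sprintf("<sulcus_measurement> depth %.2f mm; notch sign: %s\n",
              x$depth_mm, if (x$notch_sign) "POSITIVE" else "negative"))
  invisible(x)
}

#' @export
plot.sulcus_measurement <- function(x, profile = NULL, ...) {
  if (is.null(profile))
    stop("supply the measured profile: plot(m, profile = p)")
  pts <- if (inherits(profile, "sulcus_profile")) profile$points else profile
  graphics::plot(pts, type = "l", asp = 1, xlab = "mm", ylab = "mm", ...)
  graphics::segments(x$tangent_segment[1L, 1L], x$tangent_segment[1L, 2L],
                     x$tangent_segment[2L, 1L], x$tangent_segment[2L, 2L],
                     col = "red")
  if (!is.null(x$deepest_point))
    graphics::points(x$deepest_point[1L], x$deepest_point[2L],
                     pch = 4, col = "blue")
  invisible(x)
}
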