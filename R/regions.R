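#' Anatomical landmarks for the regional partition
#'
#' The six-segment partition of the lateral condyle is constructed from
#' anatomy: the first separating plane passes through the trochlear notch,
#' spanned by the femoral-shaft direction and the vector connecting the
#' most posterior points of the medial and lateral condyles; a second,
#' parallel plane sits at 60 % of the notch-to-posterior distance.
#'
#' @param trochlear_notch_point 3D point (mm) at the trochlear notch.
#' @param posterior_point_medial,posterior_point_lateral 3D points (mm) at
#'   the most posterior aspect of the medial and lateral condyles.
#' @param shaft_axis_direction Unit 3-vector along the femoral shaft.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(trochlear_notch_point, posterior_point_medial,
                      posterior_point_lateral, shaft_axis_direction) {
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 3L || anyNA(v) || any(!is.finite(v)))
      stop(nm, " must be a finite 3-vector")
    as.numeric(v)
  }
  sa <- chk(shaft_axis_direction, "shaft_axis_direction")
  if (sqrt(sum(sa^2)) == 0) stop("shaft_axis_direction must be nonzero")
  structure(list(
    trochlear_notch_point = chk(trochlear_notch_point,
                                "trochlear_notch_point"),
    posterior_point_medial = chk(posterior_point_medial,
                                 "posterior_point_medial"),
    posterior_point_lateral = chk(posterior_point_lateral,
                                  "posterior_point_lateral"),
    shaft_axis_direction = sa / sqrt(sum(sa^2))),
    class = "landmarks")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build the six-segment partition of the condyle surface
#'
#' Plane 1 (trochlea/condyle separator) is spanned by the shaft axis and
#' the medial-to-lateral posterior-points vector and passes through the
#' trochlear notch.  Plane 2 is parallel to it, offset posteriorly by 60 %
#' of the signed notch-to-posterior distance, separating the central
#' weight-bearing segment from the posterior segment.  The internal
#' (medial) / external (lateral) split lies at 50 % of the medio-lateral
#' extent of the segmented surface.
#'
#' @param slices List of [slice_contour()] (positions define the
#'   medio-lateral extent).
#' @param lm A [landmarks()] object.
#' @return An object of class `region_partition`: plane origin and unit
#'   anterior normal, the plane-2 offset (signed distance, negative =
#'   posterior), the medio-lateral split coordinate and lateral sign, and
#'   the segment labels.
#' @export
build_partition <- function(slices, lm) {
  stopifnot(inherits(lm, "landmarks"))
  if (length(slices) < 2L) stop("partition needs at least 2 slices")
  ml_vec <- lm$posterior_point_lateral - lm$posterior_point_medial
  nrm_ml <- sqrt(sum(ml_vec^2))
  if (nrm_ml == 0) stop("posterior landmark points coincide")
  normal <- cross3(lm$shaft_axis_direction, ml_vec / nrm_ml)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-8)
    stop("degenerate landmarks: shaft axis is parallel to the ",
         "posterior-points vector")
  normal <- normal / nn
  post_mid <- (lm$posterior_point_medial + lm$posterior_point_lateral) / 2
  s_post <- sum((post_mid - lm$trochlear_notch_point) * normal)
  if (s_post == 0)
    stop("degenerate landmarks: posterior points lie in the notch plane")
  if (s_post > 0) { normal <- -normal; s_post <- -s_post }  # anterior = +
  xs <- vapply(slices, function(s) s$x_ml_mm, numeric(1L))
  ml_split <- (min(xs) + max(xs)) / 2
  lateral_sign <- sign(lm$posterior_point_lateral[1L] -
                       lm$posterior_point_medial[1L])
  if (lateral_sign == 0) lateral_sign <- 1
  structure(list(plane_origin = lm$trochlear_notch_point,
                 plane_normal = normal,
                 plane2_offset = 0.6 * s_post,
                 ml_split = ml_split,
                 lateral_sign = lateral_sign,
                 labels = c("AI", "AE", "CI", "CE", "PI", "PE")),
            class = "region_partition")
}

# Segment label of 3D points (rows): anterior/central/posterior by signed
# distance to plane 1, internal/external by side of the medio-lateral split.
segment_label <- function(partition, pts) {
  s <- (pts[, 1L] - partition$plane_origin[1L]) * partition$plane_normal[1L] +
       (pts[, 2L] - partition$plane_origin[2L]) * partition$plane_normal[2L] +
       (pts[, 3L] - partition$plane_origin[3L]) * partition$plane_normal[3L]
  ap <- ifelse(s > 0, "A", ifelse(s > partition$plane2_offset, "C", "P"))
  side <- ifelse((pts[, 1L] - partition$ml_split) *
                   partition$lateral_sign > 0, "E", "I")
  paste0(ap, side)
}

#' Per-segment surface and defect metrics
#'
#' Assigns every triangle of the reconstructed surface to exactly one of
#' the six segments by centroid position and accumulates per-segment
#' surface area; defect quantities are attributed the same way on the
#' primary (bridged) and concave (depressed) strip meshes, so segment
#' values sum exactly to the totals.  Defect volume is distributed over
#' segments in proportion to each segment's share of the primary area.
#' Per-segment extent measures (length, width, depth) are taken over the
#' depressed points falling in the segment.
#'
#' @param partition A [build_partition()] result.
#' @param slices List of [slice_contour()] / `bridged_slice` objects in
#'   increasing slice order (the full segmentation).
#' @param bridged The same list after [bridge_all()]; defaults to bridging
#'   `slices` on the fly.
#' @param k Resample points per contour.
#' @return A `data.frame` of class `segment_metrics` with one row per
#'   segment: `region`, `region_surface_cm2`, `defect_length_mm`,
#'   `defect_width_mm`, `defect_depth_mm`, `affected_area_cm2`,
#'   `percent_of_region`, `concave_area_cm2`, `volume_mm3`.
#' @export
assign_regions <- function(partition, slices, bridged = bridge_all(slices),
                           k = 200) {
  stopifnot(inherits(partition, "region_partition"))
  labs <- partition$labels
  zero <- stats::setNames(numeric(length(labs)), labs)

  prepped <- lapply(bridged, substituted_contour)
  mesh <- reconstruct_surface(prepped, k = k)
  tri_lab <- segment_label(partition, triangle_centroids(mesh))
  areas <- triangle_areas(mesh)
  region_mm2 <- zero
  agg <- tapply(areas, factor(tri_lab, levels = labs), sum, default = 0)
  region_mm2[labs] <- agg[labs]

  is_def <- vapply(bridged, inherits, logical(1L), "bridged_slice")
  affected_mm2 <- concave_mm2 <- vol <- zero
  len <- wid <- dep <- zero
  if (any(is_def)) {
    defs <- bridged[is_def]
    xs <- vapply(bridged, function(s) as_contour(s)$x_ml_mm, numeric(1L))
    xd <- xs[is_def]
    for (field in c("bridge_points", "depressed_points")) {
      m <- defect_strip_mesh(defs, xd, field, k)
      if (!is.null(m)) {
        fl <- segment_label(partition, triangle_centroids(m))
        fa <- triangle_areas(m)
        acc <- tapply(fa, factor(fl, levels = labs), sum, default = 0)
        if (field == "bridge_points") affected_mm2[labs] <- acc[labs]
        else concave_mm2[labs] <- acc[labs]
      }
    }
    gaps <- numeric(length(bridged))
    gaps[is_def] <- vapply(defs, slice_gap_area, numeric(1L))
    total_vol <- if (length(xs) > 1L) trapz(xs, gaps) else 0
    if (sum(affected_mm2) > 0)
      vol <- total_vol * affected_mm2 / sum(affected_mm2)

    spacing <- as_contour(defs[[1L]])$slice_spacing_mm
    x_contrib <- stats::setNames(rep(list(numeric(0)), length(labs)), labs)
    for (i in seq_along(defs)) {
      b <- defs[[i]]
      p3 <- cbind(xd[i], b$depressed_points)
      pl <- segment_label(partition, p3)
      dists <- point_polyline_distance(b$depressed_points, b$bridge_points)
      for (lab in unique(pl)) {
        sel <- pl == lab
        ylim <- range(b$depressed_points[sel, 1L])
        len[lab] <- max(len[lab], diff(ylim))
        dep[lab] <- max(dep[lab], max(dists[sel]))
        x_contrib[[lab]] <- c(x_contrib[[lab]], xd[i])
      }
    }
    for (lab in labs)
      if (length(x_contrib[[lab]]))
        wid[lab] <- diff(range(x_contrib[[lab]])) + spacing
  }

  out <- data.frame(
    region = labs,
    region_surface_cm2 = convert_mm2_to_cm2(region_mm2),
    defect_length_mm = as.numeric(len),
    defect_width_mm = as.numeric(wid),
    defect_depth_mm = as.numeric(dep),
    affected_area_cm2 = convert_mm2_to_cm2(affected_mm2),
    percent_of_region = ifelse(region_mm2 > 0,
                               100 * affected_mm2 / region_mm2, 0),
    concave_area_cm2 = convert_mm2_to_cm2(concave_mm2),
    volume_mm3 = as.numeric(vol),
    row.names = NULL)
  class(out) <- c("segment_metrics", "data.frame")
  out
}

#' Primary defect location
#'
#' The per-knee location call: the segment holding the largest share of the
#' primary (bridged) defect area.  Exact ties are broken in the fixed order
#' CE, CI, AE, AI, PE, PI (central-external first, matching the most common
#' clinical location).
#'
#' @param segments A [assign_regions()] result (or any data frame with
#'   `region` and `affected_area_cm2`).
#' @return A segment label, or `"none"` when no segment carries defect
#'   area.
#' @export
classify_primary_location <- function(segments) {
  pref <- c("CE", "CI", "AE", "AI", "PE", "PI")
  a <- stats::setNames(segments$affected_area_cm2, segments$region)
  a <- a[pref[pref %in% names(a)]]
  if (all(a <= 0)) return("none")
  names(a)[which.max(a)]
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(paste0("<region_partition> plane normal (%.2f, %.2f, %.2f), ",
                     "plane-2 offset %.2f mm, ml split %.2f mm\n"),
              x$plane_normal[1L], x$plane_normal[2L], x$plane_normal[3L],
              x$plane2_offset, x$ml_split))
  invisible(x)
}
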