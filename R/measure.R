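#' Measure one knee end to end
#'
#' The full MRI morphometry pipeline for a single knee: bridge every
#' marked slice (optionally auto-detecting unmarked depressions first),
#' reconstruct the subchondral bone surface, compute total and defect
#' metrics, and - when landmarks are available - partition the condyle
#' into the six anatomical segments and localize the defect.
#'
#' @param slices List of [slice_contour()] in increasing slice order.
#' @param landmarks Optional [landmarks()]; required for the regional
#'   breakdown.
#' @param detect If `TRUE`, run [detect_defect_interval()] on contours
#'   without an expert mark.  Marks present in the input are always
#'   authoritative.
#' @param detect_threshold Deviation threshold (mm) for detection.
#' @param n_flank Flank vertices per side for the bridge spline.
#' @param k Resample points per contour for surface reconstruction.
#' @return An object of class `notch_knee`: list with `total`
#'   ([total_surface_area()]), `metrics` ([defect_metrics()]), and, when
#'   landmarks were given, `partition`, `segments` and `location`.
#' @examples
#' ph <- generate_phantom(phantom_spec(slice_spacing_mm = 3,
#'                                     in_plane_step_mm = 0.5))
#' knee <- measure_knee(ph$slices, ph$landmarks)
#' knee$metrics$depth_mm
#' knee$location
#' @export
measure_knee <- function(slices, landmarks = NULL, detect = FALSE,
                         detect_threshold = 0.3, n_flank = 5, k = 200) {
  if (detect) {
    slices <- lapply(slices, function(s) {
      if (is.null(s$mark))
        s$mark <- detect_defect_interval(s, detect_threshold)
      s
    })
  }
  bridged <- bridge_all(slices, n_flank = n_flank)
  total <- total_surface_area(bridged, k = k)
  metrics <- defect_metrics(bridged, total, k = k)
  out <- list(total = total, metrics = metrics, partition = NULL,
              segments = NULL, location = NULL)
  if (!is.null(landmarks)) {
    out$partition <- build_partition(slices, landmarks)
    out$segments <- assign_regions(out$partition, slices, bridged, k = k)
    out$location <- classify_primary_location(out$segments)
  }
  structure(out, class = "notch_knee")
}

#' @export
print.notch_knee <- function(x, ...) {
  cat(sprintf("<notch_knee> condyle surface %.1f cm^2\n",
              x$total$total_area_cm2))
  print(x$metrics)
  if (!is.null(x$location))
    cat(sprintf("  primary location: %s\n", x$location))
  invisible(x)
}

#' @export
summary.notch_knee <- function(object, ...) {
  cat("Knee morphometry\n")
  cat("----------------\n")
  print(object)
  if (!is.null(object$segments)) {
    cat("Per-segment breakdown:\n")
    print(format_segment_table(object$segments), row.names = FALSE)
  }
  invisible(object)
}

#' Defect metrics as a one-row data frame
#'
#' @param x A `notch_knee` or `defect_metrics` object.
#' @param ... Unused.
#' @return A one-row `data.frame` with the total condyle area (when
#'   available) and the defect metric columns, named exactly as the
#'   metric fields.
#' @export
as.data.frame.notch_knee <- function(x, ...) {
  cbind(data.frame(total_area_cm2 = x$total$total_area_cm2),
        as.data.frame(unclass(x$metrics)))
}

#' @export
as.data.frame.defect_metrics <- function(x, ...) {
  as.data.frame(unclass(x))
}
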