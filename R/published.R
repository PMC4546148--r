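#' Reference per-segment table for the clinical cohort
#'
#' The published per-segment averages for a reference cohort of 50
#' ACL-injured knees with a lateral femoral notch sign, in the schema of
#' [assign_regions()].  These values are reference data for the
#' internal-consistency arithmetic ([consistency_checks()]); the package
#' does not recompute them (the underlying images are not public).
#'
#' Columns: region surface and areas in cm^2, extents and depth in mm,
#' volume in mm^3.  The printed percent-of-region column of the source
#' table does not equal affected/region from the printed values; it is
#' carried as-is and not used by any check.
#'
#' @return A `data.frame` of class `segment_metrics`, one row per segment.
#' @seealso [reference_cohort_results()]
#' @export
reference_segment_table <- function() {
  out <- data.frame(
    region = c("CE", "CI", "AE", "AI", "PE", "PI"),
    region_surface_cm2 = c(4.0, 3.2, 6.6, 8.4, 6.8, 3.7),
    defect_length_mm = c(10.7, 8.6, 7.3, 3.4, 0.1, 0.0),
    defect_width_mm = c(13.0, 4.7, 11.0, 3.3, 0.2, 0.0),
    defect_depth_mm = c(2.8, 2.2, 2.1, 1.5, 0.1, 0.0),
    affected_area_cm2 = c(0.9, 0.2, 0.5, 0.06, 0.004, 0.0),
    percent_of_region = c(0.3, 0.08, 0.07, 0.008, 0.001, 0.0),
    concave_area_cm2 = c(1.3, 0.5, 0.7, 0.2, 0.007, 0.0),
    volume_mm3 = c(221.0, 85.3, 120.8, 28.2, 1.3, 0.0))
  class(out) <- c("segment_metrics", "data.frame")
  out
}

#' Reference cohort totals and screening counts
#'
#' The published cohort-level results accompanying
#' [reference_segment_table()]: mean total condyle surface, defect surface
#' (concave), affected (primary, bridged) surface, volume, depth and
#' percent-of-condyle over the 50 knees, each in the units the source
#' reports (several areas are given in both mm^2 and cm^2), plus the
#' screening funnel (radiographs examined, notch-positive radiographs,
#' knees excluded after MRI review, knees analyzed) and the share of
#' knees with the primary defect in the central-external segment.
#'
#' @return A list with components `totals` (for [consistency_checks()]),
#'   `screening` and `location_ce_percent`.
#' @export
reference_cohort_results <- function() {
  list(
    totals = list(
      total_area_mm2 = 3271.7, total_area_cm2 = 32.7,
      concave_area_mm2 = 266.1, concave_area_cm2 = 2.7,
      affected_area_mm2 = 169, affected_area_cm2 = 1.7,
      volume_mm3 = 456.5,
      depth_mm = 3.0,
      percent_of_condyle = 5.2),
    screening = list(radiographs_examined = 422,
                     notch_positive_radiographs = 64,
                     excluded_after_mri = 14,
                     knees_analyzed = 50),
    location_ce_percent = 51)
}

#' Reference summary object for the consistency checks
#'
#' Bundles [reference_segment_table()] and the totals of
#' [reference_cohort_results()] in the shape [consistency_checks()]
#' expects.
#'
#' @return A list with `segments` and `totals`.
#' @examples
#' consistency_checks(reference_summary())
#' @export
reference_summary <- function() {
  list(segments = reference_segment_table(),
       totals = reference_cohort_results()$totals)
}
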