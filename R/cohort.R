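#' A per-knee record
#'
#' Bundles the screening measurements and the MRI morphometry of one knee
#' for cohort-level aggregation.
#'
#' @param id Unique knee identifier.
#' @param sulcus_depth_mm Radiographic sulcus depth (mm), or `NA` if not
#'   screened.
#' @param mri_notch_confirmed Logical: notch sign confirmed on MRI, or
#'   `NA`.
#' @param metrics A [defect_metrics()] result (or compatible list).
#' @param total A [total_surface_area()] result or a number (cm^2).
#' @param segments Optional [assign_regions()] table.
#' @param location Optional primary-location label
#'   ([classify_primary_location()]); derived from `segments` when absent.
#' @return An object of class `knee_record`.
#' @export
knee_record <- function(id, sulcus_depth_mm = NA_real_,
                        mri_notch_confirmed = NA, metrics, total = NA_real_,
                        segments = NULL, location = NULL) {
  total_cm2 <- if (inherits(total, "condyle_metrics")) total$total_area_cm2
               else as.numeric(total)
  if (is.null(location) && !is.null(segments))
    location <- classify_primary_location(segments)
  structure(list(id = id,
                 sulcus_depth_mm = as.numeric(sulcus_depth_mm),
                 mri_notch_confirmed = mri_notch_confirmed,
                 metrics = metrics, total_area_cm2 = total_cm2,
                 segments = segments, location = location),
            class = "knee_record")
}

metric_fields <- c("ap_length_mm", "ml_width_mm", "depth_mm",
                   "primary_area_cm2", "concave_area_cm2", "volume_mm3",
                   "percent_of_condyle")

#' Screen a cohort by the notch-sign criterion
#'
#' Keeps knees whose radiographic sulcus depth meets the threshold
#' (inclusive) and whose notch sign was confirmed on MRI; suspicious
#' radiographs without MRI confirmation are excluded.  Record order is
#' preserved and the operation is idempotent.
#'
#' @param records List of [knee_record()] carrying `sulcus_depth_mm` and
#'   `mri_notch_confirmed`.
#' @param threshold_mm Sulcus-depth threshold (mm), default 1.5.
#' @return The retained records, in input order.
#' @export
screen_cohort <- function(records, threshold_mm = 1.5) {
  if (length(records) == 0L) return(records)
  missing_ids <- vapply(records, function(r) {
    if (is.na(r$sulcus_depth_mm) || is.na(r$mri_notch_confirmed))
      as.character(r$id) else NA_character_
  }, character(1L))
  missing_ids <- missing_ids[!is.na(missing_ids)]
  if (length(missing_ids))
    stop("records missing screening fields: ",
         paste(missing_ids, collapse = ", "))
  keep <- vapply(records, function(r) {
    classify_notch_sign(r$sulcus_depth_mm, threshold_mm) &&
      isTRUE(r$mri_notch_confirmed)
  }, logical(1L))
  records[keep]
}

#' Summarize a cohort of knee records
#'
#' Arithmetic means and standard deviations (n - 1 denominator; `NA` for a
#' single knee) of the total condyle area and every defect metric, the
#' per-segment mean table (averaging over all knees, zeros included, so
#' segment columns remain additive to the cohort totals), and the
#' primary-location frequency in percent.
#'
#' @param records Non-empty list of [knee_record()].
#' @return An object of class `cohort_summary`: list with `n`, `mean` and
#'   `sd` (named vectors over `total_area_cm2` and the defect metrics),
#'   `segments` (mean per-segment table), `totals` (the means, for
#'   [consistency_checks()]), and `location_freq` (percent per label).
#' @export
summarize_cohort <- function(records) {
  n <- length(records)
  if (n == 0L) stop("cannot summarize an empty cohort")
  fields <- c("total_area_cm2", metric_fields)
  vals <- vapply(records, function(r) {
    c(r$total_area_cm2,
      vapply(metric_fields, function(f) as.numeric(r$metrics[[f]]),
             numeric(1L)))
  }, numeric(length(fields)))
  vals <- matrix(vals, nrow = length(fields),
                 dimnames = list(fields, NULL))
  mu <- apply(vals, 1L, mean)
  sdv <- if (n > 1L) apply(vals, 1L, stats::sd)
         else stats::setNames(rep(NA_real_, length(fields)), fields)

  labs <- c("AI", "AE", "CI", "CE", "PI", "PE")
  seg_cols <- c("region_surface_cm2", "defect_length_mm", "defect_width_mm",
                "defect_depth_mm", "affected_area_cm2", "percent_of_region",
                "concave_area_cm2", "volume_mm3")
  seg_mean <- matrix(0, nrow = length(labs), ncol = length(seg_cols),
                     dimnames = list(labs, seg_cols))
  for (r in records) {
    if (is.null(r$segments)) next
    m <- as.matrix(r$segments[match(labs, r$segments$region), seg_cols])
    m[is.na(m)] <- 0
    seg_mean <- seg_mean + m
  }
  seg_mean <- seg_mean / n
  segments <- data.frame(region = labs, seg_mean, row.names = NULL)
  class(segments) <- c("segment_metrics", "data.frame")

  locs <- vapply(records, function(r) {
    if (is.null(r$location)) "none" else r$location
  }, character(1L))
  location_freq <- 100 * table(locs) / n

  totals <- list(total_area_cm2 = mu[["total_area_cm2"]],
                 affected_area_cm2 = mu[["primary_area_cm2"]],
                 concave_area_cm2 = mu[["concave_area_cm2"]],
                 volume_mm3 = mu[["volume_mm3"]],
                 percent_of_condyle = mu[["percent_of_condyle"]])
  structure(list(n = n, mean = mu, sd = sdv, segments = segments,
                 totals = totals,
                 location_freq = c(location_freq)),
            class = "cohort_summary")
}

#' Internal-consistency checks of a cohort summary
#'
#' Verifies the arithmetic that ties a per-segment table to its cohort
#' totals: (a) segment surfaces sum to the total condyle surface, (b)
#' segment affected (primary) areas sum to the total affected area, (c)
#' segment concave areas sum to the total defect surface, (d) segment
#' volumes sum to the total volume, (e) the percent-of-condyle equals
#' 100 x affected / total, and (f) any mm^2 / cm^2 value pairs agree at
#' one-decimal reporting precision.  Failures are reported, not raised.
#'
#' @param x A [summarize_cohort()] result, or any list with a `segments`
#'   table and a `totals` list (optionally carrying `total_area_mm2`,
#'   `affected_area_mm2`, `concave_area_mm2` for the unit pairings).
#' @param tol_per_term Absolute tolerance contributed by each printed
#'   value entering a check; the default 0.05 is the half-step of
#'   one-decimal rounding.  Pass a tiny value (e.g. `1e-9`) for
#'   full-precision summaries.
#' @return A `data.frame` of class `notch_checks` with columns `check`,
#'   `description`, `lhs`, `rhs`, `tol`, `pass`.
#' @export
consistency_checks <- function(x, tol_per_term = 0.05) {
  seg <- x$segments
  tot <- x$totals
  n_seg <- nrow(seg)
  rows <- list()
  add <- function(check, description, lhs, rhs, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, description = description, lhs = lhs, rhs = rhs,
      tol = tol, pass = is.finite(lhs) && is.finite(rhs) &&
        abs(lhs - rhs) <= tol)
  }
  sum_tol <- (n_seg + 1L) * tol_per_term
  add("a", "segment surfaces sum to total condyle surface [cm^2]",
      sum(seg$region_surface_cm2), tot$total_area_cm2, sum_tol)
  add("b", "segment affected areas sum to total affected area [cm^2]",
      sum(seg$affected_area_cm2), tot$affected_area_cm2, sum_tol)
  add("c", "segment concave areas sum to total defect surface [cm^2]",
      sum(seg$concave_area_cm2), tot$concave_area_cm2, sum_tol)
  add("d", "segment volumes sum to total defect volume [mm^3]",
      sum(seg$volume_mm3), tot$volume_mm3, sum_tol)
  if (!is.null(tot$percent_of_condyle) && tot$total_area_cm2 > 0) {
    # rounding of the affected area and total propagates into the ratio
    tol_e <- tol_per_term +
      100 * tol_per_term / tot$total_area_cm2 +
      100 * tot$affected_area_cm2 * tol_per_term / tot$total_area_cm2^2
    add("e", "percent of condyle equals 100 x affected / total [%]",
        tot$percent_of_condyle,
        100 * tot$affected_area_cm2 / tot$total_area_cm2, tol_e)
  }
  pairs <- list(c("total_area_mm2", "total_area_cm2"),
                c("affected_area_mm2", "affected_area_cm2"),
                c("concave_area_mm2", "concave_area_cm2"))
  for (p in pairs) {
    if (is.null(tot[[p[1L]]]) || is.null(tot[[p[2L]]])) next
    add("f", paste0("unit pairing ", p[1L], " / ", p[2L], " [cm^2]"),
        convert_mm2_to_cm2(tot[[p[1L]]]), tot[[p[2L]]],
        tol_per_term + tol_per_term / 100)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("notch_checks", "data.frame")
  out
}

#' @export
print.notch_checks <- function(x, ...) {
  cat("Internal-consistency checks:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-55s %10.4f vs %10.4f  %s\n",
                x$check[i], x$description[i], x$lhs[i], x$rhs[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  cat(sprintf("%d of %d checks pass\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d knees\n", x$n))
  flds <- names(x$mean)
  for (f in flds)
    cat(sprintf("  %-20s mean %8.1f   SD %s\n", f, x$mean[[f]],
                if (is.na(x$sd[[f]])) "   --" else sprintf("%8.1f", x$sd[[f]])))
  cat("Per-segment means:\n")
  print(format_segment_table(x$segments), row.names = FALSE)
  cat("Primary location (%):\n")
  print(round(x$location_freq, 1))
  invisible(x)
}

format_segment_table <- function(seg) {
  out <- seg
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], round, digits = 1L)
  out
}
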