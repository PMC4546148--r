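SEG_FORMAT <- "notchmorph-segmentation"
SEG_VERSION <- 1L

#' Write a segmentation exchange file
#'
#' Serializes a knee segmentation (ordered slice contours with optional
#' defect marks, plus optional landmarks and provenance metadata) to the
#' package's JSON exchange format.  The header records the format version,
#' units (mm) and axis convention explicitly; files round-trip losslessly
#' through [read_segmentation()].
#'
#' @param slices List of [slice_contour()] in increasing slice order.
#' @param path Output file path.
#' @param landmarks Optional [landmarks()].
#' @param knee_id Knee identifier stored in the file.
#' @param metadata Optional named list of provenance text fields (scanner,
#'   sequence, field strength, ...).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(slices, path, landmarks = NULL,
                               knee_id = "knee", metadata = NULL) {
  xs <- vapply(slices, function(s) s$x_ml_mm, numeric(1L))
  if (any(diff(xs) <= 0))
    stop("slices must be strictly ordered by x_ml_mm before writing")
  doc <- list(
    format = SEG_FORMAT,
    version = SEG_VERSION,
    units = "mm",
    axes = list(x = "medial->lateral", y = "posterior->anterior",
                z = "distal->proximal",
                slice_plane = "sagittal (constant x); in-plane coords (y, z)"),
    knee_id = as.character(knee_id))
  if (!is.null(metadata)) doc$metadata <- metadata
  if (!is.null(landmarks))
    doc$landmarks <- list(
      trochlear_notch_point = landmarks$trochlear_notch_point,
      posterior_point_medial = landmarks$posterior_point_medial,
      posterior_point_lateral = landmarks$posterior_point_lateral,
      shaft_axis_direction = landmarks$shaft_axis_direction)
  doc$slices <- lapply(slices, function(s) {
    sl <- list(x_ml_mm = s$x_ml_mm, slice_spacing_mm = s$slice_spacing_mm,
               points = s$points)
    if (!is.null(s$mark))
      sl$defect_mark <- list(start_index = s$mark$start_index,
                             end_index = s$mark$end_index)
    sl
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a segmentation exchange file
#'
#' Parses and fully validates a file written by [write_segmentation()]:
#' the declared version must be supported, slice positions strictly
#' increasing, and every contour and mark well-formed.  Parse errors name
#' the offending slice.
#'
#' @param path File path.
#' @return A list with `slices` (list of [slice_contour()], marks
#'   attached), `landmarks` ([landmarks()] or `NULL`), `knee_id` and
#'   `metadata`.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, SEG_FORMAT))
    stop("not a ", SEG_FORMAT, " file: ", path)
  if (!identical(as.integer(doc$version), SEG_VERSION))
    stop("unsupported segmentation format version ", doc$version,
         " (supported: ", SEG_VERSION, ")")
  if (is.null(doc$slices) || length(doc$slices) == 0L)
    stop("segmentation file contains no slices: ", path)
  slices <- vector("list", length(doc$slices))
  for (i in seq_along(doc$slices)) {
    sl <- doc$slices[[i]]
    pts <- sl$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    mark <- if (!is.null(sl$defect_mark))
      defect_mark(sl$defect_mark$start_index, sl$defect_mark$end_index)
    slices[[i]] <- tryCatch(
      slice_contour(sl$x_ml_mm, pts, sl$slice_spacing_mm, mark),
      error = function(e)
        stop("slice ", i, " of ", path, ": ", conditionMessage(e),
             call. = FALSE))
  }
  xs <- vapply(slices, function(s) s$x_ml_mm, numeric(1L))
  if (anyDuplicated(xs))
    stop("duplicate slice positions in ", path)
  if (any(diff(xs) <= 0))
    stop("slice positions not strictly increasing in ", path,
         " (first violation after slice ", which(diff(xs) <= 0)[1L], ")")
  lm <- NULL
  if (!is.null(doc$landmarks))
    lm <- landmarks(doc$landmarks$trochlear_notch_point,
                    doc$landmarks$posterior_point_medial,
                    doc$landmarks$posterior_point_lateral,
                    doc$landmarks$shaft_axis_direction)
  list(slices = slices, landmarks = lm,
       knee_id = doc$knee_id, metadata = doc$metadata)
}

#' Read and write digitized radiograph profiles
#'
#' Profiles travel as two-column CSV (`x_mm`, `y_mm`) preceded by a
#' one-line orientation header `# outward: dx dy` declaring the side away
#' from the bone.
#'
#' @param path File path.
#' @param profile A [sulcus_profile()] (for writing).
#' @return `read_sulcus_profile()` returns a [sulcus_profile()];
#'   `write_sulcus_profile()` returns `path` invisibly.
#' @export
read_sulcus_profile <- function(path) {
  first <- readLines(path, n = 1L)
  outward <- c(0, 1)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec(
      "outward:\\s*(-?[0-9.]+)[ ,]+(-?[0-9.]+)", first))[[1L]]
    if (length(m) == 3L) outward <- as.numeric(m[2:3])
  }
  df <- utils::read.csv(path, skip = skip)
  if (ncol(df) < 2L) stop("profile CSV needs columns x_mm, y_mm: ", path)
  sulcus_profile(as.matrix(df[, 1:2]), outward = outward)
}

#' @rdname read_sulcus_profile
#' @export
write_sulcus_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sulcus_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# outward: %g %g", profile$outward[1L],
                     profile$outward[2L]), con)
  utils::write.csv(data.frame(x_mm = profile$points[, 1L],
                              y_mm = profile$points[, 2L]),
                   con, row.names = FALSE)
  invisible(path)
}

#' Write metric tables as CSV
#'
#' `write_metrics_csv()` writes one row per knee with the defect metric
#' columns (named exactly as the metric fields, total condyle area
#' first); `write_segments_csv()` writes a per-segment table in the
#' column order of [assign_regions()].  Both use `.` as decimal separator
#' and a fixed column order for reproducible reports.
#'
#' @param x A `notch_knee`, `defect_metrics` or `segment_metrics` object
#'   (or a data frame already in the right schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  df <- if (inherits(x, c("notch_knee", "defect_metrics")))
    as.data.frame(x) else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_segments_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write the phantom ground-truth sidecar
#'
#' One row per closed-form metric of a generated phantom, as CSV.
#'
#' @param phantom A [generate_phantom()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "notch_phantom"))
  tr <- phantom$truth
  utils::write.csv(data.frame(metric = names(tr),
                              value = vapply(tr, as.numeric, numeric(1L))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Cohort CSV round trip
#'
#' One row per knee: screening fields, total area, the defect metrics,
#' the primary-location label, and (when present) the per-segment table
#' flattened into `<REGION>_<column>` columns.
#'
#' @param records List of [knee_record()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a list of [knee_record()].
#' @export
write_cohort_csv <- function(records, path) {
  labs <- c("AI", "AE", "CI", "CE", "PI", "PE")
  seg_cols <- c("region_surface_cm2", "defect_length_mm", "defect_width_mm",
                "defect_depth_mm", "affected_area_cm2", "percent_of_region",
                "concave_area_cm2", "volume_mm3")
  rows <- lapply(records, function(r) {
    base <- data.frame(id = as.character(r$id),
                       sulcus_depth_mm = r$sulcus_depth_mm,
                       mri_notch_confirmed = r$mri_notch_confirmed,
                       total_area_cm2 = r$total_area_cm2)
    met <- as.data.frame(lapply(r$metrics[metric_fields], as.numeric))
    base <- cbind(base, met,
                  location = if (is.null(r$location)) NA_character_
                             else r$location)
    if (!is.null(r$segments)) {
      seg <- r$segments[match(labs, r$segments$region), seg_cols]
      flat <- as.data.frame(as.list(stats::setNames(
        unlist(seg), paste(rep(labs, times = length(seg_cols)),
                           rep(seg_cols, each = length(labs)), sep = "_"))))
      base <- cbind(base, flat)
    }
    base
  })
  ncols <- vapply(rows, ncol, integer(1L))
  if (length(unique(ncols)) > 1L)
    stop("all records must carry the same fields (mixed segment tables)")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labs <- c("AI", "AE", "CI", "CE", "PI", "PE")
  seg_cols <- c("region_surface_cm2", "defect_length_mm", "defect_width_mm",
                "defect_depth_mm", "affected_area_cm2", "percent_of_region",
                "concave_area_cm2", "volume_mm3")
  has_seg <- all(paste(rep(labs, length(seg_cols)),
                       rep(seg_cols, each = length(labs)),
                       sep = "_") %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    metrics <- structure(as.list(df[i, metric_fields]),
                         class = "defect_metrics")
    segments <- NULL
    if (has_seg) {
      segments <- data.frame(region = labs)
      for (col in seg_cols)
        segments[[col]] <- as.numeric(df[i, paste(labs, col, sep = "_")])
      class(segments) <- c("segment_metrics", "data.frame")
    }
    knee_record(id = df$id[i],
                sulcus_depth_mm = df$sulcus_depth_mm[i],
                mri_notch_confirmed = df$mri_notch_confirmed[i],
                metrics = metrics, total = df$total_area_cm2[i],
                segments = segments,
                location = if (!is.null(df$location) &&
                               !is.na(df$location[i])) df$location[i])
  })
}
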