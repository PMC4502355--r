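# Regional peaks, focality and montage comparison.
#
# "Peak" field values on a voxel grid are sensitive to discretization
# spikes at electrode and tissue edges, so peaks are reported both as the
# absolute maximum and as a robust high percentile (99.9th for masks of
# at least 1e4 voxels, plain maximum for smaller masks).

#' Robust peak of a field magnitude over a mask
#'
#' @param magnitude 3-D array (e.g. `solution$Emag`).
#' @param mask Logical array of the same dimensions.
#' @param percentile Percentile in (50, 100]; default 99.9.
#' @return List with `robust` (the percentile) and `max`.
#' @export
peak_field <- function(magnitude, mask, percentile = 99.9) {
  if (!any(mask)) stop("mask error: empty mask", call. = FALSE)
  if (!(percentile > 50 && percentile <= 100))
    stop("percentile must be in (50, 100]", call. = FALSE)
  v <- magnitude[mask]
  v <- v[!is.na(v)]
  list(robust = stats::quantile(v, percentile / 100, names = FALSE),
       max = max(v))
}

#' @keywords internal
robust_or_max <- function(v, percentile, min_n = 1e4) {
  if (length(v) >= min_n)
    stats::quantile(v, percentile / 100, names = FALSE) else max(v)
}

#' Per-ROI field summary
#'
#' @param solution A `field_solution` with `Emag` and `Jmag`.
#' @param rois A `roi_volume` from [label_rois()].
#' @param percentile Robust-peak percentile.
#' @return A data.frame (class `roi_report`) with one row per ROI:
#'   `peak_E` (robust), `max_E`, `mean_E` (V/m), `peak_J` (A/m^2),
#'   `n_voxels`; plus the montage name and percentile as attributes.
#' @export
roi_summary <- function(solution, rois, percentile = 99.9) {
  stopifnot(inherits(solution, "field_solution"),
            inherits(rois, "roi_volume"))
  if (!identical(dim(rois$labels), solution$dim) ||
      max(abs(rois$origin - solution$origin)) > 1e-9)
    stop("geometry error: ROI and solution lattices are not aligned",
         call. = FALSE)
  rows <- lapply(names(rois$label_codes), function(nm) {
    m <- rois$labels == rois$label_codes[[nm]]
    e <- solution$Emag[m]; j <- solution$Jmag[m]
    ok <- !is.na(e)
    e <- e[ok]; j <- j[ok]
    data.frame(roi = nm,
               peak_E = robust_or_max(e, percentile),
               max_E = max(e),
               mean_E = mean(e),
               peak_J = robust_or_max(j, percentile),
               n_voxels = length(e))
  })
  out <- do.call(rbind, rows)
  attr(out, "montage") <- solution$montage
  attr(out, "percentile") <- percentile
  attr(out, "voxel_size") <- solution$voxel_size
  class(out) <- c("roi_report", "data.frame")
  out
}

#' Brain mask of a solved montage
#'
#' Gray plus white matter voxels of the labeled volume carried by the
#' solution.
#'
#' @param solution A `field_solution` from [solve_montage()].
#' @return Logical array.
#' @export
brain_mask <- function(solution) {
  stopifnot(!is.null(solution$labels))
  solution$labels == solution$label_codes[["gray"]] |
    solution$labels == solution$label_codes[["white"]]
}

#' Focality of the induced field
#'
#' Focal volume is the brain volume carrying at least `fraction` of the
#' robust brain peak (volume at half maximum by default); a smaller focal
#' volume means a more focal montage. A depth profile (median |E| in 5 mm
#' bins of distance below the scalp surface radius) is included.
#'
#' @param solution A `field_solution` with `Emag`.
#' @param brain Logical brain mask.
#' @param fraction Fraction of the robust peak, in (0, 1); default 0.5.
#' @param percentile Robust-peak percentile.
#' @param scalp_radius_mm Scalp radius used for the depth axis; defaults
#'   to the maximum radius of any non-air voxel.
#' @return List of class `focality_report`: `peak_E`, `max_E`,
#'   `focal_volume_mm3`, `brain_volume_mm3`, `depth_profile` (data.frame).
#' @export
focality_volume <- function(solution, brain, fraction = 0.5,
                            percentile = 99.9, scalp_radius_mm = NULL) {
  stopifnot(inherits(solution, "field_solution"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)", call. = FALSE)
  if (!any(brain)) stop("mask error: empty brain mask", call. = FALSE)
  e <- solution$Emag[brain]
  e <- e[!is.na(e)]
  vox_mm3 <- solution$voxel_size^3
  peak <- robust_or_max(e, percentile)
  focal <- if (peak == 0) 0 else sum(e >= fraction * peak) * vox_mm3

  co <- coord_arrays(solution$dim, solution$voxel_size, solution$origin)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  if (is.null(scalp_radius_mm)) {
    skin <- solution$labels == solution$label_codes[["skin"]]
    scalp_radius_mm <- max(r[skin])
  }
  depth <- (scalp_radius_mm - r)[brain][!is.na(solution$Emag[brain])]
  bins <- floor(depth / 5) * 5
  prof <- stats::aggregate(list(median_E = e),
                           by = list(depth_mm = bins), FUN = stats::median)
  prof <- prof[order(prof$depth_mm), ]
  structure(list(peak_E = peak, max_E = max(e),
                 focal_volume_mm3 = focal,
                 brain_volume_mm3 = length(e) * vox_mm3,
                 fraction = fraction,
                 depth_profile = prof,
                 montage = solution$montage),
            class = "focality_report")
}

#' Compare montages on a common phantom
#'
#' @param roi_reports Named list (by montage) of [roi_summary()] outputs.
#' @param focality_reports Optional named list of [focality_volume()]
#'   outputs for the same montages.
#' @param deep_rois ROIs counted as deep structures for the
#'   deep/superficial peak ratio.
#' @return List with `table` (long data.frame: montage, roi, metric,
#'   value) and `summary` (per montage: focal volume, deep and superficial
#'   robust peaks and their ratio).
#' @export
compare_montages <- function(roi_reports, focality_reports = NULL,
                             deep_rois = c("thalamus", "brainstem",
                                           "cingulate", "insula_L",
                                           "insula_R")) {
  if (length(roi_reports) < 2)
    stop("need at least two montages to compare", call. = FALSE)
  vs <- vapply(roi_reports, function(r) attr(r, "voxel_size"), 0)
  rois0 <- sort(roi_reports[[1]]$roi)
  for (r in roi_reports) {
    if (!identical(sort(r$roi), rois0) || attr(r, "voxel_size") != vs[1])
      stop("comparability error: reports come from different phantoms",
           call. = FALSE)
  }
  long <- do.call(rbind, lapply(names(roi_reports), function(nm) {
    r <- roi_reports[[nm]]
    do.call(rbind, lapply(c("peak_E", "max_E", "mean_E", "peak_J"),
                          function(metric)
      data.frame(montage = nm, roi = r$roi, metric = metric,
                 value = r[[metric]])))
  }))
  summary <- do.call(rbind, lapply(names(roi_reports), function(nm) {
    r <- roi_reports[[nm]]
    deep <- max(r$peak_E[r$roi %in% deep_rois])
    sup <- max(r$peak_E[!r$roi %in% deep_rois])
    data.frame(montage = nm, deep_peak_E = deep, superficial_peak_E = sup,
               deep_superficial_ratio = deep / sup,
               focal_volume_mm3 = if (!is.null(focality_reports))
                 focality_reports[[nm]]$focal_volume_mm3 else NA_real_)
  }))
  list(table = long, summary = summary)
}
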