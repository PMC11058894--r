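#' Voxelwise speed of a velocity field
#'
#' Euclidean norm of the three velocity components, per voxel and frame.
#'
#' @param field A [velocity_field()].
#' @return A 4D array of speeds, cm/s.
#' @export
speed_volume <- function(field) {
  sqrt(field$vx^2 + field$vy^2 + field$vz^2)
}

#' Median-filter a speed volume with a 3x3x3 kernel
#'
#' Per frame, a 3x3x3 spatial median with replicated edges is applied over
#' the full volume (before any masking), suppressing isolated noisy voxels
#' without eroding the mask boundary.
#'
#' @param speed A 4D speed array.
#' @return The filtered 4D array.
#' @export
median_filter_speed <- function(speed) {
  d <- dim(speed)
  if (length(d) != 4) abort("speed must be a 4D array")
  out <- speed
  for (k in seq_len(d[4])) {
    out[, , , k] <- array(
      median_filter_box(as.vector(speed[, , , k]), d[1:3], 1L, 1L, 1L),
      d[1:3])
  }
  out
}

#' Maximum LV speed curve
#'
#' Per frame, the maximum (filtered) speed at any site within the LV mask.
#'
#' @param speed A 4D speed array (typically [median_filter_speed()] output).
#' @param masks Logical 4D array of per-frame LV masks matching `speed`, or a
#'   logical 3D array reused for every frame.
#' @param frame_times Frame times in ms.
#' @return An [inflow_curve()] of kind `lv_max_speed` (cm/s).
#' @export
lv_max_speed_curve <- function(speed, masks, frame_times) {
  d <- dim(speed)
  if (length(dim(masks)) == 3) {
    if (!identical(dim(masks), d[1:3])) abort("mask shape does not match speed")
    masks <- array(masks, dim = d)
  }
  if (!identical(dim(masks), d)) abort("mask shape does not match speed")
  vals <- vapply(seq_len(d[4]), function(k) {
    m <- masks[, , , k]
    if (!any(m)) abort(sprintf("LV mask is empty at frame %d", k))
    max(speed[, , , k][m])
  }, numeric(1))
  inflow_curve(frame_times, vals, kind = "lv_max_speed")
}

#' LVvel: E/A from the maximum speed inside the LV
#'
#' The automated method: voxel speeds are 3x3x3 median-filtered, the maximum
#' within the LV mask is taken per frame, and the E and A peaks are detected
#' inside the diastolic window. Early and late diastole are not split a
#' priori: the two-peak selection inside one diastolic window identifies E
#' and A, matching the mitral-plane methods for comparability.
#'
#' @param field A [velocity_field()].
#' @param masks Logical 4D (or 3D) LV mask array.
#' @param diastole_window Passed to [detect_ea_peaks()].
#' @param filter_order `"filter_then_mask"` (default) filters the full
#'   volume before masking; `"mask_then_filter"` zeroes non-LV voxels first.
#' @param ... Further arguments to [detect_ea_peaks()].
#' @return A `peak_pair` with the LV speed curve attached as attribute
#'   `curve`.
#' @export
lvvel_ea <- function(field, masks, diastole_window = "auto",
                     filter_order = c("filter_then_mask", "mask_then_filter"),
                     ...) {
  filter_order <- match.arg(filter_order)
  speed <- speed_volume(field)
  if (filter_order == "mask_then_filter") {
    m4 <- if (length(dim(masks)) == 3) array(masks, dim = dim(speed)) else masks
    speed[!m4] <- 0
  }
  speed <- median_filter_speed(speed)
  curve <- lv_max_speed_curve(speed, masks, field$frame_times)
  pk <- detect_ea_peaks(curve, diastole_window, ...)
  attr(pk, "curve") <- curve
  pk
}
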