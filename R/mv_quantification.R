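#' Reformat velocities onto a tracked plane
#'
#' For each frame, a square grid of points spanning the tracked mitral plane
#' is sampled from the velocity field by trilinear interpolation of the three
#' components, and the interpolated vector is projected onto the frame's
#' plane normal. The sign convention is positive toward the apex, so
#' diastolic inflow is positive. Grid points falling outside the field are
#' set to 0 and flagged, and are excluded from inflow masks downstream.
#'
#' @param field A [velocity_field()].
#' @param plane A `tracked_plane` with one pose per field frame.
#' @param grid_spacing In-plane sample spacing, mm.
#' @param grid_extent Total in-plane extent of the square grid, mm.
#' @return A `plane_velocity_map`: through-plane velocity array
#'   `[n_u, n_v, T]` in cm/s, grid metadata, an `inside` flag array, the
#'   plane, and (initially `NULL`) inflow masks.
#' @export
reformat_velocity <- function(field, plane, grid_spacing = 1, grid_extent = 50) {
  nt <- n_frames(field)
  if (nrow(plane$origins) != nt)
    abort("plane frame count does not match the velocity field")
  if (grid_spacing <= 0 || grid_extent <= 0)
    abort("grid_spacing and grid_extent must be positive")
  g <- seq(-grid_extent / 2, grid_extent / 2, by = grid_spacing)
  nu <- length(g)
  uv <- cbind(rep(g, times = nu), rep(g, each = nu))  # [n_pts, 2]
  values <- array(0, dim = c(nu, nu, nt))
  inside <- array(FALSE, dim = c(nu, nu, nt))
  for (k in seq_len(nt)) {
    pts <- matrix(plane$origins[k, ], nrow(uv), 3, byrow = TRUE) +
      uv[, 1] %o% plane$basis_u[k, ] + uv[, 2] %o% plane$basis_v[k, ]
    ijk <- world_to_voxel(pts, field$affine)
    sx <- trilinear_sample(field$vx[, , , k], ijk)
    sy <- trilinear_sample(field$vy[, , , k], ijk)
    sz <- trilinear_sample(field$vz[, , , k], ijk)
    v <- sx * plane$normals[k, 1] + sy * plane$normals[k, 2] +
      sz * plane$normals[k, 3]
    ok <- !is.na(v)
    vals <- numeric(nrow(uv))
    vals[ok] <- v[ok]
    values[, , k] <- matrix(vals, nu, nu)
    inside[, , k] <- matrix(ok, nu, nu)
  }
  structure(list(values = values, inside = inside, masks = NULL,
                 grid_spacing = grid_spacing, grid_extent = grid_extent,
                 grid_coords = g, plane = plane,
                 frame_times = field$frame_times),
            class = "plane_velocity_map")
}

#' @export
print.plane_velocity_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<plane_velocity_map> %d x %d samples (%g mm), %d frames%s\n",
              d[1], d[2], x$grid_spacing, d[3],
              if (is.null(x$masks)) "" else ", segmented"))
  invisible(x)
}

#' Correct a plane velocity map for the plane's own motion
#'
#' Subtracts the plane's normal velocity from every in-grid sample of each
#' frame, yielding through-plane velocity relative to the moving annulus.
#'
#' @param map A `plane_velocity_map`.
#' @param plane_vel Per-frame plane velocity in cm/s; defaults to the
#'   `plane_velocity` stored in the map's plane (see [plane_velocity()]).
#' @return The corrected `plane_velocity_map`.
#' @export
correct_for_plane_motion <- function(map, plane_vel = NULL) {
  if (is.null(plane_vel)) plane_vel <- map$plane$plane_velocity
  if (is.null(plane_vel))
    abort("no plane velocity available; run plane_velocity() first")
  nt <- dim(map$values)[3]
  if (length(plane_vel) != nt)
    abort("plane velocity length does not match the number of frames")
  for (k in seq_len(nt)) {
    frame <- map$values[, , k]
    frame[map$inside[, , k]] <- frame[map$inside[, , k]] - plane_vel[k]
    map$values[, , k] <- frame
  }
  map
}

#' Median-filter a plane velocity map
#'
#' Per-frame 3x3 spatial median with replicated edges; masks, if already
#' computed, are left untouched.
#'
#' @param map A `plane_velocity_map`.
#' @return The filtered map.
#' @export
median_filter_map <- function(map) {
  d <- dim(map$values)
  for (k in seq_len(d[3])) {
    map$values[, , k] <- matrix(
      median_filter_box(as.vector(map$values[, , k]),
                        c(d[1], d[2], 1L), 1L, 1L, 0L),
      d[1], d[2])
  }
  map
}

#' Segment the mitral inflow area on each frame
#'
#' Per frame: positive through-plane velocities are thresholded at
#' `max(min_velocity, frac_of_max * frame maximum)`; of the resulting
#' connected components the one containing (or nearest to) the grid centre is
#' kept; holes are filled. Frames with no forward flow get an empty mask.
#'
#' @param map A `plane_velocity_map`.
#' @param min_velocity Absolute velocity floor, cm/s.
#' @param frac_of_max Relative threshold as a fraction of each frame's
#'   maximum positive value.
#' @return The map with `masks` (logical array) filled.
#' @export
segment_inflow_area <- function(map, min_velocity = 5, frac_of_max = 0.15) {
  d <- dim(map$values)
  masks <- array(FALSE, dim = d)
  ctr <- (d[1:2] + 1) / 2
  for (k in seq_len(d[3])) {
    frame <- map$values[, , k]
    frame[!map$inside[, , k]] <- 0
    mx <- max(frame)
    if (mx <= 0) next
    thr <- max(min_velocity, frac_of_max * mx)
    bw <- frame >= thr
    if (!any(bw)) next
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    labm <- EBImage::imageData(lab)
    ctr_lab <- labm[round(ctr[1]), round(ctr[2])]
    if (ctr_lab == 0) {
      on <- which(labm > 0, arr.ind = TRUE)
      dist2 <- (on[, 1] - ctr[1])^2 + (on[, 2] - ctr[2])^2
      ctr_lab <- labm[on[which.min(dist2), , drop = FALSE]]
    }
    comp <- labm == ctr_lab
    filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
    masks[, , k] <- filled & map$inside[, , k]
  }
  map$masks <- masks
  map
}

#' Maximum inflow velocity curve (MVvel)
#'
#' Per frame, the maximum through-plane velocity within the segmented inflow
#' area; 0 on frames with an empty mask.
#'
#' @param map A segmented `plane_velocity_map`.
#' @return An [inflow_curve()] of kind `max_velocity` (cm/s).
#' @export
max_velocity_curve <- function(map) {
  if (is.null(map$masks)) abort("map has no inflow masks; run segment_inflow_area()")
  nt <- dim(map$values)[3]
  vals <- vapply(seq_len(nt), function(k) {
    m <- map$masks[, , k]
    if (!any(m)) 0 else max(map$values[, , k][m])
  }, numeric(1))
  inflow_curve(map$frame_times, vals, kind = "max_velocity")
}

#' Volumetric inflow rate curve (MVflow)
#'
#' Per frame, the through-plane velocity integrated over the segmented
#' inflow area (sum times pixel area), in mL/s. Negative values are allowed
#' (systolic/regurgitant frames).
#'
#' @param map A segmented `plane_velocity_map`.
#' @return An [inflow_curve()] of kind `flow_rate` (mL/s).
#' @export
flow_rate_curve <- function(map) {
  if (is.null(map$masks)) abort("map has no inflow masks; run segment_inflow_area()")
  px_area_cm2 <- (map$grid_spacing / 10)^2
  nt <- dim(map$values)[3]
  vals <- vapply(seq_len(nt), function(k) {
    m <- map$masks[, , k]
    if (!any(m)) 0 else sum(map$values[, , k][m]) * px_area_cm2
  }, numeric(1))
  inflow_curve(map$frame_times, vals, kind = "flow_rate")
}

#' Full mitral-plane processing chain
#'
#' Reformat onto the tracked plane, correct for plane motion, 3x3
#' median-filter, and segment the inflow area — the shared front end of the
#' MVvel and MVflow measurements.
#'
#' @inheritParams reformat_velocity
#' @inheritParams segment_inflow_area
#' @param motion_correct Subtract the plane's own normal velocity.
#' @return A segmented, filtered `plane_velocity_map`.
#' @export
mv_velocity_map <- function(field, plane, grid_spacing = 1, grid_extent = 50,
                            motion_correct = TRUE,
                            min_velocity = 5, frac_of_max = 0.15) {
  map <- reformat_velocity(field, plane, grid_spacing, grid_extent)
  if (motion_correct) map <- correct_for_plane_motion(map)
  map <- median_filter_map(map)
  segment_inflow_area(map, min_velocity, frac_of_max)
}

#' MVvel: E/A from the mitral-plane maximum velocity curve
#'
#' @inheritParams mv_velocity_map
#' @param diastole_window Passed to [detect_ea_peaks()].
#' @param ... Further arguments to [detect_ea_peaks()].
#' @return A `peak_pair` (see [detect_ea_peaks()]) with the curve attached as
#'   attribute `curve`.
#' @export
mvvel_ea <- function(field, plane, diastole_window = "auto",
                     grid_spacing = 1, grid_extent = 50, ...) {
  map <- mv_velocity_map(field, plane, grid_spacing, grid_extent)
  curve <- max_velocity_curve(map)
  pk <- detect_ea_peaks(curve, diastole_window, ...)
  attr(pk, "curve") <- curve
  pk
}

#' MVflow: E/A from the mitral-plane volumetric flow curve
#'
#' @inheritParams mvvel_ea
#' @return A `peak_pair` with the flow curve attached as attribute `curve`.
#' @export
mvflow_ea <- function(field, plane, diastole_window = "auto",
                      grid_spacing = 1, grid_extent = 50, ...) {
  map <- mv_velocity_map(field, plane, grid_spacing, grid_extent)
  curve <- flow_rate_curve(map)
  pk <- detect_ea_peaks(curve, diastole_window, ...)
  attr(pk, "curve") <- curve
  pk
}
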