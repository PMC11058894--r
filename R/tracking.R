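#' @name valve_tracking
#' @title Mitral annulus tracking from a long-axis cine series
#'
#' @description
#' The mitral annulus plane is followed over the cardiac cycle from a single
#' end-diastolic initialisation of two annulus landmarks on a long-axis
#' ("3-chamber") cine. Each landmark is tracked frame-to-frame by normalized
#' cross-correlation (NCC) template matching, once forward and once backward
#' around the (cyclic) cardiac cycle, and the two passes are fused by a
#' weighted average whose weights decrease linearly with the number of steps
#' from the starting frame. The tracked chord defines a plane per frame, and
#' the plane's own velocity along its normal is available for downstream
#' motion correction of through-plane velocities.
NULL

world_to_cine_px <- function(points, cine) {
  rel <- sweep(points, 2, cine$origin)
  cbind(rel %*% cine$u, rel %*% cine$v) / cine$spacing + 1
}

cine_px_to_world <- function(px, cine) {
  n <- nrow(px)
  matrix(cine$origin, n, 3, byrow = TRUE) +
    (px[, 1] - 1) * cine$spacing * matrix(cine$u, n, 3, byrow = TRUE) +
    (px[, 2] - 1) * cine$spacing * matrix(cine$v, n, 3, byrow = TRUE)
}

# patch with replicated edges, centred on integer pixel (cx, cy)
extract_patch <- function(img, cx, cy, half) {
  d <- dim(img)
  rows <- pmin(pmax(cx + (-half:half), 1L), d[1])
  cols <- pmin(pmax(cy + (-half:half), 1L), d[2])
  img[rows, cols, drop = FALSE]
}

ncc_score <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-1)
  stats::cor(as.vector(a), as.vector(b))
}

# quadratic subpixel refinement along one axis of an NCC surface
subpixel_offset <- function(cm1, c0, cp1) {
  den <- cm1 - 2 * c0 + cp1
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (cm1 - cp1) / den))
}

# one cyclic NCC tracking pass; frames visited in `order` (1-based indices),
# order[1] carries the initial position
ncc_pass <- function(images, order, init_px, template_half, search, ncc_floor) {
  nt <- dim(images)[3]
  pos <- matrix(NA_real_, nt, 2)
  pos[order[1], ] <- init_px
  n_fail <- 0L
  cur_pos <- init_px
  for (s in seq_len(length(order) - 1)) {
    f_prev <- order[s]; f_cur <- order[s + 1]
    ci <- round(cur_pos)
    tmpl <- extract_patch(images[, , f_prev], ci[1], ci[2], template_half)
    scores <- matrix(-1, 2 * search + 1, 2 * search + 1)
    for (dx in -search:search) {
      for (dy in -search:search) {
        win <- extract_patch(images[, , f_cur], ci[1] + dx, ci[2] + dy,
                             template_half)
        scores[dx + search + 1, dy + search + 1] <- ncc_score(tmpl, win)
      }
    }
    best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
    if (scores[best[1], best[2]] < ncc_floor) {
      n_fail <- n_fail + 1L
      pos[f_cur, ] <- cur_pos
      next
    }
    dx <- best[1] - search - 1; dy <- best[2] - search - 1
    sub <- c(0, 0)
    if (best[1] > 1 && best[1] < nrow(scores))
      sub[1] <- subpixel_offset(scores[best[1] - 1, best[2]],
                                scores[best[1], best[2]],
                                scores[best[1] + 1, best[2]])
    if (best[2] > 1 && best[2] < ncol(scores))
      sub[2] <- subpixel_offset(scores[best[1], best[2] - 1],
                                scores[best[1], best[2]],
                                scores[best[1], best[2] + 1])
    # the NCC displacement measures the feature's motion relative to its
    # (possibly off-centre) position inside the template, so it is added to
    # the continuous previous position, not to the rounded patch centre
    cur_pos <- cur_pos + c(dx + sub[1], dy + sub[2])
    pos[f_cur, ] <- cur_pos
  }
  list(pos = pos, n_fail = n_fail)
}

#' Track annulus landmarks through a cine series
#'
#' Bidirectional cyclic NCC template tracking of two landmarks from a single
#' initialisation frame. The forward and backward passes are combined with
#' linearly decreasing weights: at a frame reached after `t` forward steps of
#' `T` total, the fused position is `(T - t)/T * forward + t/T * backward`,
#' so both passes agree exactly with the initialisation at the start frame.
#'
#' @param cine A `cine_series` (see [generate_phantom()]).
#' @param init_landmarks 2 x 3 matrix of world-mm landmark positions at the
#'   initialisation frame.
#' @param init_frame Initialisation frame index, 0-based (as stored in the
#'   landmark seed JSON).
#' @param template_half Half-size of the square NCC template in pixels
#'   (default 10, i.e. 21 x 21).
#' @param search Search radius in pixels around the previous position.
#' @param ncc_floor Minimum acceptable NCC peak; below it the previous
#'   position is carried over, and if that happens on more than 25% of frames
#'   the tracking errors out.
#' @return A `landmark_tracks` object: array `[T, 2, 3]` of world-mm
#'   positions with the cine frame times attached.
#' @export
track_landmarks <- function(cine, init_landmarks, init_frame = 0L,
                            template_half = 10L, search = 10L,
                            ncc_floor = 0.3) {
  d <- dim(cine$images)
  nt <- d[3]
  fi <- as.integer(init_frame) + 1L
  if (fi < 1L || fi > nt) abort("init_frame out of range")
  init_px <- world_to_cine_px(init_landmarks, cine)
  if (any(init_px < 1) || any(init_px[, 1] > d[1]) || any(init_px[, 2] > d[2]))
    abort("initial landmarks fall outside the cine image")

  fwd_order <- ((fi - 1 + 0:(nt - 1)) %% nt) + 1L
  bwd_order <- ((fi - 1 - 0:(nt - 1)) %% nt) + 1L
  steps_fwd <- (0:(nt - 1))[match(seq_len(nt), fwd_order)]
  w_f <- (nt - steps_fwd) / nt

  tracks <- array(NA_real_, dim = c(nt, 2, 3))
  for (l in 1:2) {
    f <- ncc_pass(cine$images, fwd_order, init_px[l, ], template_half,
                  search, ncc_floor)
    b <- ncc_pass(cine$images, bwd_order, init_px[l, ], template_half,
                  search, ncc_floor)
    if (f$n_fail > 0.25 * nt || b$n_fail > 0.25 * nt)
      abort("tracking failure: NCC peak below floor on more than 25% of frames")
    fused_px <- f$pos * w_f + b$pos * (1 - w_f)
    tracks[, l, ] <- cine_px_to_world(fused_px, cine)
  }
  structure(tracks, frame_times = cine$frame_times, class = "landmark_tracks")
}

#' Build a tracked mitral plane from landmark tracks
#'
#' Per frame, the plane origin is the midpoint of the landmark chord; the
#' plane contains the chord and the cine through-plane direction; its normal
#' is the unit vector in the cine image plane perpendicular to the chord,
#' with the sign chosen to point toward the apex.
#'
#' @param tracks A `landmark_tracks` array from [track_landmarks()].
#' @param cine The `cine_series` the tracks came from.
#' @param apex_hint World-mm point on the apical side of the annulus (must
#'   not lie on the landmark chord).
#' @return A `tracked_plane`: per-frame origins, unit normals, orthonormal
#'   in-plane basis, the landmark tracks, frame times, and (once
#'   [plane_velocity()] has been called) the plane's normal velocity.
#' @export
landmarks_to_plane <- function(tracks, cine, apex_hint) {
  nt <- dim(tracks)[1]
  origins <- normals <- bu <- bv <- matrix(NA_real_, nt, 3)
  for (k in seq_len(nt)) {
    p1 <- tracks[k, 1, ]; p2 <- tracks[k, 2, ]
    chord <- p2 - p1
    len <- sqrt(sum(chord^2))
    if (len < 1e-9) abort("coincident landmarks: chord has zero length")
    u <- chord / len
    origins[k, ] <- (p1 + p2) / 2
    n <- cross3(u, cine$through)
    n <- n / sqrt(sum(n^2))
    if (sum(n * (apex_hint - origins[k, ])) < 0) n <- -n
    if (abs(sum(n * (apex_hint - origins[k, ]))) < 1e-9)
      abort("apex_hint lies on the landmark chord")
    normals[k, ] <- n
    bu[k, ] <- u
    v <- cross3(n, u)
    bv[k, ] <- v / sqrt(sum(v^2))
  }
  ang <- angles_between(normals[-nt, , drop = FALSE], normals[-1, , drop = FALSE])
  if (any(ang > 30))
    warn("tracked plane normals change by more than 30 degrees between frames")
  structure(list(origins = origins, normals = normals,
                 basis_u = bu, basis_v = bv,
                 landmark_tracks = tracks,
                 frame_times = attr(tracks, "frame_times"),
                 plane_velocity = NULL),
            class = "tracked_plane")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

angles_between <- function(a, b) {
  d <- pmin(1, pmax(-1, rowSums(a * b)))
  acos(d) * 180 / pi
}

#' Plane velocity along its normal
#'
#' Signed speed of the plane origin along the per-frame normal, by central
#' differences with a cyclic boundary (the cardiac cycle wraps), in cm/s.
#'
#' @param tracked A `tracked_plane`.
#' @param frame_times Frame times in ms; defaults to the times stored in the
#'   tracked plane.
#' @return The `tracked_plane` with `plane_velocity` (cm/s per frame) filled.
#' @export
plane_velocity <- function(tracked, frame_times = NULL) {
  if (is.null(frame_times)) frame_times <- tracked$frame_times
  nt <- nrow(tracked$origins)
  if (nt < 3) abort("at least 3 frames are required")
  if (any(diff(frame_times) <= 0)) abort("frame_times must be strictly increasing")
  period <- infer_period(frame_times)
  vel <- numeric(nt)
  for (k in seq_len(nt)) {
    kp <- if (k == nt) 1L else k + 1L
    km <- if (k == 1L) nt else k - 1L
    dt <- frame_times[kp] - frame_times[km]
    if (kp < k) dt <- dt + period
    if (km > k) dt <- dt + period
    disp <- tracked$origins[kp, ] - tracked$origins[km, ]
    vel[k] <- 100 * sum(disp * tracked$normals[k, ]) / dt  # mm/ms -> cm/s
  }
  tracked$plane_velocity <- vel
  tracked
}

#' @export
print.tracked_plane <- function(x, ...) {
  cat(sprintf("<tracked_plane> %d frames; origin z %.1f..%.1f mm\n",
              nrow(x$origins), min(x$origins[, 3]), max(x$origins[, 3])))
  invisible(x)
}

#' Write a tracked plane to JSON
#' @param tracked A `tracked_plane`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_tracked_plane <- function(tracked, path) {
  jsonlite::write_json(
    list(origins = tracked$origins, normals = tracked$normals,
         basis_u = tracked$basis_u, basis_v = tracked$basis_v,
         frame_times = tracked$frame_times,
         plane_velocity = tracked$plane_velocity),
    path, digits = NA, null = "null")
  invisible(path)
}

#' Read a tracked plane from JSON
#' @param path JSON file written by [write_tracked_plane()].
#' @return A `tracked_plane`.
#' @export
read_tracked_plane <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(origins = as.matrix(x$origins),
                 normals = as.matrix(x$normals),
                 basis_u = as.matrix(x$basis_u),
                 basis_v = as.matrix(x$basis_v),
                 landmark_tracks = NULL,
                 frame_times = as.numeric(x$frame_times),
                 plane_velocity = if (is.null(x$plane_velocity)) NULL
                                  else as.numeric(x$plane_velocity)),
            class = "tracked_plane")
}

#' Tracked plane for a phantom's true annulus trajectory
#'
#' Convenience constructor building the ground-truth `tracked_plane` directly
#' from a phantom's analytic annulus trajectory (bypassing cine tracking),
#' useful for isolating quantification errors from tracking errors.
#'
#' @param phantom A [generate_phantom()] result.
#' @return A `tracked_plane` with `plane_velocity` filled.
#' @export
true_annulus_plane <- function(phantom) {
  tr <- phantom$truth$annulus_trajectory
  nt <- nrow(tr$midpoint)
  tracks <- array(NA_real_, dim = c(nt, 2, 3))
  tracks[, 1, ] <- tr$landmark_1
  tracks[, 2, ] <- tr$landmark_2
  attr(tracks, "frame_times") <- phantom$field$frame_times
  class(tracks) <- "landmark_tracks"
  apex <- c(grid_center_xy(phantom$params), apex_z(phantom$params))
  plane_velocity(landmarks_to_plane(tracks, phantom$cine, apex))
}
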