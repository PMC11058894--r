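#' Correct velocity aliasing by temporal phase unwrapping
#'
#' Phase-contrast velocities beyond the encoding limit wrap into
#' `[-venc, venc)`. This routine unwraps each voxel's velocity time course
#' component-wise: frame 0 is assumed alias-free, and every subsequent frame
#' is shifted by the integer multiple of `2 * venc` that brings it closest to
#' the (already corrected) previous frame. Output values may legitimately
#' exceed the VENC. The transform is idempotent on fields that are already
#' temporally smooth relative to the VENC.
#'
#' Known failure mode: if frame 0 itself is aliased, the whole time course is
#' shifted consistently wrong; anchor the cycle so that frame 0 falls in a
#' low-velocity phase (end-diastole).
#'
#' @param field A [velocity_field()].
#' @param verbose Emit a message with the number of corrected voxel samples.
#' @return A [velocity_field()] with unwrapped velocities.
#' @export
unwrap_velocity <- function(field, verbose = TRUE) {
  venc <- field$venc
  nt <- n_frames(field)
  n_corrected <- 0L
  comps <- c("vx", "vy", "vz")
  out <- field
  for (comp in comps) {
    arr <- field[[comp]]
    prev <- arr[, , , 1]
    for (t in 2:nt) {
      cur <- arr[, , , t]
      k <- round((prev - cur) / (2 * venc))
      n_corrected <- n_corrected + sum(k != 0)
      cur <- cur + 2 * venc * k
      arr[, , , t] <- cur
      prev <- cur
    }
    out[[comp]] <- arr
  }
  if (verbose)
    message(sprintf("unwrap_velocity: corrected %d voxel samples", n_corrected))
  out
}

#' Fit and remove background phase offsets
#'
#' Background phase errors appear as a slowly varying spatial offset added to
#' every velocity frame. For each component, a spatial polynomial (order 0-2
#' in world mm coordinates) is fitted by least squares to the time-averaged
#' velocity over static-tissue voxels and subtracted from every frame.
#'
#' @param field A [velocity_field()].
#' @param static_mask Logical 3D array marking static voxels, or `"auto"`:
#'   voxels whose temporal-mean speed and temporal speed SD both fall below
#'   `static_thresholds` are taken as static.
#' @param order Polynomial order, 0, 1 (default) or 2.
#' @param static_thresholds Length-2 numeric, cm/s: upper bounds on
#'   temporal-mean speed and temporal speed SD for the `"auto"` mask.
#' @return A list with `field` (corrected [velocity_field()]) and `model`
#'   (class `background_model`: the order, per-component coefficients, and the
#'   static mask used).
#' @export
correct_background_phase <- function(field, static_mask = "auto", order = 1,
                                     static_thresholds = c(2, 2)) {
  if (!order %in% 0:2) abort("polynomial order must be 0, 1 or 2")
  d <- dim(field$vx)
  if (identical(static_mask, "auto")) {
    spd <- speed_volume(field)
    sm <- apply(spd, 1:3, mean)
    ssd <- sqrt(pmax(0, apply(spd^2, 1:3, mean) - sm^2) *
                  d[4] / max(1, d[4] - 1))
    static_mask <- sm < static_thresholds[1] & ssd < static_thresholds[2]
  }
  if (!is.array(static_mask) || !identical(dim(static_mask), d[1:3]))
    abort("static_mask must be a logical array matching the field grid")
  idx <- which(static_mask)
  if (length(idx) == 0) abort("static mask is empty")

  ijk <- arrayInd(idx, d[1:3])
  world <- voxel_to_world(ijk, field$affine)
  X_static <- poly_design(world, order)
  if (length(idx) < ncol(X_static))
    abort("fewer static voxels than polynomial coefficients")

  all_ijk <- arrayInd(seq_len(prod(d[1:3])), d[1:3])
  X_all <- poly_design(voxel_to_world(all_ijk, field$affine), order)

  out <- field
  coefs <- list()
  for (comp in c("vx", "vy", "vz")) {
    tmean <- apply(field[[comp]], 1:3, mean)
    beta <- stats::lm.fit(X_static, tmean[idx])$coefficients
    beta[is.na(beta)] <- 0
    coefs[[comp]] <- beta
    bg <- array(X_all %*% beta, dim = d[1:3])
    arr <- field[[comp]]
    for (t in seq_len(d[4])) arr[, , , t] <- arr[, , , t] - bg
    out[[comp]] <- arr
  }
  model <- structure(list(order = order, coefficients = coefs,
                          static_mask = static_mask),
                     class = "background_model")
  list(field = out, model = model)
}

poly_design <- function(world, order) {
  x <- world[, 1]; y <- world[, 2]; z <- world[, 3]
  X <- cbind(intercept = rep(1, nrow(world)))
  if (order >= 1) X <- cbind(X, x = x, y = y, z = z)
  if (order >= 2)
    X <- cbind(X, x2 = x^2, y2 = y^2, z2 = z^2,
               xy = x * y, xz = x * z, yz = y * z)
  X
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> order %d, %d static voxels\n",
              x$order, sum(x$static_mask)))
  invisible(x)
}
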