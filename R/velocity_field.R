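#' Time-resolved three-component velocity field
#'
#' Container for 4D Flow velocity data: one 4D array (x, y, z, time) per
#' velocity component, the components being along the world x/y/z axes, in
#' cm/s. Geometry is carried by a 4x4 voxel-to-world affine (mm, 0-based voxel
#' indices), timing by a vector of frame times (ms), and the velocity-encoding
#' limit by `venc` (cm/s).
#'
#' @param vx,vy,vz Numeric 4D arrays of identical dimension `[X, Y, Z, T]`,
#'   velocity along world x, y, z in cm/s.
#' @param affine 4x4 voxel-to-world transform; world mm coordinates of the
#'   centre of voxel `(i, j, k)` (1-based) are `affine %*% c(i-1, j-1, k-1, 1)`.
#' @param frame_times Strictly increasing frame times in ms, length `T`.
#' @param venc Velocity-encoding limit in cm/s (positive).
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, vz, affine, frame_times, venc) {
  dims <- dim(vx)
  if (length(dims) != 4L)
    abort("velocity components must be 4D arrays [X, Y, Z, T]")
  if (!identical(dim(vy), dims) || !identical(dim(vz), dims))
    abort("all three velocity components must share the same dimensions")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    abort("affine must be a 4x4 matrix")
  if (length(frame_times) != dims[4L])
    abort("frame_times length must equal the number of timeframes")
  if (any(diff(frame_times) <= 0))
    abort("frame_times must be strictly increasing")
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    abort("venc must be a single positive number")
  if (anyNA(vx) || anyNA(vy) || anyNA(vz) ||
      !all(is.finite(range(vx))) || !all(is.finite(range(vy))) ||
      !all(is.finite(range(vz))))
    abort("velocity data must be finite")
  structure(
    list(vx = vx, vy = vy, vz = vz, affine = affine,
         frame_times = as.numeric(frame_times), venc = venc),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  vs <- voxel_size(x)
  cat(sprintf(
    "<velocity_field> %d x %d x %d voxels, %d frames\n  voxel size %.2f x %.2f x %.2f mm, VENC %g cm/s\n  frames %.1f..%.1f ms\n",
    d[1], d[2], d[3], d[4], vs[1], vs[2], vs[3], x$venc,
    x$frame_times[1], x$frame_times[length(x$frame_times)]))
  invisible(x)
}

#' @export
dim.velocity_field <- function(x) dim(x$vx)

n_frames <- function(field) dim(field$vx)[4L]

voxel_size <- function(field) {
  sqrt(colSums(field$affine[1:3, 1:3]^2))
}

#' Cardiac cycle length implied by the frame grid
#'
#' Frames are assumed uniformly spread over one cardiac cycle, so the cycle
#' length is `n * mean(diff(frame_times))`.
#' @param frame_times Frame times in ms.
#' @return Cycle length in ms.
#' @keywords internal
infer_period <- function(frame_times) {
  length(frame_times) * mean(diff(frame_times))
}

# world mm -> continuous 1-based voxel coordinates
world_to_voxel <- function(points, affine) {
  pts <- cbind(points, 1)
  vox <- pts %*% t(solve(affine))
  vox[, 1:3, drop = FALSE] + 1
}

voxel_to_world <- function(ijk, affine) {
  pts <- cbind(ijk - 1, 1)
  (pts %*% t(affine))[, 1:3, drop = FALSE]
}

# Vectorized trilinear interpolation of one 3D volume at continuous 1-based
# voxel coordinates (n x 3). Points outside the grid return NA.
trilinear_sample <- function(vol, ijk) {
  d <- dim(vol)
  n <- nrow(ijk)
  out <- rep(NA_real_, n)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), d[1] - 1L); fx <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), d[2] - 1L); fy <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), d[3] - 1L); fz <- p[, 3] - k0
  # degenerate single-slab axes: clamp the low corner and zero the fraction
  if (d[1] == 1L) { i0[] <- 1; fx[] <- 0 }
  if (d[2] == 1L) { j0[] <- 1; fy[] <- 0 }
  if (d[3] == 1L) { k0[] <- 1; fz[] <- 0 }
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  v000 <- vol[cbind(i0, j0, k0)]; v100 <- vol[cbind(i1, j0, k0)]
  v010 <- vol[cbind(i0, j1, k0)]; v110 <- vol[cbind(i1, j1, k0)]
  v001 <- vol[cbind(i0, j0, k1)]; v101 <- vol[cbind(i1, j0, k1)]
  v011 <- vol[cbind(i0, j1, k1)]; v111 <- vol[cbind(i1, j1, k1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Write a velocity field as three NIfTI component files
#'
#' Components are written as `<prefix>_vx.nii.gz`, `<prefix>_vy.nii.gz`,
#' `<prefix>_vz.nii.gz` (X x Y x Z x T, float32, cm/s) plus a small JSON
#' sidecar `<prefix>_meta.json` holding frame times and VENC.
#'
#' @param field A [velocity_field()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_velocity_field <- function(field, prefix) {
  for (comp in c("vx", "vy", "vz")) {
    img <- RNifti::asNifti(field[[comp]], datatype = "float")
    # the sform encodes the voxel-to-world geometry (and hence voxel size)
    img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
    RNifti::writeNifti(img, paste0(prefix, "_", comp, ".nii.gz"))
  }
  jsonlite::write_json(
    list(frame_times_ms = field$frame_times, venc_cms = field$venc),
    paste0(prefix, "_meta.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a velocity field written by [write_velocity_field()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [velocity_field()].
#' @export
read_velocity_field <- function(prefix) {
  comps <- lapply(c("vx", "vy", "vz"), function(comp) {
    RNifti::readNifti(paste0(prefix, "_", comp, ".nii.gz"))
  })
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  aff <- unclass(RNifti::xform(comps[[1]]))
  velocity_field(array(as.numeric(comps[[1]]), dim = dim(comps[[1]])),
                 array(as.numeric(comps[[2]]), dim = dim(comps[[2]])),
                 array(as.numeric(comps[[3]]), dim = dim(comps[[3]])),
                 affine = aff,
                 frame_times = meta$frame_times_ms,
                 venc = meta$venc_cms)
}

#' Write a binary mask series as NIfTI
#' @param masks Logical/integer 4D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output file (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask_series <- function(masks, affine, path) {
  img <- RNifti::asNifti(array(as.integer(masks), dim = dim(masks)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask series from NIfTI
#' @param path NIfTI file.
#' @return Logical 4D array.
#' @export
read_mask_series <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img))
}
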