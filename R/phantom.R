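#' Parameters of the synthetic 4D transmitral inflow phantom
#'
#' Builds and validates the parameter set of the synthetic 4D Flow phantom.
#' The defaults emulate a typical clinical whole-heart 4D Flow acquisition
#' (VENC 120 cm/s, 2.8 mm isotropic voxels, 30 reconstructed timeframes over
#' one cardiac cycle) and a normal biphasic transmitral inflow with peak E
#' 60 cm/s and peak A 50 cm/s (E/A = 1.2).
#'
#' The phantom places a transmitral jet along the world z axis (the LV long
#' axis; apex toward +z). The jet's through-plane velocity is separable:
#' a temporal envelope that is the sum of two raised-cosine pulses (E and A),
#' a Gaussian lateral cross-section of scale `jet_radius` truncated at 3
#' sigma, and an asymmetric axial profile peaking `vena_contracta_offset` mm
#' apical to the moving annulus plane (steep decay on the basal side, slow on
#' the apical side, mimicking a vena contracta just downstream of the
#' orifice). The annulus translates sinusoidally along z with peak-to-peak
#' excursion `annulus_excursion`. A systolic outflow jet (negative z
#' direction, lateral offset from the inflow axis) is placed inside the LV
#' mask so that unwindowed maximum-speed analysis would pick up systole.
#'
#' Default E and A peak times sit exactly on the default 30-frame grid
#' (cycle fractions 16/30 and 27/30) so that the sampled curves attain the
#' analytic peak values: the phantom is a measurement target, not a model of
#' timing jitter.
#'
#' @param grid_shape Integer vector of 3, voxels per axis.
#' @param voxel_size Isotropic voxel size, mm.
#' @param n_frames Number of reconstructed timeframes (>= 8).
#' @param cycle_length Cardiac cycle length, ms.
#' @param venc Velocity-encoding limit, cm/s.
#' @param peak_e_velocity,peak_a_velocity Peak E and A inflow velocity at the
#'   vena contracta, cm/s.
#' @param e_peak_time_frac,a_peak_time_frac Peak times as fractions of the
#'   cycle; must satisfy `0 < e < a < 1`.
#' @param e_width,a_width Raised-cosine half-widths of the E and A pulses, ms.
#' @param jet_radius Gaussian lateral scale (sigma) of the inflow jet, mm.
#' @param jet_axial_basal,jet_axial_apical Axial Gaussian scales of the jet on
#'   the basal (annulus) and apical sides of the vena contracta, mm.
#' @param vena_contracta_offset Distance of the peak-velocity locus apical to
#'   the annulus plane, mm.
#' @param annulus_excursion Peak-to-peak longitudinal annulus excursion, mm.
#' @param annulus_radius Half-distance between the two annulus landmarks, mm.
#' @param systolic_velocity Peak speed of the systolic outflow component,
#'   cm/s (set 0 to disable).
#' @param systolic_peak_frac,systolic_width Timing of the systolic outflow
#'   pulse (cycle fraction, and half-width in ms).
#' @param noise_sd Gaussian noise SD added to each velocity component, cm/s.
#' @param inject_aliasing If `TRUE`, stored velocities are wrapped into
#'   `[-venc, venc)` by modular arithmetic, as phase aliasing does.
#' @param seed Integer seed making the phantom bit-reproducible.
#'
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(41L, 41L, 55L),
                           voxel_size = 2.8,
                           n_frames = 30L,
                           cycle_length = 1000,
                           venc = 120,
                           peak_e_velocity = 60,
                           peak_a_velocity = 50,
                           e_peak_time_frac = 16 / 30,
                           a_peak_time_frac = 27 / 30,
                           e_width = 130,
                           a_width = 100,
                           jet_radius = 15,
                           jet_axial_basal = 10,
                           jet_axial_apical = 20,
                           vena_contracta_offset = 5,
                           annulus_excursion = 8,
                           annulus_radius = 16,
                           systolic_velocity = 80,
                           systolic_peak_frac = 0.18,
                           systolic_width = 120,
                           noise_sd = 0,
                           inject_aliasing = FALSE,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
            n_frames = as.integer(n_frames), cycle_length = cycle_length,
            venc = venc, peak_e_velocity = peak_e_velocity,
            peak_a_velocity = peak_a_velocity,
            e_peak_time_frac = e_peak_time_frac,
            a_peak_time_frac = a_peak_time_frac,
            e_width = e_width, a_width = a_width, jet_radius = jet_radius,
            jet_axial_basal = jet_axial_basal,
            jet_axial_apical = jet_axial_apical,
            vena_contracta_offset = vena_contracta_offset,
            annulus_excursion = annulus_excursion,
            annulus_radius = annulus_radius,
            systolic_velocity = systolic_velocity,
            systolic_peak_frac = systolic_peak_frac,
            systolic_width = systolic_width,
            noise_sd = noise_sd, inject_aliasing = isTRUE(inject_aliasing),
            seed = as.integer(seed))
  validate_phantom_params(p)
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  stopifnot(length(p$grid_shape) == 3L, all(p$grid_shape >= 9L))
  if (p$voxel_size <= 0) abort("voxel_size must be positive")
  if (p$n_frames < 8L) abort("n_frames must be at least 8")
  if (p$venc <= 0) abort("venc must be positive")
  if (p$cycle_length <= 0) abort("cycle_length must be positive")
  if (!(p$e_peak_time_frac > 0 && p$e_peak_time_frac < p$a_peak_time_frac &&
        p$a_peak_time_frac < 1))
    abort("peak time fractions must satisfy 0 < E < A < 1")
  if (p$peak_e_velocity < 0 || p$peak_a_velocity < 0)
    abort("peak velocities must be non-negative")
  if (p$jet_radius <= p$voxel_size)
    abort("jet_radius must exceed voxel_size")
  if (p$e_width <= 0 || p$a_width <= 0)
    abort("pulse widths must be positive")
  if (p$noise_sd < 0) abort("noise_sd must be non-negative")
  # the truncated (3 sigma) jet must fit laterally inside the grid
  half_extent <- (p$grid_shape[1:2] - 1) / 2 * p$voxel_size
  if (any(3 * p$jet_radius > half_extent))
    abort("jet exceeds the grid: 3 * jet_radius is wider than the lateral half-extent")
  invisible(p)
}

# ---- analytic building blocks -----------------------------------------------

raised_cosine <- function(t, center, half_width, amplitude) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= half_width
  out[inside] <- amplitude / 2 * (1 + cos(pi * (t[inside] - center) / half_width))
  out
}

#' Analytic transmitral inflow envelope of the phantom
#'
#' Sum of the E and A raised-cosine pulses: the through-plane velocity at the
#' vena contracta as a function of time.
#'
#' @param params A [phantom_params()].
#' @param t Times in ms (within one cycle).
#' @return Velocities in cm/s.
#' @export
inflow_envelope <- function(params, t) {
  raised_cosine(t, params$e_peak_time_frac * params$cycle_length,
                params$e_width, params$peak_e_velocity) +
    raised_cosine(t, params$a_peak_time_frac * params$cycle_length,
                  params$a_width, params$peak_a_velocity)
}

systolic_envelope <- function(params, t) {
  raised_cosine(t, params$systolic_peak_frac * params$cycle_length,
                params$systolic_width, params$systolic_velocity)
}

# Longitudinal annulus position (mm, along world z) over the cycle:
# sinusoidal apical displacement, at the end-diastolic position at t = 0.
annulus_z_position <- function(params, t) {
  z0 <- annulus_base_z(params)
  z0 + params$annulus_excursion / 2 *
    (1 - cos(2 * pi * t / params$cycle_length))
}

annulus_z_speed <- function(params, t) {
  # derivative of annulus_z_position in mm/ms -> cm/s (x100)
  100 * params$annulus_excursion / 2 * (2 * pi / params$cycle_length) *
    sin(2 * pi * t / params$cycle_length)
}

annulus_base_z <- function(params) {
  params$voxel_size * round(0.28 * (params$grid_shape[3] - 1))
}

apex_z <- function(params) {
  params$voxel_size * (params$grid_shape[3] - 5)
}

grid_center_xy <- function(params) {
  (params$grid_shape[1:2] - 1) / 2 * params$voxel_size
}

# Asymmetric axial jet profile: dz is the signed distance from the vena
# contracta along +z (apical positive). Basal side decays fast.
jet_axial_profile <- function(params, dz) {
  s <- ifelse(dz < 0, params$jet_axial_basal, params$jet_axial_apical)
  exp(-dz^2 / (2 * s^2))
}

# Gaussian lateral profile truncated at 3 sigma, as a matrix over the grid.
jet_lateral_profile <- function(params) {
  ctr <- grid_center_xy(params)
  x <- (seq_len(params$grid_shape[1]) - 1) * params$voxel_size
  y <- (seq_len(params$grid_shape[2]) - 1) * params$voxel_size
  r2 <- outer((x - ctr[1])^2, (y - ctr[2])^2, "+")
  prof <- exp(-r2 / (2 * params$jet_radius^2))
  prof[r2 > (3 * params$jet_radius)^2] <- 0
  prof
}

# Effective lateral area of the truncated Gaussian jet, cm^2.
jet_effective_area_cm2 <- function(params) {
  2 * pi * (params$jet_radius / 10)^2 * (1 - exp(-9 / 2))
}

# Whether the summed E+A envelope is monophasic (single diastolic local
# maximum) on a fine time grid.
envelope_is_fused <- function(params) {
  tt <- seq(0.3 * params$cycle_length, params$cycle_length, by = 1)
  v <- inflow_envelope(params, tt)
  n <- length(v)
  is_max <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]
  sum(is_max) < 2
}

wrap_to_venc <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic 4D Flow phantom with known ground truth
#'
#' Produces a time-resolved three-component velocity field containing a
#' transmitral inflow jet through a moving annulus plane, a long-axis cine
#' series in which the two annulus landmarks are rendered as bright blobs, a
#' per-frame LV mask, landmark seeds for tracking initialisation, and an
#' analytic ground-truth record. See [phantom_params()] for the model.
#'
#' @param params A [phantom_params()].
#' @return A list of class `flow_phantom` with elements `field`
#'   ([velocity_field()]), `cine` (`cine_series`), `lv_mask` (logical 4D
#'   array), `landmarks` (init landmark seed: frame index and two world-mm
#'   points), `truth` (`phantom_truth`), and `params`.
#' @export
generate_phantom <- function(params) {
  validate_phantom_params(params)
  p <- params
  nx <- p$grid_shape[1]; ny <- p$grid_shape[2]; nz <- p$grid_shape[3]
  nt <- p$n_frames
  frame_times <- (seq_len(nt) - 1) / nt * p$cycle_length
  zc <- (seq_len(nz) - 1) * p$voxel_size
  ctr <- grid_center_xy(p)

  lat <- jet_lateral_profile(p)
  # systolic outflow: lateral Gaussian offset from the inflow axis
  out_ctr_x <- ctr[1] + 10 * p$voxel_size
  x <- (seq_len(nx) - 1) * p$voxel_size
  y <- (seq_len(ny) - 1) * p$voxel_size
  r2_out <- outer((x - out_ctr_x)^2, (y - ctr[2])^2, "+")
  out_sigma <- 8
  lat_out <- exp(-r2_out / (2 * out_sigma^2))
  lat_out[r2_out > (3 * out_sigma)^2] <- 0

  env <- inflow_envelope(p, frame_times)
  env_sys <- systolic_envelope(p, frame_times)
  z_ann <- annulus_z_position(p, frame_times)
  z_vc <- z_ann + p$vena_contracta_offset
  apex <- apex_z(p)

  vz <- array(0, dim = c(nx, ny, nz, nt))
  lv_mask <- array(FALSE, dim = c(nx, ny, nz, nt))
  r2_ctr <- outer((x - ctr[1])^2, (y - ctr[2])^2, "+")
  lv_base_radius <- 38

  for (k in seq_len(nt)) {
    ax <- jet_axial_profile(p, zc - z_vc[k])
    frame <- outer(as.vector(lat), ax)
    if (p$systolic_velocity > 0 && env_sys[k] > 0) {
      ax_out <- as.numeric(zc >= z_ann[k] + 5 & zc <= apex - 14)
      frame <- frame * env[k] - outer(as.vector(lat_out), ax_out) * env_sys[k]
    } else {
      frame <- frame * env[k]
    }
    vz[, , , k] <- frame
    # hemi-ellipsoidal LV cavity from the (moving) annulus plane to the apex
    lv_len <- apex - z_ann[k]
    inside_z <- which(zc >= z_ann[k] & zc <= apex)
    msk <- array(FALSE, dim = c(nx, ny, nz))
    for (iz in inside_z) {
      rad <- lv_base_radius * sqrt(pmax(0, 1 - ((zc[iz] - z_ann[k]) / lv_len)^2))
      msk[, , iz] <- r2_ctr <= rad^2
    }
    # the mask may never be empty: keep at least the apical cap voxel row
    if (!any(msk)) msk[, , inside_z[1]] <- r2_ctr <= (2 * p$voxel_size)^2
    lv_mask[, , , k] <- msk
  }

  vx <- array(0, dim = c(nx, ny, nz, nt))
  vy <- array(0, dim = c(nx, ny, nz, nt))
  if (p$noise_sd > 0) {
    withr::local_seed(p$seed)
    nvox <- length(vz)
    vx <- vx + array(stats::rnorm(nvox, sd = p$noise_sd), dim = dim(vx))
    vy <- vy + array(stats::rnorm(nvox, sd = p$noise_sd), dim = dim(vy))
    vz <- vz + array(stats::rnorm(nvox, sd = p$noise_sd), dim = dim(vz))
  }
  if (p$inject_aliasing) {
    vx <- wrap_to_venc(vx, p$venc)
    vy <- wrap_to_venc(vy, p$venc)
    vz <- wrap_to_venc(vz, p$venc)
  }

  affine <- diag(c(rep(p$voxel_size, 3), 1))
  field <- velocity_field(vx, vy, vz, affine, frame_times, p$venc)

  lm1 <- cbind(ctr[1] - p$annulus_radius, ctr[2], z_ann)
  lm2 <- cbind(ctr[1] + p$annulus_radius, ctr[2], z_ann)
  cine <- render_cine(p, lm1, lm2, frame_times)

  truth <- structure(list(
    true_peak_e = p$peak_e_velocity,
    true_peak_a = p$peak_a_velocity,
    true_ea_ratio = p$peak_e_velocity / p$peak_a_velocity,
    true_peak_flow_e = p$peak_e_velocity *
      jet_axial_profile(p, -p$vena_contracta_offset) *
      jet_effective_area_cm2(p),
    true_peak_flow_a = p$peak_a_velocity *
      jet_axial_profile(p, -p$vena_contracta_offset) *
      jet_effective_area_cm2(p),
    annulus_trajectory = list(landmark_1 = lm1, landmark_2 = lm2,
                              midpoint = cbind(ctr[1], ctr[2], z_ann)),
    plane_speed = annulus_z_speed(p, frame_times),
    fused = envelope_is_fused(p)
  ), class = "phantom_truth")

  landmarks <- list(frame_index = 0L,
                    points_mm = rbind(lm1[1, ], lm2[1, ]))

  structure(list(field = field, cine = cine, lv_mask = lv_mask,
                 landmarks = landmarks, truth = truth, params = p),
            class = "flow_phantom")
}

# Long-axis ("3ch"-like) cine: the x-z plane through the jet axis, 1 mm
# pixels, annulus landmarks rendered as bright Gaussian blobs over a faint
# static texture so normalized cross-correlation tracking is well-posed.
render_cine <- function(params, lm1, lm2, frame_times) {
  p <- params
  ctr <- grid_center_xy(p)
  spacing <- 1
  nu <- ceiling((p$grid_shape[1] - 1) * p$voxel_size) + 1
  nv <- ceiling((p$grid_shape[3] - 1) * p$voxel_size) + 1
  ug <- (seq_len(nu) - 1) * spacing  # world x
  vg <- (seq_len(nv) - 1) * spacing  # world z
  texture <- 0.05 * outer(sin(2 * pi * ug / 37), sin(2 * pi * vg / 53))
  nt <- length(frame_times)
  imgs <- array(0, dim = c(nu, nv, nt))
  blob_sigma <- 3
  for (k in seq_len(nt)) {
    b1 <- outer(exp(-(ug - lm1[k, 1])^2 / (2 * blob_sigma^2)),
                exp(-(vg - lm1[k, 3])^2 / (2 * blob_sigma^2)))
    b2 <- outer(exp(-(ug - lm2[k, 1])^2 / (2 * blob_sigma^2)),
                exp(-(vg - lm2[k, 3])^2 / (2 * blob_sigma^2)))
    imgs[, , k] <- texture + b1 + b2
  }
  structure(list(images = imgs,
                 origin = c(0, ctr[2], 0),
                 u = c(1, 0, 0), v = c(0, 0, 1), through = c(0, 1, 0),
                 spacing = spacing, frame_times = frame_times),
            class = "cine_series")
}

#' @export
print.flow_phantom <- function(x, ...) {
  cat(sprintf(
    "<flow_phantom> E %g / A %g cm/s (E/A %.2f%s), %d frames, VENC %g cm/s\n",
    x$truth$true_peak_e, x$truth$true_peak_a, x$truth$true_ea_ratio,
    if (x$truth$fused) ", fused" else "", x$params$n_frames, x$params$venc))
  invisible(x)
}

#' Write a phantom to disk in standard formats
#'
#' Velocity components go to three NIfTI files (float32, cm/s), the LV mask
#' and cine to NIfTI, the landmark seed and ground truth to JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_velocity_field(phantom$field, file.path(dir, "phantom"))
  write_mask_series(phantom$lv_mask, phantom$field$affine,
                    file.path(dir, "phantom_lvmask.nii.gz"))
  cine <- phantom$cine
  img <- RNifti::asNifti(cine$images, datatype = "float")
  RNifti::writeNifti(img, file.path(dir, "phantom_cine.nii.gz"))
  jsonlite::write_json(
    list(frame_index = phantom$landmarks$frame_index,
         points_mm = phantom$landmarks$points_mm),
    file.path(dir, "phantom_landmarks.json"), digits = NA)
  tr <- phantom$truth
  jsonlite::write_json(
    list(true_peak_e = tr$true_peak_e, true_peak_a = tr$true_peak_a,
         true_ea_ratio = tr$true_ea_ratio,
         true_peak_flow_e = tr$true_peak_flow_e,
         true_peak_flow_a = tr$true_peak_flow_a,
         fused = tr$fused,
         annulus_midpoint_mm = tr$annulus_trajectory$midpoint),
    file.path(dir, "phantom_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a landmark seed JSON
#' @param path JSON file with fields `frame_index` and `points_mm`.
#' @return List with `frame_index` (integer) and `points_mm` (2 x 3 matrix).
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(frame_index = as.integer(x$frame_index),
       points_mm = matrix(as.numeric(x$points_mm), nrow = 2))
}

# ---- synthetic paired measurements ------------------------------------------

#' Simulate a paired per-subject measurement table
#'
#' Draws per-subject reference ("echo") peak E, peak A and E/A values, then
#' per-method values linearly related to the reference
#' (`value = slope * echo + intercept + noise`), so the agreement statistics
#' can be exercised against known ground-truth relationships.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param echo Reference distribution parameters: a list with `peak_e_mean`,
#'   `peak_e_sd` (cm/s), `ea_mean`, `ea_sd`, `ea_min`, `ea_max`.
#' @param methods Named list; one entry per method, each a list with `slope`,
#'   `intercept` and `sd` (noise SD, >= 0), applied to every metric.
#' @param seed Integer seed.
#'
#' @return A long tibble with columns `subject_id`, `metric`
#'   (`ea`, `peak_e`, `peak_a`), `method` (`echo` plus the names of
#'   `methods`), and `value`.
#' @export
make_paired_measurements <- function(n_subjects,
                                     echo = list(peak_e_mean = 75,
                                                 peak_e_sd = 15,
                                                 ea_mean = 1.0, ea_sd = 0.4,
                                                 ea_min = 0.5, ea_max = 2.8),
                                     methods = list(
                                       lvvel = list(slope = 1, intercept = 0, sd = 0.1),
                                       mvvel = list(slope = 1, intercept = 0, sd = 0.1),
                                       mvflow = list(slope = 1, intercept = 0, sd = 0.1)),
                                     seed = 1L) {
  if (n_subjects < 4) abort("n_subjects must be at least 4")
  for (m in names(methods)) {
    if (methods[[m]]$sd < 0)
      abort(sprintf("negative noise SD for method '%s'", m))
  }
  withr::local_seed(as.integer(seed))
  peak_e <- pmax(20, stats::rnorm(n_subjects, echo$peak_e_mean, echo$peak_e_sd))
  ea <- pmin(echo$ea_max,
             pmax(echo$ea_min, stats::rnorm(n_subjects, echo$ea_mean, echo$ea_sd)))
  peak_a <- peak_e / ea
  ref <- tibble(subject_id = rep(seq_len(n_subjects), times = 3),
                metric = rep(c("ea", "peak_e", "peak_a"), each = n_subjects),
                method = "echo",
                value = c(ea, peak_e, peak_a))
  rows <- purrr::map(names(methods), function(m) {
    sp <- methods[[m]]
    dplyr::mutate(ref, method = m,
                  value = sp$slope * .data$value + sp$intercept +
                    stats::rnorm(dplyr::n(), 0, sp$sd))
  })
  dplyr::bind_rows(ref, rows)
}
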