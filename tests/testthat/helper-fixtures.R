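# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the default noise-free study phantom
default_phantom <- function() {
  cached("phantom", function() generate_phantom(phantom_params()))
}

phantom_apex <- function(phantom) {
  p <- phantom$params
  c((p$grid_shape[1:2] - 1) / 2 * p$voxel_size,
    p$voxel_size * (p$grid_shape[3] - 5))
}

# tracked plane obtained through the full cine-tracking route
default_tracked_plane <- function() {
  cached("plane", function() {
    ph <- default_phantom()
    tracks <- track_landmarks(ph$cine, ph$landmarks$points_mm,
                              ph$landmarks$frame_index)
    plane_velocity(landmarks_to_plane(tracks, ph$cine, phantom_apex(ph)))
  })
}

default_mv_map <- function() {
  cached("mv_map", function() {
    ph <- default_phantom()
    mv_velocity_map(ph$field, default_tracked_plane())
  })
}

default_lv_peaks <- function() {
  cached("lv_peaks", function() {
    ph <- default_phantom()
    lvvel_ea(ph$field, ph$lv_mask)
  })
}

default_mv_peaks <- function() {
  cached("mv_peaks", function() {
    curve <- max_velocity_curve(default_mv_map())
    detect_ea_peaks(curve)
  })
}

default_mvflow_peaks <- function() {
  cached("mvflow_peaks", function() {
    curve <- flow_rate_curve(default_mv_map())
    detect_ea_peaks(curve)
  })
}

# small, fast phantom for structural tests (jet scaled down to fit the grid)
small_phantom_params <- function(...) {
  phantom_params(grid_shape = c(25L, 25L, 35L), n_frames = 20L,
                 e_peak_time_frac = 11 / 20, a_peak_time_frac = 18 / 20,
                 jet_radius = 8, ...)
}

# a phantom whose E and A envelopes overlap into a single diastolic peak
fused_phantom_params <- function(...) {
  phantom_params(e_peak_time_frac = 0.55, a_peak_time_frac = 0.65,
                 e_width = 150, a_width = 150, ...)
}

# voxels untouched by either the inflow jet (truncated at 3 sigma) or the
# systolic outflow jet: truly static background for phase-offset fitting
static_background_mask <- function(params) {
  p <- params
  ctr <- (p$grid_shape[1:2] - 1) / 2 * p$voxel_size
  x <- (seq_len(p$grid_shape[1]) - 1) * p$voxel_size
  y <- (seq_len(p$grid_shape[2]) - 1) * p$voxel_size
  r2_in <- outer((x - ctr[1])^2, (y - ctr[2])^2, "+")
  r2_out <- outer((x - (ctr[1] + 10 * p$voxel_size))^2, (y - ctr[2])^2, "+")
  lateral <- r2_in > (3 * p$jet_radius)^2 & r2_out > 24^2
  array(rep(lateral, p$grid_shape[3]), dim = p$grid_shape)
}

# minimal hand-built velocity field: uniform velocity per component
uniform_field <- function(v, dims = c(8, 8, 8, 6), voxel = 2, venc = 120) {
  mk <- function(val) array(val, dim = dims)
  velocity_field(mk(v[1]), mk(v[2]), mk(v[3]),
                 affine = diag(c(rep(voxel, 3), 1)),
                 frame_times = seq(0, by = 50, length.out = dims[4]),
                 venc = venc)
}

# minimal hand-built static tracked plane with given normal
static_plane <- function(n_frames, origin, normal, basis_u, basis_v,
                         frame_times = seq(0, by = 50, length.out = n_frames),
                         plane_vel = rep(0, n_frames)) {
  structure(list(origins = matrix(origin, n_frames, 3, byrow = TRUE),
                 normals = matrix(normal, n_frames, 3, byrow = TRUE),
                 basis_u = matrix(basis_u, n_frames, 3, byrow = TRUE),
                 basis_v = matrix(basis_v, n_frames, 3, byrow = TRUE),
                 landmark_tracks = NULL, frame_times = frame_times,
                 plane_velocity = plane_vel),
            class = "tracked_plane")
}

# hand-built plane velocity map (for segmentation/curve unit tests)
manual_map <- function(values, spacing = 1, masks = NULL,
                       frame_times = NULL) {
  d <- dim(values)
  if (is.null(frame_times)) frame_times <- seq(0, by = 50, length.out = d[3])
  structure(list(values = values, inside = array(TRUE, dim = d),
                 masks = masks, grid_spacing = spacing,
                 grid_extent = (d[1] - 1) * spacing,
                 grid_coords = seq(-(d[1] - 1) / 2, (d[1] - 1) / 2,
                                   length.out = d[1]) * spacing,
                 plane = NULL, frame_times = frame_times),
            class = "plane_velocity_map")
}
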