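test_that("a static cine yields a constant track at the initialisation", {
  ph <- generate_phantom(small_phantom_params(annulus_excursion = 0))
  tracks <- track_landmarks(ph$cine, ph$landmarks$points_mm, 0)
  for (l in 1:2) {
    ref <- matrix(ph$landmarks$points_mm[l, ], nrow(tracks[, l, ]), 3,
                  byrow = TRUE)
    # constant up to quadratic-subpixel refinement jitter (well below 0.1 px)
    expect_lt(max(abs(tracks[, l, ] - ref)), 0.05)
  }
})

test_that("phantom annulus motion is tracked to sub-pixel accuracy", {
  ph <- default_phantom()
  tracks <- track_landmarks(ph$cine, ph$landmarks$points_mm, 0)
  tr <- ph$truth$annulus_trajectory
  err1 <- sqrt(rowSums((tracks[, 1, ] - tr$landmark_1)^2))
  err2 <- sqrt(rowSums((tracks[, 2, ] - tr$landmark_2)^2))
  expect_lt(max(err1), 1)  # <= 1 cine pixel (1 mm)
  expect_lt(max(err2), 1)
  # excursion amplitude recovered within one voxel
  amp <- diff(range(tracks[, 1, 3]))
  expect_lt(abs(amp - ph$params$annulus_excursion), ph$params$voxel_size)
})

test_that("landmark seeds outside the image or frame range are rejected", {
  ph <- generate_phantom(small_phantom_params())
  bad <- ph$landmarks$points_mm
  bad[1, 1] <- 1e4
  expect_error(track_landmarks(ph$cine, bad, 0), "outside")
  expect_error(track_landmarks(ph$cine, ph$landmarks$points_mm, 99),
               "out of range")
})

test_that("plane construction follows the chord/through-plane geometry", {
  tracks <- array(0, dim = c(4, 2, 3))
  tracks[, 1, ] <- matrix(c(0, 0, 0), 4, 3, byrow = TRUE)
  tracks[, 2, ] <- matrix(c(20, 0, 0), 4, 3, byrow = TRUE)
  attr(tracks, "frame_times") <- seq(0, 150, by = 50)
  class(tracks) <- "landmark_tracks"
  cine <- list(through = c(0, 1, 0))
  pl <- landmarks_to_plane(tracks, cine, apex_hint = c(10, 0, 40))
  expect_equal(pl$origins[1, ], c(10, 0, 0))
  expect_equal(pl$normals[1, ], c(0, 0, 1))
  # swapping the landmarks gives the identical plane
  sw <- tracks
  sw[, 1, ] <- tracks[, 2, ]; sw[, 2, ] <- tracks[, 1, ]
  attr(sw, "frame_times") <- attr(tracks, "frame_times")
  class(sw) <- "landmark_tracks"
  pl2 <- landmarks_to_plane(sw, cine, apex_hint = c(10, 0, 40))
  expect_equal(pl2$origins, pl$origins)
  expect_equal(pl2$normals, pl$normals)
  # degenerate input
  tracks[, 2, ] <- tracks[, 1, ]
  expect_error(landmarks_to_plane(tracks, cine, c(10, 0, 40)), "coincident")
})

test_that("pure translation keeps the plane normal constant", {
  ph <- default_phantom()
  pl <- default_tracked_plane()
  spread <- apply(pl$normals, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 0.02)
})

test_that("plane velocity is zero for a static plane and exact for linear motion", {
  pl0 <- static_plane(6, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  expect_equal(plane_velocity(pl0)$plane_velocity, rep(0, 6))
  # 3 cm/s along the normal: 0.03 mm/ms; central differences are exact on the
  # interior frames (the cyclic wrap breaks linearity at the two ends)
  times <- seq(0, by = 50, length.out = 8)
  pl <- static_plane(8, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                     frame_times = times)
  pl$origins[, 3] <- 0.03 * times
  v <- plane_velocity(pl)$plane_velocity
  expect_equal(v[2:7], rep(3, 6), tolerance = 1e-12)
  bad_times <- times; bad_times[3] <- bad_times[2]
  expect_error(plane_velocity(pl, bad_times), "strictly increasing")
})

test_that("sinusoidal annulus excursion gives the closed-form peak plane speed", {
  ph <- default_phantom()
  pl <- true_annulus_plane(ph)
  d_mm <- ph$params$annulus_excursion / 2
  t_ms <- ph$params$cycle_length
  analytic_peak <- 100 * 2 * pi * d_mm / t_ms  # cm/s
  # discrete central differences attenuate a sinusoid by sinc(2*pi/N)
  n <- ph$params$n_frames
  attenuation <- sin(2 * pi / n) / (2 * pi / n)
  expect_equal(max(pl$plane_velocity), analytic_peak * attenuation,
               tolerance = 0.05)
  # and the cine-tracked plane agrees with the analytic one
  tracked <- default_tracked_plane()
  expect_equal(max(tracked$plane_velocity), analytic_peak * attenuation,
               tolerance = 0.05)
})

test_that("combined track lies between the forward and backward passes", {
  # with identical passes (static cine) the combination equals either pass;
  # on the moving phantom the fused track must stay within the per-frame
  # bounding box of the two passes by convexity
  ph <- default_phantom()
  cine <- ph$cine
  init_px <- ea4dflow:::world_to_cine_px(ph$landmarks$points_mm, cine)
  nt <- dim(cine$images)[3]
  fwd <- ea4dflow:::ncc_pass(cine$images, 1:nt, init_px[1, ], 10L, 10L, 0.3)
  bwd <- ea4dflow:::ncc_pass(cine$images, c(1, nt:2), init_px[1, ], 10L, 10L, 0.3)
  tracks <- track_landmarks(cine, ph$landmarks$points_mm, 0)
  comb_px <- ea4dflow:::world_to_cine_px(tracks[, 1, ], cine)
  lo <- pmin(fwd$pos, bwd$pos) - 1e-9
  hi <- pmax(fwd$pos, bwd$pos) + 1e-9
  expect_true(all(comb_px >= lo & comb_px <= hi))
  expect_equal(comb_px[1, ], unname(init_px[1, ]), tolerance = 1e-9)
})

test_that("tracked planes round-trip through JSON", {
  pl <- default_tracked_plane()
  path <- withr::local_tempfile(fileext = ".json")
  write_tracked_plane(pl, path)
  pl2 <- read_tracked_plane(path)
  expect_equal(pl2$origins, pl$origins, tolerance = 1e-12)
  expect_equal(pl2$normals, pl$normals, tolerance = 1e-12)
  expect_equal(pl2$plane_velocity, pl$plane_velocity, tolerance = 1e-12)
})
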