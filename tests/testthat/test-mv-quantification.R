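test_that("reformatting projects interpolated vectors onto the plane normal", {
  pl <- static_plane(6, c(7, 7, 7), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  along <- uniform_field(c(0, 0, 10))
  map <- reformat_velocity(along, pl, grid_spacing = 1, grid_extent = 8)
  expect_true(all(abs(map$values - 10) < 1e-12))
  expect_true(all(map$inside))
  ortho <- uniform_field(c(10, 0, 0))
  map2 <- reformat_velocity(ortho, pl, grid_spacing = 1, grid_extent = 8)
  expect_true(all(abs(map2$values) < 1e-12))
  # frame-count mismatch
  pl4 <- static_plane(4, c(7, 7, 7), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  expect_error(reformat_velocity(along, pl4), "does not match")
})

test_that("grid points outside the field are zeroed and excluded", {
  pl <- static_plane(6, c(7, 7, 7), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  f <- uniform_field(c(0, 0, 10))
  map <- reformat_velocity(f, pl, grid_spacing = 1, grid_extent = 40)
  expect_false(all(map$inside))
  expect_true(all(map$values[!map$inside] == 0))
})

test_that("the reformatted phantom map peaks at the analytic plane-level value", {
  ph <- default_phantom()
  p <- ph$params
  map <- reformat_velocity(ph$field, true_annulus_plane(ph))
  e_frame <- round(p$e_peak_time_frac * p$n_frames) + 1
  analytic <- p$peak_e_velocity *
    ea4dflow:::jet_axial_profile(p, -p$vena_contracta_offset)
  expect_lt(abs(max(map$values[, , e_frame]) - analytic) / analytic, 0.03)
})

test_that("plane-motion correction subtracts the plane's normal velocity", {
  pl <- static_plane(6, c(7, 7, 7), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  f <- uniform_field(c(0, 0, 5))
  map <- reformat_velocity(f, pl, grid_spacing = 1, grid_extent = 8)
  # static plane: identity
  same <- correct_for_plane_motion(map, rep(0, 6))
  expect_identical(same$values, map$values)
  # fluid and plane both moving at 5 cm/s along the normal: relative velocity 0
  rel <- correct_for_plane_motion(map, rep(5, 6))
  expect_true(all(abs(rel$values) < 1e-12))
  # on the phantom, correction changes every in-grid sample by exactly the
  # per-frame plane velocity
  ph <- default_phantom()
  pl_t <- default_tracked_plane()
  raw <- reformat_velocity(ph$field, pl_t)
  cor <- correct_for_plane_motion(raw)
  for (k in c(5, 17, 28)) {
    delta <- raw$values[, , k][raw$inside[, , k]] -
      cor$values[, , k][cor$inside[, , k]]
    expect_equal(unique(round(delta, 10)), round(pl_t$plane_velocity[k], 10))
  }
})

test_that("inflow segmentation keeps the central connected component", {
  d <- c(31, 31, 1)
  # all zeros: empty mask
  m0 <- segment_inflow_area(manual_map(array(0, dim = d)))
  expect_false(any(m0$masks))
  # single central jet
  vals <- array(0, dim = d)
  ij <- as.matrix(expand.grid(1:31, 1:31))
  r2c <- (ij[, 1] - 16)^2 + (ij[, 2] - 16)^2
  vals[cbind(ij, 1)] <- ifelse(r2c <= 9, 60, 0)
  m1 <- segment_inflow_area(manual_map(vals))
  expect_true(all(m1$masks[, , 1][vals[, , 1] >= 9]))
  expect_equal(sum(m1$masks), sum(r2c <= 9))
  # a hotter but disjoint corner blob is not the inflow area
  vals2 <- vals
  r2corner <- (ij[, 1] - 5)^2 + (ij[, 2] - 5)^2
  vals2[cbind(ij, 1)] <- vals2[cbind(ij, 1)] + ifelse(r2corner <= 4, 80, 0)
  m2 <- segment_inflow_area(manual_map(vals2))
  expect_true(all(m2$masks[, , 1][r2c <= 9]))
  expect_false(any(m2$masks[, , 1][r2corner <= 4]))
})

test_that("3x3 median filtering is edge-safe, spike-removing and bounded", {
  const <- manual_map(array(7, dim = c(9, 9, 2)))
  expect_identical(median_filter_map(const)$values, const$values)
  spike <- array(0, dim = c(9, 9, 1))
  spike[5, 5, 1] <- 1000
  expect_true(all(median_filter_map(manual_map(spike))$values == 0))
  withr::local_seed(1)
  rnd <- manual_map(array(stats::rnorm(9 * 9 * 3), dim = c(9, 9, 3)))
  filt <- median_filter_map(rnd)$values
  for (k in 1:3) {
    frame <- rnd$values[, , k]
    for (i in 1:9) for (j in 1:9) {
      nb <- frame[max(1, i - 1):min(9, i + 1), max(1, j - 1):min(9, j + 1)]
      expect_gte(filt[i, j, k], min(nb))
      expect_lte(filt[i, j, k], max(nb))
    }
  }
})

test_that("curves integrate and maximize the map over the inflow masks", {
  vals <- array(10, dim = c(21, 21, 3))
  masks <- array(FALSE, dim = c(21, 21, 3))
  masks[1:20, 1:20, ] <- TRUE  # 400 px at 1 mm^2 = 4 cm^2
  map <- manual_map(vals, masks = masks)
  mv <- max_velocity_curve(map)
  expect_equal(mv$values, rep(10, 3))
  fl <- flow_rate_curve(map)
  expect_equal(fl$values, rep(40, 3))  # 10 cm/s * 4 cm^2
  empty <- manual_map(vals, masks = array(FALSE, dim = c(21, 21, 3)))
  expect_equal(max_velocity_curve(empty)$values, rep(0, 3))
  expect_equal(flow_rate_curve(empty)$values, rep(0, 3))
  expect_error(max_velocity_curve(manual_map(vals)), "no inflow masks")
})

test_that("phantom curve peaks land on the envelope peak frames", {
  ph <- default_phantom()
  p <- ph$params
  curve <- max_velocity_curve(default_mv_map())
  dt <- p$cycle_length / p$n_frames
  pk <- detect_ea_peaks(curve)
  expect_lte(abs(pk$e_time - p$e_peak_time_frac * p$cycle_length), dt)
  expect_lte(abs(pk$a_time - p$a_peak_time_frac * p$cycle_length), dt)
})

test_that("MVflow E/A is within 10% of the true volumetric ratio", {
  ph <- default_phantom()
  pk <- default_mvflow_peaks()
  truth <- ph$truth$true_peak_flow_e / ph$truth$true_peak_flow_a
  expect_lt(abs(pk$ea_ratio - truth) / truth, 0.1)
})

test_that("MVvel underestimates the vena-contracta peaks but keeps the ratio", {
  ph <- default_phantom()
  pk <- default_mv_peaks()
  expect_lte(pk$e_value, ph$truth$true_peak_e)
  expect_lte(pk$a_value, ph$truth$true_peak_a)
  expect_lt(abs(pk$ea_ratio - ph$truth$true_ea_ratio) /
              ph$truth$true_ea_ratio, 0.05)
})

test_that("the mitral pipeline is deterministic", {
  ph <- generate_phantom(small_phantom_params())
  pl <- true_annulus_plane(ph)
  m1 <- mv_velocity_map(ph$field, pl)
  m2 <- mv_velocity_map(ph$field, pl)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$masks, m2$masks)
  expect_identical(detect_ea_peaks(max_velocity_curve(m1)),
                   detect_ea_peaks(max_velocity_curve(m2)))
})
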