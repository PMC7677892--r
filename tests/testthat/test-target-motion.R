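test_that("null parameters give identically zero motion", {
  hx <- fix_heart()
  p0 <- target_motion_params(avpd = 0, apex_drift = 0, normal_amp = 0,
                             thickening = 0, noise_sd = 0)
  mt <- generate_target_motion(hx$mesh, hx$coords, p0)
  expect_true(all(vapply(mt$frames, function(f) max(abs(f)), 0) == 0))
})

test_that("frame 0 is zero, frames are time-ordered, generator is reproducible", {
  hx <- fix_heart()
  p <- target_motion_params(noise_sd = 0.5, seed = 7)
  m1 <- generate_target_motion(hx$mesh, hx$coords, p)
  m2 <- generate_target_motion(hx$mesh, hx$coords, p)
  expect_identical(m1$frames, m2$frames)
  expect_true(all(m1$frames[[1]] == 0))
  expect_true(all(diff(m1$frame_times) > 0))
  expect_equal(length(m1$frames), 10)
})

test_that("basal descent and apex quiescence follow the configured amplitudes", {
  hx <- fix_heart()
  p <- target_motion_params(avpd = 12, apex_drift = 0, normal_amp = 0,
                            thickening = 0, noise_sd = 0)
  mt <- generate_target_motion(hx$mesh, hx$coords, p)
  pk <- peak_frame(mt)
  s_pk <- max(mt$time_course)   # frames sample the time course near its peak
  ring <- basal_ring_nodes(hx$mesh, hx$coords)
  expect_equal(avpd(mt$frames[[pk]], ring), 12 * s_pk, tolerance = 1e-6)
  expect_lt(max(abs(mt$frames[[pk]][hx$mesh$apex_patch, ])), 1e-6)
  # AVPD/VAD sign conventions oppose under rigid translation
  n <- nrow(hx$mesh$nodes)
  u_rigid <- matrix(rep(c(0, 0, -5), each = n), ncol = 3)
  expect_equal(avpd(u_rigid, ring), 5)
  expect_equal(vad(u_rigid, hx$mesh$apex_patch), -5)
})

test_that("epicardial normal displacement reduces correctly", {
  hx <- fix_heart()
  m <- hx$mesh
  sw_nodes <- extract_epicardial_normal_displacement(
    m, list(matrix(0, nrow(m$nodes), 3)))
  # pure normal displacement of 2 mm at one frame -> 2 mm everywhere
  u2 <- matrix(0, nrow(m$nodes), 3)
  u2[sw_nodes$nodes, ] <- 2 * sw_nodes$normal
  ext <- extract_epicardial_normal_displacement(m, list(u2))
  expect_equal(ext$value, rep(2, length(ext$value)), tolerance = 1e-10)
  # tangential sliding -> zero
  tang <- sw_nodes$normal[, c(2, 1, 3)]
  tang[, 2] <- -sw_nodes$normal[, 1]
  tang[, 1] <- sw_nodes$normal[, 2]
  tang[, 3] <- 0
  u3 <- matrix(0, nrow(m$nodes), 3)
  u3[sw_nodes$nodes, ] <- tang
  ext3 <- extract_epicardial_normal_displacement(m, list(u3))
  expect_lt(max(ext3$value), 1e-10)
  # brute-force per-node loop oracle equals the vectorized reduction
  p <- target_motion_params(noise_sd = 0.3, seed = 3)
  mt <- generate_target_motion(m, hx$coords, p)
  ext4 <- extract_epicardial_normal_displacement(m, mt)
  brute <- vapply(seq_along(ext4$nodes), function(i) {
    nid <- ext4$nodes[i]
    best <- 0
    for (fr in mt$frames)
      best <- max(best, abs(sum(fr[nid, ] * ext4$normal[i, ])))
    best
  }, 0)
  expect_equal(ext4$value, brute, tolerance = 1e-12)
})

test_that("mean epicardial normal displacement grows from apex to base", {
  hx <- fix_heart()
  # normal-dominated motion: the invariant concerns the monotone profile
  p <- target_motion_params(avpd = 0, apex_drift = 0, thickening = 0,
                            normal_amp = 6, noise_sd = 0)
  mt <- generate_target_motion(hx$mesh, hx$coords, p)
  prof <- epi_normal_profile(hx$mesh, hx$coords, mt$frames, n_bins = 8)
  prof <- prof[!is.na(prof$disp), ]
  # monotone non-decreasing up to small sampling wiggle
  expect_true(all(diff(prof$disp) > -0.15))
  expect_gt(prof$disp[nrow(prof)], prof$disp[1])
})
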