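test_that("node distance statistics match direct computation", {
  set.seed(31)
  n <- 200
  a <- matrix(stats::rnorm(3 * n), n, 3)
  b <- matrix(stats::rnorm(3 * n), n, 3)
  st <- node_distance_stats(a, b)
  d <- sqrt(rowSums((a - b)^2))
  expect_equal(unname(st["mean"]), mean(d), tolerance = 1e-12)
  expect_equal(unname(st["sd"]), sqrt(mean((d - mean(d))^2)), tolerance = 1e-12)
  expect_equal(unname(node_distance_stats(a, a)), c(0, 0))
  # rigid 3 mm offset: mean 3, sd 0
  off <- a + matrix(rep(c(3, 0, 0), each = n), ncol = 3)
  expect_equal(unname(node_distance_stats(off, a)), c(3, 0), tolerance = 1e-12)
  expect_error(node_distance_stats(a, b[1:10, ]), "mismatch")
})

test_that("AVPD and VAD follow their sign conventions", {
  hx <- fix_heart()
  n <- nrow(hx$mesh$nodes)
  ring <- basal_ring_nodes(hx$mesh, hx$coords)
  apex <- hx$mesh$apex_patch
  expect_gt(length(ring), 4)
  # base moved 5 mm toward the apex: AVPD +5
  u <- matrix(0, n, 3); u[ring, 3] <- -5
  expect_equal(avpd(u, ring), 5)
  expect_equal(vad(u, apex), 0)
  # apex moved 2 mm toward the base: VAD +2
  u2 <- matrix(0, n, 3); u2[apex, 3] <- 2
  expect_equal(vad(u2, apex), 2)
  # circumferential twist about the long axis leaves both at zero
  xy <- hx$mesh$nodes[, 1:2]
  u3 <- cbind(-xy[, 2], xy[, 1], 0) * 0.05
  expect_lt(abs(avpd(u3, ring)), 1e-10)
  expect_lt(abs(vad(u3, apex)), 1e-10)
  expect_error(avpd(u, integer(0)), "empty")
})

test_that("ejection metrics reduce the PV record correctly", {
  fake <- structure(list(
    timeline = data.frame(V_LV = c(120, 100, 70, 70), p_LV = c(1, 5, 9, 6)),
    V_ed = list(LV = 120)), class = "sim_result")
  em <- ejection_metrics(fake, "LV")
  expect_equal(unname(em["EF"]), 100 * (120 - 70) / 120)
  expect_equal(unname(em["PP"]), 9)
  # no ejection: EF 0
  flat <- structure(list(timeline = data.frame(V_LV = c(120, 120),
                                               p_LV = c(1, 1)),
                         V_ed = list(LV = 120)), class = "sim_result")
  expect_equal(unname(ejection_metrics(flat, "LV")["EF"]), 0)
})

test_that("fiber strain matches closed forms and objectivity", {
  hx <- fix_heart()
  m <- hx$mesh
  n <- nrow(m$nodes)
  # uniform stretch along x with fibers along x: E_ff = (lambda^2 - 1)/2
  fib <- uniform_fiber_field(m, c(1, 0, 0), c(0, 1, 0))
  lam <- 1.1
  u <- cbind((lam - 1) * m$nodes[, 1], 0, 0)
  e <- fiber_strain_field(m, fib, u)
  expect_equal(e, rep((lam^2 - 1) / 2, length(e)), tolerance = 1e-10)
  # rigid rotation: zero strain
  th <- 0.4
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  u_rot <- m$nodes %*% t(Rz) - m$nodes
  e_rot <- fiber_strain_field(m, fib, u_rot)
  expect_lt(max(abs(e_rot)), 1e-10)
  # random affine field: matches E = (F'F - I)/2 computed directly
  set.seed(9)
  A <- 0.1 * matrix(stats::rnorm(9), 3)
  u_aff <- m$nodes %*% t(A)
  F0 <- diag(3) + A
  E0 <- (t(F0) %*% F0 - diag(3)) / 2
  e_aff <- fiber_strain_field(m, fib, u_aff)
  expect_equal(e_aff, rep(E0[1, 1], length(e_aff)), tolerance = 1e-10)
})

test_that("wall thickening recovers uniform transmural expansion", {
  hx <- fix_heart()
  m <- hx$mesh
  wt0 <- wall_thickening(m, matrix(0, nrow(m$nodes), 3))
  expect_true(all(abs(wt0$thickening_pct) < 1e-10))
  # generator round-trip: thickening-only motion
  p <- target_motion_params(avpd = 0, apex_drift = 0, normal_amp = 0,
                            thickening = 0.10, noise_sd = 0)
  mt <- generate_target_motion(m, hx$coords, p)
  wt <- wall_thickening(m, mt$frames[[peak_frame(mt)]])
  # LV pairs whose baseline distance matches the nominal wall thickness
  sel <- abs(wt$t_ed - m$params$lv_thickness) < 0.15 * m$params$lv_thickness
  expect_gt(sum(sel), 10)
  expect_equal(mean(wt$thickening_pct[sel]), 10, tolerance = 0.2 * 10)
})

test_that("metrics are invariant to node renumbering", {
  set.seed(33)
  n <- 150
  u <- matrix(stats::rnorm(3 * n), n, 3)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  perm <- sample(n)
  st1 <- node_distance_stats(u, v)
  st2 <- node_distance_stats(u[perm, ], v[perm, ])
  expect_equal(st1, st2, tolerance = 1e-12)
  ring <- sample(n, 20)
  expect_equal(avpd(u, ring), avpd(u[perm, ], match(ring, perm)))
})
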