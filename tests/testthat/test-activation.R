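test_that("eikonal times match closed forms on axis-aligned bars", {
  bar <- build_bar_mesh(40, 10, 10, 2)
  fib <- uniform_fiber_field(bar, c(1, 0, 0), c(0, 1, 0))
  # isotropic propagation along the bar
  cp <- conduction_params(0.6, 0.6, 0.6,
                          stim_nodes = which(bar$nodes[, 1] < 1e-9))
  am <- solve_eikonal(bar, fib, cp)
  far <- which(abs(bar$nodes[, 1] - 40) < 1e-9)
  expect_equal(mean(am$t_act[far]), 40 / 0.6, tolerance = 0.03)
  # transverse propagation at v_s across the fibers
  cp2 <- conduction_params(0.6, 0.24, 0.24,
                           stim_nodes = which(bar$nodes[, 2] < 1e-9))
  am2 <- solve_eikonal(bar, fib, cp2)
  fy <- which(abs(bar$nodes[, 2] - 10) < 1e-9)
  expect_equal(mean(am2$t_act[fy]), 10 / 0.24, tolerance = 0.05)
})

test_that("oblique anisotropy approaches the point-source closed form", {
  bar <- build_bar_mesh(40, 10, 10, 2)
  f <- c(1, 1, 0) / sqrt(2); s <- c(-1, 1, 0) / sqrt(2)
  fib <- uniform_fiber_field(bar, f, s)
  cp <- conduction_params(0.6, 0.2, 0.2,
                          stim_nodes = which(rowSums(abs(bar$nodes)) < 1e-9))
  am <- solve_eikonal(bar, fib, cp)
  x <- c(40, 10, 0)
  M <- 0.36 * outer(f, f) + 0.04 * (outer(s, s) + outer(c(0, 0, 1), c(0, 0, 1)))
  exact <- sqrt(drop(t(x) %*% solve(M) %*% x))
  node <- which(abs(bar$nodes[, 1] - 40) < 1e-9 &
                  abs(bar$nodes[, 2] - 10) < 1e-9 &
                  abs(bar$nodes[, 3]) < 1e-9)
  expect_equal(am$t_act[node], exact, tolerance = 0.03 * exact)
})

test_that("solver never exceeds the anisotropic graph-distance bound", {
  hx <- fix_heart()
  co <- hx$coords
  cp <- conduction_params(stim_nodes = rv_endo_stimulus(hx$mesh, co))
  am <- solve_eikonal(hx$mesh, hx$fibers, cp)
  dj <- dijkstra_activation(hx$mesh, hx$fibers, cp)
  ok <- is.finite(am$t_act) & is.finite(dj)
  expect_true(all(am$t_act[ok] <= dj[ok] + 1e-9))
  # excluded regions carry NA; ventricular nodes are all reached
  vn <- ventricular_nodes(hx$mesh)
  expect_true(all(is.finite(am$t_act[vn])))
  expect_true(all(am$t_act[cp$stim_nodes] == 0))
  expect_true(all(am$t_act[vn] >= 0))
})

test_that("conduction tuning hits the target total activation time", {
  hx <- fix_heart()
  cp <- conduction_params(stim_nodes = rv_endo_stimulus(hx$mesh, hx$coords),
                          qrs_target = 120)
  tuned <- tune_conduction(hx$mesh, hx$fibers, cp)
  am <- solve_eikonal(hx$mesh, hx$fibers, tuned)
  expect_equal(total_activation_time(am), 120, tolerance = 0.01 * 120)
  # homogeneity: doubling all velocities halves the times
  cp2 <- tuned
  cp2$v_f <- 2 * tuned$v_f; cp2$v_s <- 2 * tuned$v_s; cp2$v_n <- 2 * tuned$v_n
  am2 <- solve_eikonal(hx$mesh, hx$fibers, cp2)
  ok <- is.finite(am$t_act)
  expect_equal(am2$t_act[ok], am$t_act[ok] / 2, tolerance = 1e-4)
  # fixed point: target equal to the current total leaves velocities be
  cp3 <- tuned
  cp3$qrs_target <- total_activation_time(am)
  tuned2 <- tune_conduction(hx$mesh, hx$fibers, cp3)
  expect_equal(tuned2$v_f, tuned$v_f, tolerance = 1e-4)
})

test_that("invalid conduction setups are rejected", {
  expect_error(conduction_params(0.2, 0.4, 0.6), "v_f >= v_s")
  hx <- fix_heart()
  cp <- conduction_params(stim_nodes = integer(0))
  expect_error(solve_eikonal(hx$mesh, hx$fibers, cp), "empty")
})
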