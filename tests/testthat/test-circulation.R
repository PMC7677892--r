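test_that("cavity volume is exact on simple closed polyhedra", {
  # closed triangulated 10 mm cube: 1 mL exactly
  v <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (outward -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 10
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 10
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 10
  cl <- list(tris = tri, rim = integer(0), cap_edges = NULL,
             grad_uid = 1:8, grad_map = match(c(tri[, 1], tri[, 2], tri[, 3]), 1:8))
  expect_equal(cardiomech:::closed_surface_volume6(cl, v) / 6000, 1,
               tolerance = 1e-12)
})

test_that("capped hemisphere volume approaches (2/3) pi R^3", {
  R <- 10
  n_phi <- 24; n_th <- 48
  phi <- seq(0, pi / 2, length.out = n_phi + 1)
  th <- 2 * pi * (seq_len(n_th) - 1) / n_th
  # pole + lattice + rim; fan-cap the equator like a basal orifice
  pts <- rbind(c(0, 0, R))
  id <- matrix(0L, n_phi, n_th)
  for (i in 2:(n_phi + 1)) for (j in seq_len(n_th)) {
    pts <- rbind(pts, R * c(sin(phi[i]) * cos(th[j]),
                            sin(phi[i]) * sin(th[j]), cos(phi[i])))
    id[i - 1, j] <- nrow(pts)
  }
  tris <- list()
  for (j in seq_len(n_th)) {
    jp <- (j %% n_th) + 1
    tris[[length(tris) + 1]] <- c(1, id[1, j], id[1, jp])
    for (i in 1:(n_phi - 1))
      tris[[length(tris) + 1]] <- rbind(c(id[i, j], id[i + 1, j], id[i, jp]),
                                        c(id[i, jp], id[i + 1, j], id[i + 1, jp]))
  }
  tris <- do.call(rbind, tris)
  rim <- id[n_phi, ]
  cap <- cbind(rim, c(rim[-1], rim[1]))   # directed equator edges
  ids <- c(tris[, 1], tris[, 2], tris[, 3], cap[, 2], cap[, 1], rim)
  uid <- sort(unique(ids))
  cl <- list(tris = tris, rim = rim, cap_edges = cap,
             grad_uid = uid, grad_map = match(ids, uid))
  v <- cardiomech:::closed_surface_volume6(cl, pts) / 6000
  expect_equal(v, 2 / 3 * pi * R^3 / 1000, tolerance = 0.01)
})

test_that("Windkessel decay matches the RC closed form to first order in dt", {
  wk <- windkessel_params(Z = 7, R = 140, C_wk = 8, P_art0 = 10)
  decay_err <- function(dt) {
    P <- 10; t_end <- 400
    for (k in seq_len(t_end / dt)) P <- windkessel_step(P, 0, dt, wk)$P_wk
    abs(P - 10 * exp(-t_end / (wk$R * wk$C_wk)))
  }
  e10 <- decay_err(10); e5 <- decay_err(5); e2.5 <- decay_err(2.5)
  expect_lt(e10, 0.02)             # small absolute error already at dt = 10
  expect_equal(e10 / e5, 2, tolerance = 0.25)    # first-order convergence
  expect_equal(e5 / e2.5, 2, tolerance = 0.25)
})

test_that("Windkessel reaches the resistive steady state under constant flow", {
  wk <- windkessel_params(Z = 7, R = 140, C_wk = 8, P_art0 = 1)
  P <- 1; Q <- 0.05
  for (k in 1:8000) {
    s <- windkessel_step(P, Q, 1, wk)
    P <- s$P_wk
  }
  expect_equal(P, Q * wk$R, tolerance = 1e-3)
  expect_equal(s$P_prox, Q * (wk$R + wk$Z), tolerance = 1e-2)
})

test_that("isovolumic pressure solve is exact on linear volume-pressure laws", {
  calls <- 0
  vol <- function(p) { calls <<- calls + 1; 100 + 4 * p }
  res <- isovolumic_pressure(vol, V_target = 120, p_guess = 1,
                             dVdp_guess = 2)
  expect_equal(res$V, 120, tolerance = 120 * 1e-3)
  expect_lte(res$iters, 2)
  # already at target: no extra solves
  calls <- 0
  res0 <- isovolumic_pressure(vol, V_target = 104, p_guess = 1)
  expect_equal(res0$iters, 0)
  expect_equal(calls, 1)
})
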