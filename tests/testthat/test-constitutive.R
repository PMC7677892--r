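test_that("Guccione energy matches the closed form and is anisotropic", {
  # direct substitution: E_ff = 0.1, C = 2, b_f = 8
  E <- diag(c(0, 0, 0)); E[1, 1] <- 0.1
  expect_equal(guccione_energy(E, guccione_params(C_scale = 2, b_f = 8)),
               exp(0.08) - 1, tolerance = 1e-12)
  expect_equal(guccione_energy(matrix(0, 3, 3)), 0)
  expect_error(guccione_energy(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
  # monotone along the fiber-stretch ray
  ws <- vapply(seq(0, 0.2, 0.02), function(e) {
    E <- matrix(0, 3, 3); E[1, 1] <- e
    guccione_energy(E)
  }, 0)
  expect_true(all(diff(ws) > 0))
})

test_that("passive stresses are exact derivatives of their energies", {
  set.seed(11)
  gp <- guccione_params(); bk <- bulk_penalty(); nh <- neo_hookean_params()
  worst_g <- 0; worst_n <- 0
  for (r in 1:100) {
    F0 <- diag(3) + 0.05 * matrix(stats::rnorm(9), 3)
    if (det(F0) <= 0.2) next
    R <- random_rotation()
    C0 <- t(F0) %*% F0
    Sg <- passive_pk2(F0, R, gp, bk)
    Sg_fd <- fd_pk2(function(C) {
      # chol gives U with C = U'U, so F = U reproduces this C
      passive_energy(chol(C), R, gp, bk)
    }, C0)
    worst_g <- max(worst_g, max(abs(Sg - Sg_fd)) / max(abs(Sg_fd)))
    Sn <- neo_hookean_pk2(F0, nh, bk)
    Sn_fd <- fd_pk2(function(C) neo_hookean_energy(chol(C), nh, bk), C0)
    worst_n <- max(worst_n, max(abs(Sn - Sn_fd)) / max(abs(Sn_fd)))
  }
  expect_lt(worst_g, 1e-5)
  expect_lt(worst_n, 1e-5)
})

test_that("reference state is stress-free and the volumetric split is clean", {
  R <- diag(3)
  expect_equal(passive_pk2(diag(3), R), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(neo_hookean_pk2(diag(3)), matrix(0, 3, 3), tolerance = 1e-12)
  # pure volumetric stretch: only the penalty term acts
  lam <- 1.04
  kap <- bulk_penalty(650)
  W <- passive_energy(lam * diag(3), R, guccione_params(), kap)
  expect_equal(W, kap$kappa / 2 * (lam^3 - 1)^2, tolerance = 1e-10)
})

test_that("energies are frame-indifferent", {
  set.seed(12)
  F0 <- diag(3) + 0.05 * matrix(stats::rnorm(9), 3)
  R <- random_rotation()
  w0 <- passive_energy(F0, R)
  for (r in 1:20) {
    Q <- random_rotation()
    expect_equal(passive_energy(Q %*% F0, R), w0, tolerance = 1e-10)
  }
})

test_that("neo-Hookean shear response linearizes to mu gamma", {
  mu <- 10; kap <- bulk_penalty(650)
  gam <- 0.01
  F0 <- diag(3); F0[1, 2] <- gam
  S <- neo_hookean_pk2(F0, neo_hookean_params(mu), kap)
  # Cauchy = F S F' / J; shear component ~ mu gamma for small gamma
  sig <- F0 %*% S %*% t(F0) / det(F0)
  expect_equal(sig[1, 2], mu * gam, tolerance = 0.02 * mu * gam)
})

test_that("active transient has the stated support, peak and duration knob", {
  p <- active_params(T_peak = 60, t_emd = 15, tau_c = 40, tau_dur = 300,
                     tau_r = 60)
  t_act <- 20
  expect_equal(active_tension(c(0, 10, 35), t_act, p), c(0, 0, 0))
  ts <- seq(0, 800, 0.25)
  Ta <- active_tension(ts, t_act, p)
  expect_true(all(Ta >= 0 & Ta <= p$T_peak))
  # peak reaches T_peak for tau_dur >= 10 max(tau_c, tau_r)
  expect_gte(max(Ta), 0.9 * p$T_peak)
  # support length equals tau_dur; increasing tau_dur by 20% scales it by 1.2
  supp <- range(ts[Ta > 0])
  expect_equal(diff(supp), p$tau_dur, tolerance = 1)
  p2 <- active_params(tau_dur = p$tau_dur * 1.2)
  supp2 <- range(ts[active_tension(ts, t_act, p2) > 0])
  expect_equal(diff(supp2) / diff(supp), 1.2, tolerance = 0.01)
  # continuity: no jumps larger than the sampling allows
  expect_lt(max(abs(diff(Ta))), 0.02 * p$T_peak)
})

test_that("active stress has eigenvalues {Ta, eta Ta, eta Ta}", {
  R <- random_rotation()
  S <- active_pk2(10, R, eta = 0.4)
  expect_equal(sort(eigen(S, symmetric = TRUE)$values),
               c(4, 4, 10), tolerance = 1e-10)
  S0 <- active_pk2(10, R, eta = 0)
  expect_equal(sum(diag(S0)), 10, tolerance = 1e-10)
  expect_equal(qr(S0)$rank, 1)
  expect_equal(active_pk2(0, R, 0.4), matrix(0, 3, 3))
})
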