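test_that("stress-free reference state has zero residual", {
  bar <- build_bar_mesh(10, 10, 10, 5)
  fib <- uniform_fiber_field(bar)
  mdl <- mechanics_model(bar, fib,
                         bc = spring_bc_params(k_vein = 0, pericardium = FALSE),
                         cavities = character(0))
  r <- assemble_residual(mdl, matrix(0, nrow(bar$nodes), 3))
  expect_equal(r$norm, 0)
})

test_that("assembled residual is the exact gradient of the total potential", {
  set.seed(5)
  bar <- build_bar_mesh(10, 10, 10, 5)
  fib <- uniform_fiber_field(bar)
  mdl <- mechanics_model(bar, fib,
                         bc = spring_bc_params(k_vein = 0, pericardium = FALSE),
                         cavities = character(0))
  n <- nrow(bar$nodes)
  u <- matrix(stats::rnorm(3 * n, sd = 0.1), n, 3)
  Ta <- stats::runif(nrow(bar$tets), 0, 20)
  r <- assemble_residual(mdl, u, Ta, list())
  h <- 1e-6
  worst <- 0
  for (k in 1:12) {
    i <- sample(n, 1); d <- sample(3, 1)
    up <- u; up[i, d] <- up[i, d] + h
    dn <- u; dn[i, d] <- dn[i, d] - h
    e1 <- cardiomech:::model_energy_grad(mdl, up, Ta, list(), grad = FALSE)$energy
    e0 <- cardiomech:::model_energy_grad(mdl, dn, Ta, list(), grad = FALSE)$energy
    fd <- (e1 - e0) / (2 * h)
    worst <- max(worst, abs(fd - r$residual[i, d]) / max(abs(fd), 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("pressure load on a closed cavity has zero net force", {
  sh <- build_spherical_shell(10, 13, 2.5)
  fib <- uniform_fiber_field(sh)
  mdl <- mechanics_model(sh, fib,
                         bc = spring_bc_params(k_vein = 0, pericardium = FALSE),
                         cavities = "LV")
  n <- nrow(sh$nodes)
  set.seed(6)
  u <- matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
  # isolate the pressure contribution: residual(p) - residual(0)
  r1 <- assemble_residual(mdl, u, NULL, list(LV = 2))$residual
  r0 <- assemble_residual(mdl, u, NULL, list(LV = 0))$residual
  fp <- r1 - r0
  expect_lt(max(abs(colSums(fp))), 1e-8 * sum(abs(fp)))
})

test_that("zero load increment converges without moving", {
  sh <- build_spherical_shell(10, 13, 3)
  fib <- uniform_fiber_field(sh)
  mdl <- mechanics_model(sh, fib,
                         bc = spring_bc_params(k_vein = 0, pericardium = FALSE),
                         cavities = "LV")
  u0 <- matrix(0, nrow(sh$nodes), 3)
  sol <- solve_equilibrium(mdl, u0, NULL, list(LV = 0))
  expect_lte(sol$iters, 1)
  expect_equal(sol$u, u0)
})

test_that("small-pressure shell inflation matches the Lame solution", {
  mu <- 10; kap <- 100
  sh <- build_spherical_shell(10, 13, 2)
  fib <- uniform_fiber_field(sh)
  mats <- material_set(neo_hookean = neo_hookean_params(mu),
                       bulk = bulk_penalty(kap))
  mdl <- mechanics_model(sh, fib, mats,
                         bc = spring_bc_params(k_vein = 0, pericardium = FALSE),
                         cavities = "LV",
                         config = mechanics_config(pre_mu = mu,
                                                   pre_lambda = kap))
  p <- 0.05
  sol <- solve_equilibrium(mdl, matrix(0, nrow(sh$nodes), 3), NULL,
                           list(LV = p))
  rad <- sqrt(rowSums(sh$nodes^2))
  inner <- which(abs(rad - 10) < 0.4)
  ur <- mean(rowSums(sol$u[inner, ] * sh$nodes[inner, ] / rad[inner]))
  E <- 9 * kap * mu / (3 * kap + mu)
  nu <- (3 * kap - 2 * mu) / (2 * (3 * kap + mu))
  a <- 10; b <- 13
  u_lame <- p * a^3 / (E * (b^3 - a^3)) *
    ((1 - 2 * nu) * a + (1 + nu) * b^3 / (2 * a^2))
  expect_equal(ur, u_lame, tolerance = 0.10)
})

test_that("pericardial springs reduce epicardial normal motion under load", {
  hx <- fix_heart()
  xi <- hx$coords$xi
  map <- uniform_penalty_map(50)
  run <- function(peri) {
    mdl <- mechanics_model(hx$mesh, hx$fibers, coords = hx$coords,
                           bc = spring_bc_params(k_vein = 10,
                                                 pericardium = peri),
                           map = map)
    Ta <- rep(20, nrow(hx$mesh$tets))
    Ta[hx$mesh$tet_region == "BASAL_TISSUE"] <- 0
    sol <- solve_equilibrium(mdl, matrix(0, nrow(hx$mesh$nodes), 3), Ta,
                             list(LV = 0, RV = 0))
    ext <- extract_epicardial_normal_displacement(hx$mesh, list(sol$u))
    mean(ext$value)
  }
  expect_lt(run(TRUE), run(FALSE))
})
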