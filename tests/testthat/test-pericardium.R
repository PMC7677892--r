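test_that("penalty map flips a linear profile and pins the extremes", {
  set.seed(21)
  xi <- runif(4000)
  d <- 8 * xi
  map <- derive_penalty_map(d, xi, n_bins = 20, k_max = 50)
  xs <- seq(0, 1, 0.01)
  expect_lt(max(abs(map$scale(xs) - (1 - xs))), 0.05)
  expect_equal(map$scale(0), 1)
  expect_equal(map$scale(1), 0)
  expect_true(all(diff(map$scale(xs)) <= 1e-9))
  expect_true(all(map$scale(xs) >= 0 & map$scale(xs) <= 1))
})

test_that("degenerate displacement fields are rejected", {
  xi <- seq(0, 1, length.out = 100)
  expect_error(derive_penalty_map(rep(2, 100), xi), "degenerate")
})

test_that("stiffness evaluation scales and clamps", {
  xi <- runif(2000)
  map <- derive_penalty_map(5 * xi, xi, k_max = 50)
  expect_equal(stiffness_at(map, 0), 50)
  expect_equal(stiffness_at(map, 1), 0)
  expect_warning(k <- stiffness_at(map, 1.2), "clamped")
  expect_equal(k, 0)
  umap <- uniform_penalty_map(50)
  expect_equal(stiffness_at(umap, c(0, 0.5, 1)), c(50, 50, 50))
})

test_that("penalty-map recovery from generated motion meets the error bounds", {
  hx <- fix_heart()
  # known monotone profile, all other motion components off
  base <- function(noise, seed) {
    p <- target_motion_params(avpd = 0, apex_drift = 0, normal_amp = 8,
                              thickening = 0, noise_sd = noise, seed = seed)
    mt <- generate_target_motion(hx$mesh, hx$coords, p)
    ext <- extract_epicardial_normal_displacement(hx$mesh, mt)
    derive_penalty_map(ext, hx$coords$xi, n_bins = 20, k_max = 50)
  }
  xs <- seq(0, 1, 0.02)
  map0 <- base(0, 1)
  expect_lt(max(abs(map0$scale(xs) - (1 - xs))), 0.05)
  map1 <- base(0.5, 42)
  expect_lt(max(abs(map1$scale(xs) - (1 - xs))), 0.15)
})

test_that("spring tractions are linear, normal-only and energy-consistent", {
  n0 <- c(0, 0, 1)
  expect_equal(robin_normal_traction(c(0, 0, 0), n0, 50), c(0, 0, 0))
  expect_equal(robin_normal_traction(c(3, -2, 0), n0, 50), c(0, 0, 0))
  expect_equal(robin_normal_traction(0.1 * n0, n0, 50), -5 * n0)
  expect_equal(omni_spring_traction(c(1, 0, 0), 10), c(-10, 0, 0))
  expect_equal(omni_spring_traction(3 * c(1, 2, 3), 10),
               3 * omni_spring_traction(c(1, 2, 3), 10))
  # traction = -dE/du for the spring energy density 1/2 k (u.n0)^2
  u <- c(0.2, -0.1, 0.4); k <- 50; h <- 1e-7
  e_of <- function(u) 0.5 * k * sum(u * n0)^2
  fd <- -vapply(1:3, function(i) {
    du <- numeric(3); du[i] <- h
    (e_of(u + du) - e_of(u - du)) / (2 * h)
  }, 0)
  expect_equal(robin_normal_traction(u, n0, k), fd, tolerance = 1e-8)
})

test_that("penalty map JSON round-trips", {
  xi <- runif(1000)
  map <- derive_penalty_map(6 * xi^2, xi, k_max = 50)
  f <- tempfile(fileext = ".json")
  write_penalty_map(map, f)
  map2 <- read_penalty_map(f)
  xs <- seq(0, 1, 0.05)
  expect_equal(map2$scale(xs), map$scale(xs), tolerance = 0.01)
  expect_equal(map2$k_max, 50)
  unlink(f)
})
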