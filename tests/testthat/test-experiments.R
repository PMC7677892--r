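# Parametric-study behavior on a deliberately small heart so several beats
# fit in the test budget; only directions of change are asserted.

micro_config <- function() {
  cfg <- default_config()
  cfg$geometry <- list(lv_length = 64, lv_radius = 20, lv_thickness = 8,
                       rv_gap = 12, trunc_height = 12, band_height = 8,
                       edge_length = 10)
  cfg$solver$dt <- 10
  cfg
}

fix_study <- function() fixture("study", function() {
  cfg <- micro_config()
  shared <- build_shared(cfg)
  variants <- parametric_variants()[c("tpeak_x1.2", "eta_0.4", "kn_div50")]
  run_parametric_study(cfg, variants, pericardium = TRUE, shared = shared)
})

test_that("active-tension variants move ejection fraction in the reported directions", {
  st <- fix_study()
  tab <- st$table
  ef <- function(v) tab$EF[tab$variant == v & tab$arm == "with"]
  expect_gt(ef("tpeak_x1.2"), ef("control"))   # more fiber stress -> more EF
  expect_lt(ef("eta_0.4"), ef("control"))      # transverse stress -> less EF
})

test_that("softening the normal springs 50-fold frees apical motion during IVC", {
  st <- fix_study()
  m50 <- st$metrics[["kn_div50.with"]]
  mc <- st$metrics[["control.with"]]
  # apical IVC excursion (either direction) grows when the springs soften
  expect_gt(abs(m50$vad_ivc) + abs(m50$ivc_epi_outward),
            abs(mc$vad_ivc) + abs(mc$ivc_epi_outward))
})

test_that("percent-change columns are consistent with their absolute values", {
  st <- fix_study()
  tab <- st$table
  ctrl <- tab[tab$variant == "control" & tab$arm == "with", ]
  for (v in unique(tab$variant)) {
    row <- tab[tab$variant == v & tab$arm == "with", ]
    if (!is.finite(row$EF_pct)) next
    expect_equal(row$EF, ctrl$EF * (1 + row$EF_pct / 100), tolerance = 1e-8)
  }
})

test_that("study reports render deterministically with one row per variant arm", {
  st <- fix_study()
  d1 <- tempfile(); d2 <- tempfile()
  render_report(st, d1)
  render_report(st, d2)
  f1 <- file.path(d1, "study.csv"); f2 <- file.path(d2, "study.csv")
  expect_identical(readLines(f1), readLines(f2))
  tab <- utils::read.csv(f1)
  expect_equal(nrow(tab), nrow(st$table))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("disabling the pericardium equals a zero-stiffness override", {
  hx <- fix_heart()
  mats <- material_set()
  m_off <- mechanics_model(hx$mesh, hx$fibers, mats, hx$coords,
                           spring_bc_params(pericardium = FALSE))
  m_k0 <- mechanics_model(hx$mesh, hx$fibers, mats, hx$coords,
                          spring_bc_params(pericardium = TRUE, k_uniform = 0))
  set.seed(77)
  u <- matrix(stats::rnorm(3 * nrow(hx$mesh$nodes), sd = 0.15), ncol = 3)
  r1 <- assemble_residual(m_off, u, NULL, list(LV = 2, RV = 1))
  r2 <- assemble_residual(m_k0, u, NULL, list(LV = 2, RV = 1))
  expect_equal(r1$residual, r2$residual, tolerance = 1e-12)
  expect_equal(r1$energy, r2$energy, tolerance = 1e-12)
})
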