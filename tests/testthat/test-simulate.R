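# Beat-level behavior on top of the acceptance fixture: phase ordering,
# PV-loop orientation, stroke-volume/flow consistency, checkpoint metrics.

test_that("phases follow the admissible order and pressures stay continuous", {
  pair <- fix_pair()
  for (sim in list(pair$with, pair$without)) {
    ph <- sim$timeline$phase_LV
    allowed <- list(FILL = c("FILL", "IVC"), IVC = c("IVC", "EJECT"),
                    EJECT = c("EJECT", "IVR"), IVR = c("IVR", "DONE"),
                    DONE = "DONE")
    for (k in seq_len(length(ph) - 1))
      expect_true(ph[k + 1] %in% allowed[[ph[k]]])
    ev <- sim$events
    expect_lt(ev[["lv_ivc_start"]], ev[["lv_ejection_onset"]])
    expect_lt(ev[["lv_ejection_onset"]], ev[["lv_ejection_end"]])
    # pressure continuity at the FILL -> IVC transition
    k0 <- which(sim$time == ev[["lv_ivc_start"]])
    if (k0 > 1)
      expect_lt(abs(sim$timeline$p_LV[k0] - sim$timeline$p_LV[k0 - 1]), 0.5)
  }
})

test_that("the LV PV loop is traversed counter-clockwise", {
  pair <- fix_pair()
  tl <- pair$with$timeline
  sel <- tl$phase_LV != "DONE"
  V <- tl$V_LV[sel]; p <- tl$p_LV[sel]
  # shoelace area of the (V, p) polygon: counter-clockwise traversal
  # (pressurize at max V, eject at high p, relax at min V) is positive
  area <- sum(V * c(p[-1], p[1]) - c(V[-1], V[1]) * p) / 2
  expect_gt(area, 1)
})

test_that("stroke volume equals the integral of ejection flow", {
  pair <- fix_pair()
  tl <- pair$with$timeline
  ej <- tl$phase_LV == "EJECT"
  dt <- diff(pair$with$time)[1]
  sv_flow <- sum(tl$Q_LV[ej]) * dt
  sv <- max(tl$V_LV) - min(tl$V_LV)
  expect_equal(sv_flow, sv, tolerance = 0.05 * sv)
})

test_that("phase-aligned metrics compare at matched events, not wall-clock times", {
  pair <- fix_pair()
  # the two arms reach ejection at different times, yet metrics align by
  # fraction of systole
  expect_false(pair$with$events[["lv_ejection_end"]] ==
                 pair$without$events[["lv_ejection_end"]] &&
                 pair$with$events[["lv_ejection_onset"]] ==
                 pair$without$events[["lv_ejection_onset"]])
  expect_gte(pair$metrics_with$frac_onset, 0)
  expect_lte(pair$metrics_with$frac_onset, 1)
})

test_that("run reports and control-pair reports are deterministic renderings", {
  pair <- fix_pair()
  d <- tempfile()
  files <- render_report(pair, d)
  expect_true(all(file.exists(file.path(d, c("pv_loop_with.csv",
                                             "pv_loop_without.csv",
                                             "metrics.csv")))))
  met <- utils::read.csv(file.path(d, "metrics.csv"))
  expect_equal(met$arm, c("with", "without"))
  unlink(d, recursive = TRUE)
})
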