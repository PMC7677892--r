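# Full-beat orchestration: preload to the end-diastolic pressures, then
# march systole with per-ventricle phases FILL -> IVC -> EJECT -> IVR,
# holding cavity volume during the isovolumic phases and coupling ejection
# to the three-element Windkessel afterloads.

#' Default configuration of the desk-scale study
#'
#' One nested list holding every knob: geometry, fiber angles, activation,
#' materials, active tension, circulation, pericardial boundary conditions,
#' synthetic target motion and solver controls.
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(),                     # geometry_params() arguments
    fibers = list(alpha_endo = 80, alpha_epi = -60,
                  beta_endo = -65, beta_epi = 25),
    activation = list(v_f = 0.6, v_s = 0.4, v_n = 0.2, qrs_target = 120,
                      stim_xi_max = 0.7),
    material = list(guccione = list(C_scale = 2, b_f = 8, b_t = 3, b_fs = 4),
                    neo_hookean = list(mu = 40),
                    bulk = list(kappa = 650)),
    active = list(T_peak = 60, t_emd = 15, tau_c = 40, tau_dur = 300,
                  tau_r = 60, eta = 0),
    circulation = list(
      lv = list(Z = 7, R = 100, C_wk = 10, P_art0 = 7.0),
      rv = list(Z = 1.5, R = 24, C_wk = 20, P_art0 = 1.6),
      preload = list(EDP_LV = 1.6, EDP_RV = 0.8)),
    pericardium = list(k_max = 50, k_vein = 10, n_bins = 20,
                       k_uniform = NULL),
    target = list(avpd = 12, apex_drift = 1, normal_amp = 6,
                  thickening = 0.15, t_sys = 300, n_frames = 10,
                  noise_sd = 0, seed = 1L),
    solver = list(dt = 10, t_end = 700, tol_abs = 1e-4, max_iter = 800,
                  pre_mu = 20, vol_averaging = FALSE)
  )
}

#' Apply named overrides to a configuration
#'
#' Overrides are a named list: names are dot-paths into the config
#' (`"active.T_peak"`), values either `list(mul = x)` for a multiplier or
#' `list(set = x)` for replacement.
#' @param config a configuration list.
#' @param overrides named list of overrides.
#' @export
modify_config <- function(config, overrides) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ov <- overrides[[nm]]
    cur <- config[[path]]
    if (!is.null(ov$mul)) {
      if (is.null(cur)) stop("cannot scale unset config entry ", nm)
      config[[path]] <- cur * ov$mul
    } else if (!is.null(ov$set) || "set" %in% names(ov)) {
      config[[path]] <- ov$set
    } else stop("override for ", nm, " needs $mul or $set")
  }
  config
}

#' Precompute the shared study inputs
#'
#' Builds the mesh, wall coordinates, fibers, tuned activation map, the
#' synthetic target motion and the penalty map derived from it. These are
#' identical between the with- and without-pericardium arms.
#' @param config a configuration list (see [default_config()]).
#' @return list of shared objects.
#' @export
build_shared <- function(config = default_config()) {
  gp <- do.call(geometry_params, config$geometry)
  mesh <- build_idealized_biventricle(gp)
  coords <- compute_wall_coordinates(mesh)
  fb <- config$fibers
  fibers <- suppressMessages(assign_rule_based_fibers(
    mesh, coords, fb$alpha_endo, fb$alpha_epi, fb$beta_endo, fb$beta_epi))
  ac <- config$activation
  cp <- conduction_params(ac$v_f, ac$v_s, ac$v_n,
                          stim_nodes = rv_endo_stimulus(mesh, coords,
                                                        ac$stim_xi_max),
                          qrs_target = ac$qrs_target)
  if (!is.null(ac$qrs_target)) cp <- tune_conduction(mesh, fibers, cp)
  amap <- solve_eikonal(mesh, fibers, cp)
  motion <- generate_target_motion(mesh, coords,
                                   do.call(target_motion_params, config$target))
  epi_disp <- extract_epicardial_normal_displacement(mesh, motion)
  map <- derive_penalty_map(epi_disp, coords$xi,
                            n_bins = config$pericardium$n_bins,
                            k_max = config$pericardium$k_max)
  list(config = config, mesh = mesh, coords = coords, fibers = fibers,
       conduction = cp, amap = amap, motion = motion, epi_disp = epi_disp,
       map = map)
}

#' @noRd
shared_mechanics_model <- function(shared, pericardium) {
  cfg <- shared$config
  mats <- material_set(
    do.call(guccione_params, cfg$material$guccione),
    do.call(neo_hookean_params, cfg$material$neo_hookean),
    do.call(bulk_penalty, cfg$material$bulk))
  act <- do.call(active_params, cfg$active)
  bc <- spring_bc_params(k_vein = cfg$pericardium$k_vein,
                         pericardium = pericardium,
                         k_uniform = cfg$pericardium$k_uniform)
  sol <- cfg$solver
  avg <- if (is.null(sol$vol_averaging)) FALSE else sol$vol_averaging
  mechanics_model(shared$mesh, shared$fibers, mats, shared$coords, bc,
                  shared$map, act,
                  config = mechanics_config(tol_abs = sol$tol_abs,
                                            max_iter = sol$max_iter,
                                            pre_mu = sol$pre_mu,
                                            vol_averaging = avg))
}

#' Simulate one beat
#'
#' Preloads the ventricles to their end-diastolic pressures (the ED state
#' all displacements are reported against), then advances systole with the
#' per-ventricle phase machine until both ventricles complete isovolumic
#' relaxation or `t_end` is reached.
#'
#' @param shared output of [build_shared()].
#' @param pericardium logical: apply the epicardial normal springs.
#' @param verbose print per-step progress.
#' @return object of class `sim_result`: per-step `time`, pressures,
#'   volumes, phases, stored displacement `frames`, the ED state, phase
#'   `events` (ms), incompressibility statistics and iteration counts.
#' @export
simulate_beat <- function(shared, pericardium = TRUE, verbose = FALSE) {
  cfg <- shared$config
  model <- shared_mechanics_model(shared, pericardium)
  circ <- circulation_params(
    do.call(windkessel_params, cfg$circulation$lv),
    do.call(windkessel_params, cfg$circulation$rv),
    do.call(preload_params, cfg$circulation$preload))
  act <- model$active
  dt <- cfg$solver$dt
  t_end <- cfg$solver$t_end
  mesh <- shared$mesh

  # element activation times (ventricular only)
  ta_node <- shared$amap$t_act
  t_act_e <- (ta_node[mesh$tets[, 1]] + ta_node[mesh$tets[, 2]] +
                ta_node[mesh$tets[, 3]] + ta_node[mesh$tets[, 4]]) / 4
  t_act_e[!is.finite(t_act_e)] <- Inf

  edp <- list(LV = circ$preload$EDP_LV, RV = circ$preload$EDP_RV)
  wkp <- list(LV = circ$lv, RV = circ$rv)
  elems_of <- list(LV = which(mesh$tet_region == "LV_MYO"),
                   RV = which(mesh$tet_region == "RV_MYO"))

  # ---- preload to ED ----
  u <- matrix(0, model$n_nodes, 3)
  sol <- solve_equilibrium(model, u, NULL, edp)
  u <- sol$u
  u_ed <- u
  V_ed <- sol$volumes
  st <- list()
  for (cv in c("LV", "RV")) {
    st[[cv]] <- list(phase = "FILL", p = edp[[cv]], p_prev = edp[[cv]],
                     V = V_ed[[cv]], V_hold = NA,
                     P_wk = wkp[[cv]]$P_art0, slope = 3, Q = 0)
  }
  # cross-ventricle compliance matrix dV/dp for the pressure Newton,
  # initialized by finite-difference probes at ED and then maintained by
  # Broyden updates as the beat proceeds (mL/kPa)
  Jac <- matrix(c(3, -0.3, -0.3, 3), 2, 2,
                dimnames = list(c("LV", "RV"), c("LV", "RV")))
  dprobe <- 0.25
  u_probe <- u
  for (cv in c("LV", "RV")) {
    prp <- edp
    prp[[cv]] <- edp[[cv]] + dprobe
    sp <- minimize_potential(model, u_probe, NULL, prp)
    if (sp$converged) {
      Jac["LV", cv] <- (sp$volumes$LV - V_ed$LV) / dprobe
      Jac["RV", cv] <- (sp$volumes$RV - V_ed$RV) / dprobe
    }
  }
  events <- c()
  prev_pr <- edp
  prev_Ta <- numeric(nrow(mesh$tets))

  times <- seq(dt, t_end, by = dt)
  rec <- list()
  frames <- vector("list", length(times))
  jfrac <- numeric(length(times))
  iters_tot <- 0L

  chol_cur <- model$K0_chol
  u_last <- u
  lbfgs_mem <- NULL
  n3s <- sqrt(3 * model$n_nodes)
  eval_at <- function(pr, Ta, tol_factor = 1) {
    s <- minimize_potential(model, u_last, Ta, pr, chol = chol_cur,
                            mem_state = lbfgs_mem, tol_factor = tol_factor)
    if (!s$converged && s$res > 200 * cfg$solver$tol_abs * n3s) {
      # quasi-Newton stalled: Newton-CG with exact curvature
      s <- minimize_newton_cg(model, s$u, Ta, pr, chol = chol_cur,
                              tol_factor = tol_factor)
    }
    if (!s$converged && s$res > 200 * cfg$solver$tol_abs * n3s) {
      # genuinely stuck: ramp the load in from the last committed state
      s <- solve_equilibrium(model, u_last, Ta, pr,
                             Ta0 = Ta, pressures0 = prev_pr, chol = chol_cur)
      s$mem_state <- NULL
    }
    lbfgs_mem <<- s$mem_state
    u_last <<- s$u
    s
  }

  u_prev <- u
  S_committed <- NULL
  Ta_committed <- NULL
  W_committed <- NULL
  for (k in seq_along(times)) {
    t_wall <- Sys.time()
    iters_step0 <- iters_tot
    t <- times[k]
    Ta <- active_tension(t, t_act_e, act)
    Ta[!is.finite(t_act_e)] <- 0
    S_geo <- if (is.null(S_committed)) Ta * model$Astruct
             else S_committed + (Ta - Ta_committed) * model$Astruct
    chol_cur <- preconditioner_factor(model, Ta, S_geo = S_geo,
                                      W_el = W_committed)
    # linear time extrapolation as predictor (rejected if it inverts)
    u_warm <- u + (u - u_prev)
    if (!model_energy_grad(model, u_warm, Ta, prev_pr, grad = FALSE)$ok)
      u_warm <- u
    u_last <- u_warm
    p_step_start <- list(LV = st$LV$p, RV = st$RV$p)
    lbfgs_mem <- NULL   # curvature pairs are stale once Ta changed

    # phase-resolution loop: solve with current rules, apply transitions,
    # re-solve if any phase changed
    for (pass in 1:4) {
      # initial guess: linear pressure extrapolation keeps the first solve
      # near the constrained path (a fixed low pressure under rising active
      # tension can otherwise collapse the cavity past a fold)
      pr <- list(LV = clamp(2 * st$LV$p - st$LV$p_prev,
                            st$LV$p - 2, st$LV$p + 2),
                 RV = clamp(2 * st$RV$p - st$RV$p_prev,
                            st$RV$p - 2, st$RV$p + 2))
      if (pass > 1) pr <- list(LV = st$LV$p, RV = st$RV$p)
      for (cv in c("LV", "RV"))
        if (st[[cv]]$phase %in% c("FILL", "DONE")) pr[[cv]] <- edp[[cv]]

      # residuals of the constrained ventricles: volume mismatch (mL) for
      # IVC/IVR, pressure mismatch against the Windkessel (kPa, scaled to
      # mL by a nominal compliance) for EJECT
      resid_of <- function(sol) {
        r <- c(LV = 0, RV = 0)
        for (cv in c("LV", "RV")) {
          ph <- st[[cv]]$phase
          if (ph %in% c("IVC", "IVR")) {
            Vt <- if (ph == "IVC") V_ed[[cv]] else st[[cv]]$V_hold
            r[cv] <- sol$volumes[[cv]] - Vt
          } else if (ph == "EJECT") {
            Q <- (st[[cv]]$V - sol$volumes[[cv]]) / dt
            wk <- windkessel_step(st[[cv]]$P_wk, Q, dt, wkp[[cv]])
            r[cv] <- (pr[[cv]] - wk$P_prox) * 3
          }
        }
        r
      }
      tol_of <- function() {
        c(LV = if (st$LV$phase %in% c("IVC", "IVR")) 1e-3 * V_ed$LV else 0.06,
          RV = if (st$RV$phase %in% c("IVC", "IVR")) 1e-3 * V_ed$RV else 0.06)
      }

      sol <- eval_at(pr, Ta, tol_factor = 4)
      iters_tot <- iters_tot + sol$iters
      active_set <- c("LV", "RV")[c(!(st$LV$phase %in% c("FILL", "DONE")),
                                    !(st$RV$phase %in% c("FILL", "DONE")))]
      if (length(active_set) > 0) {
        r <- resid_of(sol)
        tolv <- tol_of()
        for (broy in 1:15) {
          if (all(abs(r[active_set]) <= tolv[active_set])) break
          Ja <- Jac[active_set, active_set, drop = FALSE]
          dp <- tryCatch(-solve(Ja, r[active_set]),
                         error = function(e) -r[active_set] / diag(Ja))
          dp <- clamp(dp, -2, 2)
          for (cv in active_set) pr[[cv]] <- pr[[cv]] + dp[[cv]]
          sol <- eval_at(pr, Ta, tol_factor = 4)
          iters_tot <- iters_tot + sol$iters
          r_new <- resid_of(sol)
          # Broyden update of the active block
          dr <- r_new[active_set] - r[active_set]
          denom <- sum(dp^2)
          if (denom > 1e-12) {
            Jac[active_set, active_set] <- Ja +
              outer(dr - as.numeric(Ja %*% dp), dp) / denom
            # guard: keep own-compliance positive and sane
            for (cv in active_set)
              if (Jac[cv, cv] < 0.2 || Jac[cv, cv] > 100) Jac[cv, cv] <- 3
          }
          r <- r_new
        }
      }

      # transitions
      changed <- FALSE
      for (cv in c("LV", "RV")) {
        ph <- st[[cv]]$phase
        V <- sol$volumes[[cv]]
        if (ph == "FILL" &&
            (mean(Ta[elems_of[[cv]]]) > 0.5 ||
               V < V_ed[[cv]] * (1 - 2e-3))) {
          # contraction has begun: close the inlet and hold the ED volume
          st[[cv]]$phase <- "IVC"
          events[paste0(tolower(cv), "_ivc_start")] <- t
          changed <- TRUE
        } else if (ph == "IVC" && pr[[cv]] >= st[[cv]]$P_wk) {
          st[[cv]]$phase <- "EJECT"
          events[paste0(tolower(cv), "_ejection_onset")] <- t
          changed <- TRUE
        } else if (ph == "EJECT") {
          Q <- (st[[cv]]$V - V) / dt
          if (Q <= 0 && t > events[paste0(tolower(cv), "_ejection_onset")]) {
            st[[cv]]$phase <- "IVR"
            st[[cv]]$V_hold <- st[[cv]]$V
            events[paste0(tolower(cv), "_ejection_end")] <- t
            changed <- TRUE
          }
        } else if (ph == "IVR" && pr[[cv]] <= edp[[cv]]) {
          st[[cv]]$phase <- "DONE"
          events[paste0(tolower(cv), "_ivr_end")] <- t
          changed <- TRUE
        }
        st[[cv]]$p <- pr[[cv]]
      }
      if (!changed) break
    }

    # commit: Windkessel update (flow only during ejection)
    u_prev <- u
    u <- sol$u
    for (cv in c("LV", "RV")) st[[cv]]$p_prev <- p_step_start[[cv]]
    for (cv in c("LV", "RV")) {
      Q <- if (st[[cv]]$phase == "EJECT")
        (st[[cv]]$V - sol$volumes[[cv]]) / dt else 0
      st[[cv]]$Q <- Q
      st[[cv]]$P_wk <- windkessel_step(st[[cv]]$P_wk, Q, dt, wkp[[cv]])$P_wk
      st[[cv]]$V <- sol$volumes[[cv]]
      st[[cv]]$p <- if (st[[cv]]$phase %in% c("FILL", "DONE")) edp[[cv]]
                    else st[[cv]]$p
    }
    prev_pr <- list(LV = st$LV$p, RV = st$RV$p)
    prev_Ta <- Ta

    det <- model_energy_grad(model, u, Ta, prev_pr, grad = FALSE,
                             details = TRUE)
    S_committed <- det$S
    Ta_committed <- Ta
    W_committed <- det$W
    ventJ <- det$J[model$vent]
    jfrac[k] <- mean(abs(ventJ - 1) <= 0.05)
    frames[[k]] <- u
    rec[[k]] <- data.frame(
      time = t, p_LV = st$LV$p, V_LV = st$LV$V, phase_LV = st$LV$phase,
      Q_LV = st$LV$Q, Pwk_LV = st$LV$P_wk,
      p_RV = st$RV$p, V_RV = st$RV$V, phase_RV = st$RV$phase,
      Q_RV = st$RV$Q, Pwk_RV = st$RV$P_wk,
      j_frac_ok = jfrac[k], stringsAsFactors = FALSE)
    if (verbose)
      cat(sprintf(
        "t=%4.0f LV %-5s p=%6.2f V=%6.1f | RV %-5s p=%5.2f V=%6.1f | %5d it %5.1fs\n",
        t, st$LV$phase, st$LV$p, st$LV$V, st$RV$phase, st$RV$p, st$RV$V,
        iters_tot - iters_step0, as.numeric(Sys.time() - t_wall, units = "secs")))
    if (st$LV$phase == "DONE" && st$RV$phase == "DONE") {
      times <- times[seq_len(k)]
      frames <- frames[seq_len(k)]
      jfrac <- jfrac[seq_len(k)]
      break
    }
  }

  timeline <- do.call(rbind, rec)
  structure(list(time = times, timeline = timeline, frames = frames,
                 u_ed = u_ed, V_ed = V_ed, events = events,
                 pericardium = pericardium, iters = iters_tot,
                 j_frac_ok = jfrac, config = cfg), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tl <- x$timeline
  cat("sim_result (", if (x$pericardium) "with" else "without",
      "pericardium ):", nrow(tl), "steps to", max(x$time), "ms\n")
  cat("  V_ED:", round(x$V_ed$LV, 1), "/", round(x$V_ed$RV, 1),
      "mL (LV/RV); min V_LV:", round(min(tl$V_LV), 1), "mL; max p_LV:",
      round(max(tl$p_LV), 2), "kPa\n")
  cat("  events:", paste(names(x$events), round(x$events), collapse = ", "),
      "\n")
  invisible(x)
}

#' Displacement relative to end-diastole at a recorded time index
#' @param sim a `sim_result`.
#' @param k step index (into `sim$time`), or one of the event names in
#'   `sim$events`.
#' @return n x 3 matrix (mm).
#' @export
displacement_at <- function(sim, k) {
  if (is.character(k)) {
    tev <- sim$events[[k]]
    if (is.null(tev)) stop("no event ", k, " in this run")
    k <- which.min(abs(sim$time - tev))
  }
  sim$frames[[k]] - sim$u_ed
}
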