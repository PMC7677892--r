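# Lumped circulation: preload, three-element Windkessel afterload and the
# per-ventricle cardiac-phase state machine. Units: kPa, mL, ms
# (resistances kPa ms/mL, compliances mL/kPa).

#' Three-element Windkessel parameters
#' @param Z characteristic (proximal) resistance (kPa ms/mL).
#' @param R peripheral resistance (kPa ms/mL).
#' @param C_wk arterial compliance (mL/kPa).
#' @param P_art0 initial arterial (Windkessel) pressure (kPa).
#' @export
windkessel_params <- function(Z = 7, R = 140, C_wk = 8, P_art0 = 9.3) {
  stopifnot(Z > 0, R > 0, C_wk > 0, P_art0 > 0)
  structure(list(Z = Z, R = R, C_wk = C_wk, P_art0 = P_art0),
            class = "windkessel_params")
}

#' Preload (end-diastolic pressure) parameters
#' @param EDP_LV,EDP_RV end-diastolic pressures (kPa).
#' @export
preload_params <- function(EDP_LV = 1.6, EDP_RV = 0.8) {
  stopifnot(EDP_LV >= 0, EDP_RV >= 0)
  structure(list(EDP_LV = EDP_LV, EDP_RV = EDP_RV), class = "preload_params")
}

#' Circulation parameter set for both ventricles
#' @param lv,rv [windkessel_params()] for the systemic and pulmonary sides.
#' @param preload a [preload_params()].
#' @export
circulation_params <- function(lv = windkessel_params(),
                               rv = windkessel_params(Z = 1.5, R = 24,
                                                      C_wk = 20, P_art0 = 1.6),
                               preload = preload_params()) {
  structure(list(lv = lv, rv = rv, preload = preload),
            class = "circulation_params")
}

#' One implicit-Euler Windkessel step
#'
#' Updates `C_wk dP_wk/dt = Q_in - P_wk/R` implicitly and returns the
#' proximal (cavity-side) pressure `P_prox = P_wk' + Z Q_in`.
#'
#' @param P_wk current Windkessel (arterial) pressure (kPa).
#' @param Q_in inflow from the ventricle (mL/ms).
#' @param dt time step (ms).
#' @param params a [windkessel_params()].
#' @return list with `P_wk` (updated) and `P_prox`.
#' @export
windkessel_step <- function(P_wk, Q_in, dt, params) {
  stopifnot(dt > 0)
  a <- params$C_wk / dt
  P_new <- (a * P_wk + Q_in) / (a + 1 / params$R)
  list(P_wk = P_new, P_prox = P_new + params$Z * Q_in)
}

#' Isovolumic pressure solve
#'
#' Secant iteration on the cavity pressure so that the mechanics volume
#' matches `V_target` to relative tolerance `tol`. `volume_of` must return
#' the converged cavity volume (mL) at a given pressure (kPa).
#'
#' @param volume_of function(p) -> volume (mL), a converged mechanics solve.
#' @param V_target target volume (mL).
#' @param p_guess starting pressure (kPa).
#' @param dVdp_guess initial volume-pressure slope estimate (mL/kPa).
#' @param tol relative volume tolerance.
#' @param max_iter iteration cap.
#' @return list with `p`, `V`, `iters`.
#' @export
isovolumic_pressure <- function(volume_of, V_target, p_guess,
                                dVdp_guess = 1, tol = 1e-3, max_iter = 30) {
  p <- p_guess
  V <- volume_of(p)
  if (abs(V - V_target) / V_target <= tol)
    return(list(p = p, V = V, iters = 0L))
  slope <- dVdp_guess
  p_prev <- p; V_prev <- V
  for (it in seq_len(max_iter)) {
    p <- p_prev + (V_target - V_prev) / slope
    V <- volume_of(p)
    if (abs(V - V_target) / V_target <= tol)
      return(list(p = p, V = V, iters = it))
    if (abs(p - p_prev) > 1e-12) slope <- (V - V_prev) / (p - p_prev)
    p_prev <- p; V_prev <- V
  }
  stop("isovolumic pressure iteration failed to bracket the target volume")
}
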