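# Material point laws: transversely isotropic Guccione passive myocardium
# with an isochoric/volumetric split, neo-Hookean non-ventricular tissue,
# volumetric penalty, and the phenomenological active-tension transient.
# Units: stresses kPa, times ms, lengths mm.

#' Guccione material parameters
#' @param C_scale stress scale C (kPa).
#' @param b_f,b_t,b_fs exponential coefficients (dimensionless).
#' @return object of class `guccione_params`.
#' @export
guccione_params <- function(C_scale = 2, b_f = 8, b_t = 3, b_fs = 4) {
  stopifnot(C_scale > 0, b_f > 0, b_t > 0, b_fs > 0)
  structure(list(C_scale = C_scale, b_f = b_f, b_t = b_t, b_fs = b_fs),
            class = "guccione_params")
}

#' Volumetric penalty parameter
#' @param kappa bulk penalty modulus (kPa).
#' @export
bulk_penalty <- function(kappa = 650) {
  stopifnot(kappa > 0)
  structure(list(kappa = kappa), class = "bulk_penalty")
}

#' Neo-Hookean parameters (non-ventricular tissue)
#'
#' The default is the effective stiffness of the basal tissue band, which
#' stands in for the atria and vessel stumps: soft enough to let the base
#' move, stiff enough to transmit the vein-anchor forces without letting
#' the ventricles swing on their anchors.
#' @param mu shear modulus (kPa).
#' @export
neo_hookean_params <- function(mu = 40) {
  stopifnot(mu > 0)
  structure(list(mu = mu), class = "neo_hookean_params")
}

#' Active-tension transient parameters
#'
#' Peak tension, electromechanical delay, rise/relaxation time constants,
#' plateau duration and the transverse active-stress fraction `eta` (0.4
#' applies 40% of the fiber active stress in the transverse plane).
#' @param T_peak peak active tension (kPa).
#' @param t_emd electromechanical delay after local activation (ms).
#' @param tau_c contraction rise time constant (ms).
#' @param tau_dur duration of the transient support (ms).
#' @param tau_r relaxation time constant (ms).
#' @param eta transverse fraction in `[0, 1]`.
#' @export
active_params <- function(T_peak = 60, t_emd = 15, tau_c = 40,
                          tau_dur = 300, tau_r = 60, eta = 0) {
  stopifnot(T_peak >= 0, t_emd >= 0, tau_c > 0, tau_dur > 0, tau_r > 0,
            eta >= 0, eta <= 1)
  structure(list(T_peak = T_peak, t_emd = t_emd, tau_c = tau_c,
                 tau_dur = tau_dur, tau_r = tau_r, eta = eta),
            class = "active_params")
}

# coefficient matrix of the Guccione exponent in the fiber frame
#' @noRd
guccione_B <- function(p) {
  matrix(c(p$b_f, p$b_fs, p$b_fs,
           p$b_fs, p$b_t, p$b_t,
           p$b_fs, p$b_t, p$b_t), 3, 3, byrow = TRUE)
}

#' Guccione strain-energy density
#'
#' `W = C/2 (exp(Q) - 1)` with
#' `Q = b_f E_ff^2 + b_t (E_ss^2 + E_nn^2 + E_sn^2 + E_ns^2) +
#'  b_fs (E_fs^2 + E_sf^2 + E_fn^2 + E_nf^2)`, the strain expressed in the
#' fiber frame.
#'
#' @param E symmetric Green-Lagrange strain (3 x 3) in fiber coordinates.
#' @param p [guccione_params()].
#' @return energy density (kPa).
#' @export
guccione_energy <- function(E, p = guccione_params()) {
  if (max(abs(E - t(E))) > 1e-8) stop("strain tensor must be symmetric")
  Q <- sum(guccione_B(p) * E^2)
  p$C_scale / 2 * (exp(Q) - 1)
}

# ---- batch kernels (n x 9 row-major tensors) ----------------------------

# passive 2nd Piola-Kirchhoff stress and energy for the Guccione law with
# volumetric penalty, from the right Cauchy-Green tensor C.
#' @noRd
guccione_stress_batch <- function(Cm, R, gp, kappa) {
  J2 <- m3_det(Cm)
  J <- sqrt(J2)
  Cinv <- m3_inv(Cm, J2)
  iso <- J^(-2 / 3)
  Cb <- iso * Cm
  Eb <- Cb / 2
  Eb[, c(1, 5, 9)] <- Eb[, c(1, 5, 9)] - 0.5
  Ehat <- m3_mul(m3_t(R), m3_mul(Eb, R))
  B <- guccione_B(gp)
  bvec <- as.vector(t(B))  # row-major to match tensor storage
  Q <- as.vector(Ehat^2 %*% bvec)
  eQ <- exp(Q)
  Sfib <- gp$C_scale * eQ * sweep(Ehat, 2, bvec, "*")
  Sb <- m3_mul(R, m3_mul(Sfib, m3_t(R)))
  trSC <- m3_dot(Sb, Cm)
  S <- iso * (Sb - (trSC / 3) * Cinv) + kappa * (J - 1) * J * Cinv
  W <- gp$C_scale / 2 * (eQ - 1) + kappa / 2 * (J - 1)^2
  list(S = S, W = W, J = J)
}

# neo-Hookean with volumetric penalty, from C
#' @noRd
neo_hookean_stress_batch <- function(Cm, mu, kappa) {
  J2 <- m3_det(Cm)
  J <- sqrt(J2)
  Cinv <- m3_inv(Cm, J2)
  iso <- J^(-2 / 3)
  trC <- m3_trace(Cm)
  S <- mu * iso * (m3_identity(nrow(Cm)) - (trC / 3) * Cinv) +
    kappa * (J - 1) * J * Cinv
  W <- mu / 2 * (iso * trC - 3) + kappa / 2 * (J - 1)^2
  list(S = S, W = W, J = J)
}

# ---- user-facing point versions -----------------------------------------

#' @noRd
triad_R <- function(triad) {
  if (is.matrix(triad)) return(triad)
  cbind(triad$f, triad$s, triad$n)
}

#' Passive second Piola-Kirchhoff stress (Guccione + penalty)
#'
#' Exact derivative `S = 2 dW/dC` of the isochorically split Guccione energy
#' plus the volumetric penalty `kappa/2 (J - 1)^2`.
#'
#' @param F deformation gradient (3 x 3), `det F > 0`.
#' @param triad 3 x 3 rotation with columns (f, s, n), or a list with those
#'   fields.
#' @param p [guccione_params()].
#' @param k [bulk_penalty()].
#' @return symmetric 3 x 3 stress (kPa).
#' @export
passive_pk2 <- function(F, triad, p = guccione_params(), k = bulk_penalty()) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det F <= 0")
  Cm <- m3_from_mat(t(F) %*% F)
  R <- m3_from_mat(triad_R(triad))
  m3_to_mat(guccione_stress_batch(Cm, R, p, k$kappa)$S)
}

#' Passive strain-energy density at a deformation gradient
#' @inheritParams passive_pk2
#' @return energy density (kPa).
#' @export
passive_energy <- function(F, triad, p = guccione_params(),
                           k = bulk_penalty()) {
  if (det(F) <= 0) stop("element inversion: det F <= 0")
  Cm <- m3_from_mat(t(F) %*% F)
  R <- m3_from_mat(triad_R(triad))
  guccione_stress_batch(Cm, R, p, k$kappa)$W
}

#' Neo-Hookean second Piola-Kirchhoff stress
#' @param F deformation gradient (3 x 3).
#' @param p [neo_hookean_params()].
#' @param k [bulk_penalty()].
#' @return symmetric 3 x 3 stress (kPa).
#' @export
neo_hookean_pk2 <- function(F, p = neo_hookean_params(), k = bulk_penalty()) {
  if (det(F) <= 0) stop("element inversion: det F <= 0")
  Cm <- m3_from_mat(t(F) %*% F)
  m3_to_mat(neo_hookean_stress_batch(Cm, p$mu, k$kappa)$S)
}

#' Neo-Hookean energy density
#' @inheritParams neo_hookean_pk2
#' @export
neo_hookean_energy <- function(F, p = neo_hookean_params(),
                               k = bulk_penalty()) {
  Cm <- m3_from_mat(t(F) %*% F)
  neo_hookean_stress_batch(Cm, p$mu, k$kappa)$W
}

#' Active-tension transient
#'
#' `T_a(t) = T_peak tanh^2((t - t_on)/tau_c) tanh^2((t_off - t)/tau_r)` on
#' `t_on < t < t_off` and 0 outside, with `t_on = t_act + t_emd` and
#' `t_off = t_on + tau_dur`. Continuous in `t`, bounded by `T_peak`.
#'
#' @param t time (ms), vectorized.
#' @param t_act local activation time (ms), scalar or same length as `t`.
#' @param p [active_params()].
#' @return active tension (kPa).
#' @export
active_tension <- function(t, t_act, p = active_params()) {
  t_on <- t_act + p$t_emd
  t_off <- t_on + p$tau_dur
  inside <- t > t_on & t < t_off
  out <- numeric(length(inside))
  Ta <- p$T_peak * tanh((t - t_on) / p$tau_c)^2 *
    tanh((t_off - t) / p$tau_r)^2
  out[inside] <- Ta[inside]
  out
}

#' Active second Piola-Kirchhoff stress
#'
#' `S_a = T_a (f f' + eta s s' + eta n n')` in the reference frame; the
#' eigenvalues are `T_a` along the fiber and `eta T_a` transversely.
#'
#' @param T_a active tension (kPa).
#' @param triad rotation with columns (f, s, n) or a list with those fields.
#' @param eta transverse active-stress fraction.
#' @return symmetric 3 x 3 stress (kPa).
#' @export
active_pk2 <- function(T_a, triad, eta = 0) {
  stopifnot(eta >= 0, eta <= 1)
  R <- triad_R(triad)
  f <- R[, 1]; s <- R[, 2]; n <- R[, 3]
  T_a * (tcrossprod(f) + eta * tcrossprod(s) + eta * tcrossprod(n))
}

# reference active structure tensor per element: f f' + eta (s s' + n n')
#' @noRd
active_structure_batch <- function(fibers, eta) {
  m3_outer(fibers$f) + eta * (m3_outer(fibers$s) + m3_outer(fibers$n))
}
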