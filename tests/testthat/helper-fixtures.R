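# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# coarse biventricle shared by most structural tests
fix_heart <- function() fixture("heart", function() {
  mesh <- build_idealized_biventricle(geometry_params(edge_length = 8))
  coords <- compute_wall_coordinates(mesh)
  fibers <- suppressMessages(assign_rule_based_fibers(mesh, coords))
  list(mesh = mesh, coords = coords, fibers = fibers)
})

# random rotation matrix with det +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# finite-difference second Piola-Kirchhoff stress: 2 dW/dC with symmetric
# central perturbations of C
fd_pk2 <- function(W_of_C, C0, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- h / 2
    dC[j, i] <- dC[j, i] + h / 2
    S[i, j] <- 2 * (W_of_C(C0 + dC) - W_of_C(C0 - dC)) / (2 * h)
  }
  S
}

# the control-pair study at desk scale, computed once and reused by the
# acceptance-style tests (both arms plus shared inputs)
fix_pair <- function() fixture("pair", function() {
  run_control_pair(default_config())
})
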