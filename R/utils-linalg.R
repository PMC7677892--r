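# Batch linear algebra on n x 9 matrices of row-major 3x3 tensors.
# Column order is (11,12,13,21,22,23,31,32,33); helpers below keep all
# element-wise kernels free of R-level loops.

M3_IDX <- matrix(1:9, 3, 3, byrow = TRUE)

#' @noRd
m3_from_mat <- function(A) matrix(as.numeric(t(A)), 1, 9)

#' @noRd
m3_to_mat <- function(a, row = 1) matrix(a[row, ], 3, 3, byrow = TRUE)

#' @noRd
m3_identity <- function(n) {
  out <- matrix(0, n, 9)
  out[, c(1, 5, 9)] <- 1
  out
}

#' @noRd
m3_mul <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    out[, M3_IDX[i, j]] <-
      A[, M3_IDX[i, 1]] * B[, M3_IDX[1, j]] +
      A[, M3_IDX[i, 2]] * B[, M3_IDX[2, j]] +
      A[, M3_IDX[i, 3]] * B[, M3_IDX[3, j]]
  }
  out
}

#' @noRd
m3_t <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

#' @noRd
m3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
    A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
    A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

#' @noRd
m3_inv <- function(A, det = NULL) {
  if (is.null(det)) det <- m3_det(A)
  out <- matrix(0, nrow(A), 9)
  out[, 1] <- A[, 5] * A[, 9] - A[, 6] * A[, 8]
  out[, 2] <- A[, 3] * A[, 8] - A[, 2] * A[, 9]
  out[, 3] <- A[, 2] * A[, 6] - A[, 3] * A[, 5]
  out[, 4] <- A[, 6] * A[, 7] - A[, 4] * A[, 9]
  out[, 5] <- A[, 1] * A[, 9] - A[, 3] * A[, 7]
  out[, 6] <- A[, 3] * A[, 4] - A[, 1] * A[, 6]
  out[, 7] <- A[, 4] * A[, 8] - A[, 5] * A[, 7]
  out[, 8] <- A[, 2] * A[, 7] - A[, 1] * A[, 8]
  out[, 9] <- A[, 1] * A[, 5] - A[, 2] * A[, 4]
  out / det
}

#' @noRd
m3_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

# Frobenius inner product A:B per row
#' @noRd
m3_dot <- function(A, B) rowSums(A * B)

# symmetric outer product v v' for an n x 3 matrix of vectors
#' @noRd
m3_outer <- function(v, w = v) {
  cbind(v[, 1] * w[, 1], v[, 1] * w[, 2], v[, 1] * w[, 3],
        v[, 2] * w[, 1], v[, 2] * w[, 2], v[, 2] * w[, 3],
        v[, 3] * w[, 1], v[, 3] * w[, 2], v[, 3] * w[, 3])
}

#' @noRd
vec3_cross <- function(a, b) {
  out <- matrix(0, nrow(a), 3)
  out[, 1] <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  out[, 2] <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  out[, 3] <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  out
}

#' @noRd
vec3_norm <- function(a) sqrt(rowSums(a * a))

#' @noRd
vec3_normalize <- function(a) {
  n <- vec3_norm(a)
  n[n == 0] <- 1
  a / n
}

# A %*% v rowwise: A n x 9, v n x 3 -> n x 3
#' @noRd
m3_mulvec <- function(A, v) {
  out <- matrix(0, nrow(A), 3)
  out[, 1] <- A[, 1] * v[, 1] + A[, 2] * v[, 2] + A[, 3] * v[, 3]
  out[, 2] <- A[, 4] * v[, 1] + A[, 5] * v[, 2] + A[, 6] * v[, 3]
  out[, 3] <- A[, 7] * v[, 1] + A[, 8] * v[, 2] + A[, 9] * v[, 3]
  out
}

# accumulate rows of `vals` (n x k) into `nbins` rows by index
#' @noRd
rowsum_by <- function(vals, idx, nbins) {
  out <- rowsum(vals, group = idx, reorder = FALSE)
  res <- matrix(0, nbins, ncol(vals))
  res[as.integer(rownames(out)), ] <- out
  res
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
smoothstep <- function(x) {
  x <- clamp(x, 0, 1)
  x * x * (3 - 2 * x)
}
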