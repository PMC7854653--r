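# Independent brute-force oracles used across tests. These deliberately avoid
# the package's vectorized code paths: direct index sums and plain-R loops.

# full double contraction sum_ij B_ij D_ij of two symmetric 3x3 matrices
oracle_double_contraction <- function(B, D) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + B[i, j] * D[i, j]
  s
}

# direct 4-index rotation C'_ijkl = R_ia R_jb R_kc R_ld C_abcd
oracle_rotate_c4 <- function(C, R) {
  Cp <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3)
      s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, d] * C[a, b, cc, d]
    Cp[i, j, k, l] <- s
  }
  Cp
}

# brute-force full symmetrization entering the kurtosis identity
oracle_kurtosis <- function(C, mean_trace) {
  K <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    K[i, j, k, l] <- (C[i, j, k, l] + C[i, k, j, l] + C[i, l, j, k]) /
      mean_trace^2
  K
}

# random symmetric PSD 6x6 covariance of moderate scale
random_psd6 <- function(scale = 0.05) {
  A <- matrix(rnorm(36, sd = scale), 6, 6)
  crossprod(A) / 6
}

# random proper rotation
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# direct (unvectorized) orientation-dispersion evaluation following the mean
# dyadic definition, with the package's degeneracy conventions re-derived
# independently: isotropic members skipped, degenerate pairs spread over
# their eigenspace projector
oracle_v_orient <- function(X, tol = 1e-6) {
  dy <- list(matrix(0, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3))
  used <- 0
  for (s in seq_len(nrow(X))) {
    M <- matrix(c(X[s, 1], X[s, 4], X[s, 5],
                  X[s, 4], X[s, 2], X[s, 6],
                  X[s, 5], X[s, 6], X[s, 3]), 3, 3)
    e <- eigen(M, symmetric = TRUE)
    sc <- max(abs(e$values[1]), 1e-12)
    if (abs(e$values[1] - e$values[3]) <= tol * sc) next
    same <- function(a, b) abs(e$values[a] - e$values[b]) <= tol * sc
    groups <- list()
    if (same(1, 2)) groups <- list(c(1, 2), 3)
    else if (same(2, 3)) groups <- list(1, c(2, 3))
    else groups <- list(1, 2, 3)
    for (g in groups) {
      P <- matrix(0, 3, 3)
      for (i in g) P <- P + tcrossprod(e$vectors[, i])
      for (i in g) dy[[i]] <- dy[[i]] + P / length(g)
    }
    used <- used + 1
  }
  if (used == 0) return(0)
  min(sapply(1:3, function(i) {
    beta <- sort(eigen(dy[[i]] / used, symmetric = TRUE)$values,
                 decreasing = TRUE)
    sqrt(max(0, (beta[2] + beta[3]) / (2 * beta[1])))
  }))
}

# small helper: reference design reused by several expensive tests
tiny_design <- function(n = 60, seed = 11) dtd_design(n = n, seed = seed)
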