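#' Convert between the 6-vector and 3x3 forms of a diffusion tensor
#'
#' The package stores a symmetric diffusion tensor as the 6-vector
#' `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` (units micrometre^2/ms), each off-diagonal
#' component stored once. `dt_matrix()` reconstructs the symmetric 3x3 form;
#' `dt_vector()` extracts the 6-vector and errors on non-symmetric input.
#'
#' @param d6 numeric length-6 vector `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @param M symmetric 3x3 matrix.
#' @param tol relative asymmetry tolerance for `dt_vector()`.
#' @return `dt_matrix()` a 3x3 symmetric matrix; `dt_vector()` a named
#'   length-6 vector. The round trip is exact.
#' @examples
#' dt_matrix(c(1, 1, 1, 0, 0, 0))          # identity tensor
#' dt_vector(diag(c(1, 2, 3)))
#' @export
dt_matrix <- function(d6) {
  stopifnot(is.numeric(d6), length(d6) == 6L)
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3L, 3L)
}

#' @rdname dt_matrix
#' @export
dt_vector <- function(M, tol = 1e-10) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)))
  scale <- max(abs(M), 1)
  if (max(abs(M - t(M))) > tol * scale)
    stop("input 3x3 matrix is not symmetric (relative asymmetry > ", tol, ")")
  M <- (M + t(M)) / 2
  setNames(c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3]), .d6_names)
}

#' Eigenvalues of a tensor in 6-vector form
#' @param d6 length-6 tensor.
#' @return eigenvalues, decreasing.
#' @keywords internal
dt_eigenvalues <- function(d6) eigen(dt_matrix(d6), symmetric = TRUE, only.values = TRUE)$values

#' Is a diffusion tensor physical (positive semidefinite)?
#'
#' A tensor is "physical" when all eigenvalues of its 3x3 form are at least
#' `-1e-12 * max(1, largest eigenvalue)`, i.e. non-negative up to float noise.
#'
#' @param d6 length-6 tensor, or an n x 6 matrix of tensors (one per row).
#' @return logical (vector for matrix input).
#' @export
is_physical <- function(d6) {
  if (is.matrix(d6)) {
    stopifnot(ncol(d6) == 6L)
    return(as.logical(cpp_psd_filter(d6, .psd_tol)))
  }
  ev <- dt_eigenvalues(d6)
  all(ev >= -.psd_tol * max(1, ev[1]))
}

#' Convert a 3x3 b-matrix to its doubled 6-vector form
#'
#' Returns `(bxx, byy, bzz, 2*bxy, 2*bxz, 2*byz)` so that the inner product
#' `b6 . d6` equals the full double contraction `sum_ij B_ij D_ij` of the 3x3
#' forms: the factor-2 bookkeeping for symmetric off-diagonals lives entirely
#' in the b-vector.
#'
#' @param B symmetric positive-semidefinite 3x3 b-matrix (ms/micrometre^2).
#' @param tol relative tolerance on negative eigenvalues.
#' @return length-6 numeric b-vector.
#' @examples
#' bvec_from_bmatrix(diag(c(1, 2, 3)))
#' @export
bvec_from_bmatrix <- function(B, tol = .psd_tol) {
  stopifnot(is.matrix(B), all(dim(B) == c(3L, 3L)))
  if (max(abs(B - t(B))) > 1e-10 * max(1, max(abs(B))))
    stop("b-matrix must be symmetric")
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(ev)))
    stop("b-matrix has a negative eigenvalue beyond tolerance (not PSD)")
  c(B[1, 1], B[2, 2], B[3, 3], 2 * B[1, 2], 2 * B[1, 3], 2 * B[2, 3])
}

#' Map between the 6x6 covariance matrix and the fourth-order tensor
#'
#' `omega_to_ctensor()` expands a symmetric 6x6 covariance matrix Omega (entries
#' `Cov(D_ij, D_kl)` in the fixed `(xx, yy, zz, xy, xz, yz)` ordering) into the
#' full 3x3x3x3 fourth-order covariance tensor `C[i,j,k,l]`, which then carries
#' the minor symmetries `C_ijkl = C_jikl = C_ijlk` and the major symmetry
#' `C_ijkl = C_klij`. `ctensor_to_omega()` inverts the map exactly and errors
#' if a minor symmetry is broken.
#'
#' @param omega symmetric 6x6 matrix.
#' @param C 3x3x3x3 array with minor symmetries.
#' @param tol symmetry tolerance.
#' @return the other representation.
#' @export
omega_to_ctensor <- function(omega) {
  stopifnot(is.matrix(omega), all(dim(omega) == c(6L, 6L)))
  if (max(abs(omega - t(omega))) > 1e-10 * max(1, max(abs(omega))))
    stop("omega must be symmetric")
  vm <- matrix(0L, 3L, 3L)
  for (a in 1:6) {
    vm[.d6_idx[a, 1], .d6_idx[a, 2]] <- a
    vm[.d6_idx[a, 2], .d6_idx[a, 1]] <- a
  }
  C <- array(0, c(3L, 3L, 3L, 3L))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C[i, j, k, l] <- omega[vm[i, j], vm[k, l]]
  C
}

#' @rdname omega_to_ctensor
#' @export
ctensor_to_omega <- function(C, tol = 1e-10) {
  stopifnot(is.array(C), all(dim(C) == c(3L, 3L, 3L, 3L)))
  scale <- max(abs(C), 1)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    if (abs(C[i, j, k, l] - C[j, i, k, l]) > tol * scale ||
        abs(C[i, j, k, l] - C[i, j, l, k]) > tol * scale)
      stop("fourth-order tensor lacks the minor symmetries C_ijkl = C_jikl = C_ijlk")
  }
  omega <- matrix(0, 6L, 6L)
  for (a in 1:6) for (b in 1:6)
    omega[a, b] <- C[.d6_idx[a, 1], .d6_idx[a, 2], .d6_idx[b, 1], .d6_idx[b, 2]]
  (omega + t(omega)) / 2
}

#' Euler-angle rotation matrix
#'
#' Composes single-axis rotations in the order named by `order`; the default
#' `"XYZ"` gives `R = X(alpha) %*% Y(beta) %*% Z(gamma)`. Angles are radians.
#'
#' @param alpha,beta,gamma rotation angles (radians) applied to the first,
#'   second and third axis named in `order`.
#' @param order 3-character permutation of "X", "Y", "Z".
#' @return proper 3x3 rotation matrix (`t(R) %*% R = I`, `det(R) = 1`).
#' @examples
#' euler_rotation(pi / 2, 0, 0)  # +90 degrees about x: y -> z
#' @export
euler_rotation <- function(alpha, beta, gamma, order = "XYZ") {
  ax <- strsplit(toupper(order), "")[[1]]
  if (length(ax) != 3L || !setequal(ax, c("X", "Y", "Z")))
    stop("order must be a permutation of XYZ")
  one <- function(axis, a) {
    ca <- cos(a); sa <- sin(a)
    switch(axis,
      X = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
      Y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
      Z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
  }
  one(ax[1], alpha) %*% one(ax[2], beta) %*% one(ax[3], gamma)
}

#' Second-order rotation acting on tensor 6-vectors
#'
#' Returns the 6x6 matrix `M` with `M %*% d6(A) = d6(R A t(R))` under the
#' package's plain component scaling. Note `M` is not orthogonal in this
#' scaling (it is orthogonal in Mandel scaling).
#'
#' @param R 3x3 rotation matrix.
#' @return 6x6 matrix.
#' @export
rotation_matrix_d6 <- function(R) {
  stopifnot(all(dim(R) == c(3L, 3L)))
  # explicit Bond-transformation entries for the plain (unscaled) convention
  M <- matrix(0, 6L, 6L)
  pr <- .d6_idx
  for (a in 1:6) {
    i <- pr[a, 1]; j <- pr[a, 2]
    if (i == j) {
      M[a, 1:3] <- R[i, 1:3]^2
      M[a, 4] <- 2 * R[i, 1] * R[i, 2]
      M[a, 5] <- 2 * R[i, 1] * R[i, 3]
      M[a, 6] <- 2 * R[i, 2] * R[i, 3]
    } else {
      M[a, 1:3] <- R[i, 1:3] * R[j, 1:3]
      M[a, 4] <- R[i, 1] * R[j, 2] + R[i, 2] * R[j, 1]
      M[a, 5] <- R[i, 1] * R[j, 3] + R[i, 3] * R[j, 1]
      M[a, 6] <- R[i, 2] * R[j, 3] + R[i, 3] * R[j, 2]
    }
  }
  M
}

#' Rotate a fourth-order covariance tensor
#'
#' Applies `C'_ijkl = R_ia R_jb R_kc R_ld C_abcd`. Accepts and returns either
#' the 6x6 matrix form or the 3x3x3x3 array form (matching the input). The
#' rotation preserves the eigenvalues of the Mandel-scaled 6x6 form (the
#' orthogonal representation); the plain-scaled spectrum is not an invariant.
#'
#' @param C 6x6 symmetric matrix or 3x3x3x3 array with minor+major symmetry.
#' @param R 3x3 proper rotation.
#' @return rotated tensor, same representation as the input.
#' @export
rotate_fourth_order <- function(C, R) {
  as_array <- is.array(C) && length(dim(C)) == 4L
  omega <- if (as_array) ctensor_to_omega(C) else C
  M <- rotation_matrix_d6(R)
  out <- M %*% omega %*% t(M)
  out <- (out + t(out)) / 2
  if (as_array) omega_to_ctensor(out) else out
}

#' Mandel-scaled form of a plain 6x6 covariance matrix
#'
#' Rescales off-diagonal tensor components by sqrt(2) on each index, giving the
#' representation in which rotations act orthogonally and whose spectrum is a
#' rotation invariant.
#' @param omega plain-scaled symmetric 6x6 matrix.
#' @return Mandel-scaled 6x6 matrix.
#' @export
mandel_form <- function(omega) {
  s <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  omega * tcrossprod(s)
}

# inverse of mandel_form
.unmandel <- function(omega_m) {
  s <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  omega_m / tcrossprod(s)
}

# Symmetric PSD square root of a plain-scaled covariance: clip negative
# eigenvalues in Mandel coordinates (class-preserving: spectral functions
# commute with the orthogonal rotation representation), then map back.
# Returns L with L %*% t(L) equal to the clipped omega.
.psd_factor <- function(omega) {
  om <- mandel_form((omega + t(omega)) / 2)
  e <- eigen(om, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lam[lam < 1e-12 * max(lam, 0)] <- 0   # float dust would pollute sqrt()
  Lm <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  s <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  (1 / s) * Lm   # row scaling: L_plain = S^-1 L_mandel
}

# clip a plain-scaled covariance to the PSD cone (in Mandel coordinates)
.psd_clip <- function(omega) {
  om <- mandel_form((omega + t(omega)) / 2)
  e <- eigen(om, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lam[lam < 1e-12 * max(lam, 0)] <- 0
  .unmandel(e$vectors %*% (lam * t(e$vectors)))
}

#' Check a 6x6 covariance for positive semidefiniteness
#' @param omega symmetric 6x6 matrix.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @return logical.
#' @export
is_psd_omega <- function(omega, tol = 1e-10) {
  ev <- eigen(mandel_form((omega + t(omega)) / 2), symmetric = TRUE,
              only.values = TRUE)$values
  min(ev) >= -tol * max(1, max(ev))
}
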