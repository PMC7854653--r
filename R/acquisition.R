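#' Random rank-1/rank-2 b-matrix acquisition design
#'
#' Generates a compressed-sensing style set of diffusion-encoding b-matrices
#' uniform in size, shape, and orientation: the trace (total b-value) is drawn
#' uniformly over `b_range`; rank-2 matrices draw their eigenvalue ratio
#' `lambda2/lambda1` uniformly on (0, 1]; orientations come from uniform Euler
#' angles with a randomly permuted rotation order (set `haar = TRUE` for
#' exactly uniform random rotations instead). One exact b = 0 measurement is
#' always included first to anchor `s0`.
#'
#' @param n total number of b-matrices including the b = 0 anchor (>= 28, so
#'   the largest 28-parameter model is identifiable). Default 216.
#' @param b_range trace range `(b_min, b_max)` in ms/micrometre^2.
#' @param rank_mix fraction of diffusion-weighted matrices with rank 1 (the
#'   remainder are rank 2).
#' @param seed integer seed.
#' @param haar use exactly uniform (Haar) random rotations instead of uniform
#'   Euler angles with random rotation order.
#' @return object of class `"dtd_design"`: a data frame with columns `id`,
#'   `rank`, plain matrix entries `bxx ... byz`, and `trace`, plus attributes
#'   `b_range`, `rank_mix`, `seed`.
#' @examples
#' des <- dtd_design(n = 60, seed = 1)
#' table(des$rank)
#' @export
dtd_design <- function(n = 216L, b_range = c(0, 5), rank_mix = 0.5, seed = 1L,
                       haar = FALSE) {
  stopifnot(n >= 28L, length(b_range) == 2L, b_range[2] > b_range[1],
            b_range[1] >= 0, rank_mix >= 0, rank_mix <= 1)
  set.seed(as.integer(seed))
  n_dw <- n - 1L
  n1 <- round(rank_mix * n_dw)
  ranks <- sample(c(rep(1L, n1), rep(2L, n_dw - n1)))
  rows <- matrix(0, n, 6L)
  tr <- numeric(n)
  rk <- c(0L, ranks)
  for (i in seq_len(n_dw)) {
    b_tot <- runif(1, b_range[1], b_range[2])
    if (ranks[i] == 1L) {
      lam <- c(b_tot, 0, 0)
    } else {
      rho <- runif(1)                      # lambda2 / lambda1 in (0, 1]
      l1 <- b_tot / (1 + rho)
      lam <- c(l1, rho * l1, 0)
    }
    if (haar) {
      # uniform rotation via QR of a Gaussian matrix (sign-fixed)
      Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      R <- Q
    } else {
      ord <- paste(sample(c("X", "Y", "Z")), collapse = "")
      R <- euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                          runif(1, 0, 2 * pi), order = ord)
    }
    B <- R %*% diag(lam) %*% t(R)
    rows[i + 1L, ] <- c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
    tr[i + 1L] <- b_tot
  }
  out <- data.frame(id = seq_len(n), rank = rk,
                    bxx = rows[, 1], byy = rows[, 2], bzz = rows[, 3],
                    bxy = rows[, 4], bxz = rows[, 5], byz = rows[, 6],
                    trace = tr)
  structure(out, b_range = b_range, rank_mix = rank_mix, seed = as.integer(seed),
            class = c("dtd_design", "data.frame"))
}

#' 3x3 b-matrix for one design row
#' @param design a `dtd_design`.
#' @param i row index.
#' @return symmetric 3x3 matrix.
#' @export
design_bmatrix <- function(design, i) {
  r <- design[i, ]
  matrix(c(r$bxx, r$bxy, r$bxz,
           r$bxy, r$byy, r$byz,
           r$bxz, r$byz, r$bzz), 3, 3)
}

#' Doubled b-vectors of a design
#'
#' Returns the N x 6 matrix of `(bxx, byy, bzz, 2bxy, 2bxz, 2byz)` rows, the
#' form contracted directly against tensor 6-vectors.
#' @param design a `dtd_design` (or data frame with the design columns).
#' @return N x 6 numeric matrix.
#' @export
design_bvecs <- function(design) {
  cbind(design$bxx, design$byy, design$bzz,
        2 * design$bxy, 2 * design$bxz, 2 * design$byz)
}

#' Audit the uniformity and covariance coverage of a design
#'
#' Quantifies the design's three uniformity properties (trace, eigenvalue
#' ratio, orientation of the principal eigenvector) and the rank of the linear
#' map from the 21-dimensional covariance space to the signal's quadratic
#' form: each b-matrix contributes the row of coefficients of the 21 unique
#' covariance entries in `t(b6) %*% Omega %*% b6`. Rank 21 means the design
#' determines every covariance component; rank-1-only designs are deficient.
#'
#' @param design a `dtd_design`.
#' @return list with `trace` values, `shape_ratio` (rank-2 rows), `principal`
#'   (N x 3 principal eigenvectors), `orientation_dispersion` (eigenvalues of
#'   the mean dyadic of principal eigenvectors), `cov_design_rank` and the
#'   `cov_design` matrix itself.
#' @export
audit_design <- function(design) {
  stopifnot(nrow(design) >= 1L)
  dw <- design[design$rank > 0L, , drop = FALSE]
  ratios <- c(); pax <- matrix(0, nrow(dw), 3L)
  for (i in seq_len(nrow(dw))) {
    B <- design_bmatrix(dw, i)
    e <- eigen(B, symmetric = TRUE)
    pax[i, ] <- e$vectors[, 1]
    if (dw$rank[i] == 2L) ratios <- c(ratios, e$values[2] / e$values[1])
  }
  dyad <- crossprod(pax) / max(1L, nrow(pax))
  Bv <- design_bvecs(dw)
  # coefficients of the 21 unique omega entries in b6' Omega b6
  cols <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  X <- matrix(0, nrow(Bv), nrow(cols))
  for (k in seq_len(nrow(cols))) {
    a <- cols[k, 1]; b <- cols[k, 2]
    X[, k] <- if (a == b) Bv[, a]^2 else 2 * Bv[, a] * Bv[, b]
  }
  list(trace = dw$trace, shape_ratio = ratios, principal = pax,
       orientation_dispersion = eigen(dyad, symmetric = TRUE)$values,
       cov_design_rank = qr(X, tol = 1e-9)$rank, cov_design = X)
}
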