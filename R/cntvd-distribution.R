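#' Constrained normal tensor-variate distribution (CNTVD) parameters
#'
#' Bundles the mean diffusion tensor (6-vector, micrometre^2/ms), the
#' fourth-order covariance tensor as a symmetric 6x6 matrix
#' ((micrometre^2/ms)^2, plain component scaling), and the non-diffusion
#' weighted signal amplitude `s0`. The pair `(mean, omega)` parameterizes the
#' *untruncated* 6-D Gaussian; the distribution itself is that Gaussian
#' restricted to the positive-semidefinite cone by rejection. The reported
#' parameters are therefore not the moments of the truncated law (the two
#' coincide as the covariance shrinks or moves away from the cone boundary).
#'
#' @param mean length-6 mean tensor `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` or a
#'   symmetric 3x3 matrix.
#' @param omega symmetric positive-semidefinite 6x6 covariance matrix
#'   (possibly singular, e.g. rank-1 for emulsions). Default zero.
#' @param s0 signal amplitude at b = 0 (arbitrary units).
#' @return an object of class `"cntvd"` with elements `mean` (length-6),
#'   `omega` (6x6) and `s0`.
#' @examples
#' p <- cntvd(0.8 * diag(3), omega_isotropic(lambda = 0.01, mu = 0.005))
#' p
#' @export
cntvd <- function(mean, omega = matrix(0, 6, 6), s0 = 1) {
  if (is.matrix(mean) && all(dim(mean) == c(3L, 3L))) mean <- dt_vector(mean)
  stopifnot(length(mean) == 6L, is.matrix(omega), all(dim(omega) == c(6L, 6L)),
            is.numeric(s0), length(s0) == 1L, s0 >= 0)
  mean <- as.numeric(mean)
  ev <- dt_eigenvalues(mean)
  if (min(ev) < -.psd_tol * max(1, max(ev)))
    stop("mean tensor must itself be physical (positive semidefinite)")
  if (!is_psd_omega(omega))
    stop("omega must be positive semidefinite (up to tolerance)")
  structure(list(mean = setNames(mean, .d6_names),
                 omega = (omega + t(omega)) / 2, s0 = s0),
            class = "cntvd")
}

#' @export
print.cntvd <- function(x, ...) {
  cat("CNTVD parameters (units: mean um^2/ms, covariance (um^2/ms)^2)\n")
  cat("  s0:", format(x$s0), "\n")
  cat("  mean tensor (eigenvalues):",
      paste(format(round(dt_eigenvalues(x$mean), 4)), collapse = ", "), "\n")
  cat("  mean 6-vector:", paste(format(round(x$mean, 4)), collapse = ", "), "\n")
  evo <- eigen(mandel_form(x$omega), symmetric = TRUE, only.values = TRUE)$values
  cat("  covariance rank:", sum(evo > 1e-10 * max(1, max(evo))),
      " | Mandel eigenvalues:", paste(format(round(evo, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Isotropic fourth-order covariance template
#'
#' `C_ijkl = lambda d_ij d_kl + mu (d_ik d_jl + d_il d_jk)`: the two-constant
#' isotropic class (analogous to bulk/shear moduli). In the plain 6x6 form the
#' upper 3x3 block has diagonal `lambda + 2 mu` and off-diagonal `lambda`; the
#' lower diagonal is `mu`.
#'
#' @param lambda,mu isotropic constants ((micrometre^2/ms)^2).
#' @return symmetric 6x6 matrix.
#' @export
omega_isotropic <- function(lambda, mu = 0) {
  J <- matrix(0, 6, 6)
  J[1:3, 1:3] <- lambda
  J + diag(c(2, 2, 2, 1, 1, 1)) * mu
}

#' Draw micro diffusion tensors from a CNTVD
#'
#' Draws `n` proposals `mean + L z` (`z` standard normal 6-vectors, `L` the
#' symmetric PSD square root of omega, computed in Mandel scaling so singular
#' covariances are handled by eigenvalue clipping) and keeps the proposals
#' whose 3x3 form has all eigenvalues >= -1e-12. Deterministic for a fixed
#' seed.
#'
#' @param params a [cntvd] object.
#' @param n number of proposals (>= 1).
#' @param seed integer seed for the standard-normal block.
#' @param z optional pre-drawn n x 6 standard normal matrix (common random
#'   numbers); overrides `seed`.
#' @return an object of class `"dtd_ensemble"`: list with `samples` (n_acc x 6
#'   matrix of accepted tensors), `n_proposed`, `acc_frac`, `seed`.
#' @examples
#' p <- cntvd(0.8 * diag(3), omega_isotropic(0.01, 0.005))
#' e <- sample_cntvd(p, 5000, seed = 1)
#' e$acc_frac
#' @export
sample_cntvd <- function(params, n, seed = 1L, z = NULL) {
  stopifnot(inherits(params, "cntvd"), n >= 1)
  if (is.null(z)) {
    set.seed(as.integer(seed))
    z <- matrix(rnorm(n * 6L), n, 6L)
  } else {
    stopifnot(is.matrix(z), ncol(z) == 6L)
    n <- nrow(z)
  }
  L <- .psd_factor(params$omega)
  D <- z %*% t(L)
  D <- sweep(D, 2L, params$mean, "+")
  keep <- as.logical(cpp_psd_filter(D, .psd_tol))
  acc <- mean(keep)
  if (acc < 1e-4)
    stop("distribution mass almost entirely outside the PSD cone ",
         "(acceptance fraction ", format(acc), ")")
  if (acc < 0.05)
    warning("low acceptance fraction (", format(acc),
            "): heavy truncation, reported parameters are far from the ",
            "truncated moments")
  samples <- D[keep, , drop = FALSE]
  colnames(samples) <- .d6_names
  structure(list(samples = samples, n_proposed = n, acc_frac = acc,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "dtd_ensemble")
}

#' @export
print.dtd_ensemble <- function(x, ...) {
  cat("DTD ensemble:", nrow(x$samples), "accepted of", x$n_proposed,
      "proposals (acceptance", format(round(x$acc_frac, 4)), ")\n")
  invisible(x)
}

# coerce ensembles / matrices to an n x 6 sample matrix
as_sample_matrix <- function(x) {
  if (inherits(x, "dtd_ensemble")) return(x$samples)
  if (inherits(x, "dtd_motif")) return(x$ensemble$samples)
  if (is.matrix(x) && ncol(x) == 6L) return(x)
  stop("expected a dtd_ensemble, dtd_motif, or n x 6 matrix of tensors")
}

#' Log density of the CNTVD
#'
#' Evaluates the log of the constrained Gaussian density: quadratic form of
#' the untruncated Gaussian minus the log normalizer, where the normalizer is
#' the Gaussian constant times the acceptance probability of the PSD cone,
#' estimated once by Monte Carlo with `n_norm` proposals. Non-physical tensors
#' have density zero (`-Inf`). For singular covariance the density only exists
#' on the support subspace `mean + range(omega)`; set `subspace = TRUE` to
#' evaluate it there with the pseudo-inverse and pseudo-determinant (a point
#' off the support returns `-Inf`).
#'
#' @param params a [cntvd] object.
#' @param D length-6 tensor or n x 6 matrix of evaluation points.
#' @param n_norm Monte Carlo proposals for the acceptance probability.
#' @param seed seed for the normalizer estimate.
#' @param subspace evaluate singular covariances on their support subspace.
#' @return log density value(s).
#' @export
cntvd_log_density <- function(params, D, n_norm = 100000L, seed = 1L,
                              subspace = FALSE) {
  stopifnot(inherits(params, "cntvd"))
  if (!is.matrix(D)) D <- matrix(D, 1L, 6L)
  stopifnot(ncol(D) == 6L)
  om <- mandel_form(params$omega)
  e <- eigen(om, symmetric = TRUE)
  pos <- e$values > 1e-12 * max(1, max(e$values))
  r <- sum(pos)
  if (r < 6L && !subspace)
    stop("omega is singular; pass subspace = TRUE to evaluate the density ",
         "on its support subspace")
  # acceptance probability of the PSD cone under the untruncated Gaussian
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_norm * 6L), n_norm, 6L)
  L <- .psd_factor(params$omega)
  P <- sweep(z %*% t(L), 2L, params$mean, "+")
  p_acc <- mean(as.logical(cpp_psd_filter(P, .psd_tol)))
  if (p_acc <= 0) stop("no Monte Carlo proposal fell inside the PSD cone")
  s <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  V <- e$vectors[, pos, drop = FALSE]
  lam <- e$values[pos]
  logdet <- sum(log(lam))
  out <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    d6 <- D[i, ]
    if (!is_physical(d6)) { out[i] <- -Inf; next }
    q_m <- s * (d6 - params$mean)        # Mandel coordinates of the deviation
    y <- crossprod(V, q_m)               # coordinates on the support
    resid <- q_m - V %*% y
    if (r < 6L && sqrt(sum(resid^2)) > 1e-6 * max(1, sqrt(sum(q_m^2)))) {
      out[i] <- -Inf; next
    }
    out[i] <- -0.5 * sum(y^2 / lam) - 0.5 * (r * log(2 * pi) + logdet) -
      log(p_acc)
  }
  out
}

#' Empirical mean and covariance of a tensor ensemble
#'
#' Sample mean 6-vector and sample 6x6 covariance (denominator `n - 1`) of the
#' accepted micro tensors.
#'
#' @param ensemble a `dtd_ensemble`, `dtd_motif`, or n x 6 matrix.
#' @return list with `mean` (length-6) and `omega` (6x6).
#' @export
empirical_moments <- function(ensemble) {
  X <- as_sample_matrix(ensemble)
  if (nrow(X) < 1L) stop("empty ensemble")
  if (nrow(X) < 2L) stop("covariance undefined for a single tensor (n = 1)")
  list(mean = setNames(colMeans(X), .d6_names), omega = cov(X))
}
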