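#' Fractional anisotropy of a diffusion tensor
#' @param d6 length-6 tensor or 3x3 matrix.
#' @return FA in `[0, 1]`.
#' @export
fa <- function(d6) {
  ev <- if (is.matrix(d6)) eigen(d6, symmetric = TRUE, only.values = TRUE)$values
        else dt_eigenvalues(d6)
  s2 <- sum(ev^2)
  if (s2 == 0) return(0)
  sqrt(1.5 * sum((ev - mean(ev))^2) / s2)
}

#' Ensemble average of a per-tensor function
#'
#' The indicator-weighted micro average: `f` evaluated on every accepted
#' micro tensor and averaged. Built-ins: `"fa"` (micro-FA), `"odf_entropy"`
#' (per-tensor ODF entropy), `"neg_log_density"` (overall DTD entropy; needs
#' `params`). Any function of a length-6 tensor may be passed instead.
#'
#' @param ensemble a `dtd_ensemble`, `dtd_motif`, or n x 6 matrix; or a
#'   [cntvd] object (an ensemble of `n` tensors is drawn from it first).
#' @param f built-in name or function.
#' @param grid [sphere_grid] for ODF-based functions.
#' @param params [cntvd] parameters for `"neg_log_density"`.
#' @param n,seed ensemble size and seed when `ensemble` is a `cntvd`.
#' @return scalar micro average.
#' @export
micro_average <- function(ensemble, f = "fa", grid = NULL, params = NULL,
                          n = 20000L, seed = 1L) {
  if (inherits(ensemble, "cntvd")) {
    params <- if (is.null(params)) ensemble else params
    ensemble <- sample_cntvd(ensemble, n = n, seed = seed)
  }
  X <- as_sample_matrix(ensemble)
  if (nrow(X) == 0L) stop("empty ensemble")
  if (is.function(f)) return(mean(apply(X, 1L, f)))
  switch(f,
    fa = mean(apply(X, 1L, fa)),
    odf_entropy = {
      if (is.null(grid)) grid <- sphere_grid()
      mean(apply(X, 1L, function(d) odf_entropy(d, grid)))
    },
    neg_log_density = {
      if (is.null(params)) stop("params needed for the density-based entropy")
      mean(-cntvd_log_density(params, X, subspace = TRUE))
    },
    stop("unknown micro function: ", f))
}

#' Size heterogeneity stain
#'
#' Standard deviation of the mean ADC `(Dxx + Dyy + Dzz) / 3` implied by the
#' covariance: the square root of the arithmetic average of the upper 3x3
#' block of omega (the projection identity with the isotropic 1/3 vector).
#' Zero for uniformly sized tensors. Units micrometre^2/ms.
#'
#' @param omega symmetric PSD 6x6 covariance (or `cntvd`, or an ensemble
#'   whose empirical covariance is used).
#' @return non-negative scalar.
#' @export
v_size <- function(omega) {
  if (inherits(omega, "cntvd")) omega <- omega$omega
  if (!(is.matrix(omega) && all(dim(omega) == c(6, 6))))
    omega <- empirical_moments(omega)$omega
  s <- sum(omega[1:3, 1:3]) / 9
  if (s < -1e-12) stop("negative upper-block average: omega is not PSD")
  sqrt(max(s, 0))
}

# eigen-decomposition with degeneracy grouping for the orientation stain
.eig_groups <- function(M, tol = 1e-6) {
  e <- eigen(M, symmetric = TRUE)
  ev <- e$values
  scale <- max(abs(ev[1]), 1e-12)
  grp <- integer(3); g <- 1L; grp[1] <- 1L
  for (i in 2:3) {
    if (abs(ev[i - 1] - ev[i]) <= tol * scale) grp[i] <- g
    else { g <- g + 1L; grp[i] <- g }
  }
  list(values = ev, vectors = e$vectors, groups = grp)
}

#' Shape heterogeneity stain
#'
#' Root sum of the variances of the eigenvalue ratios `lambda2/lambda1` and
#' `lambda3/lambda2` (eigenvalues sorted decreasing) over the ensemble.
#' Rotation of members does not change it; it is zero iff all members share
#' both ratios. Degenerate tensors: if `lambda2 = 0` (hence `lambda3 = 0`)
#' the second ratio is taken as 1 (equal shapes); if `lambda1 = 0` the tensor
#' is the null tensor and both ratios are 1.
#'
#' @param ensemble a `dtd_ensemble`, `dtd_motif` or n x 6 matrix.
#' @return non-negative scalar (dimensionless).
#' @export
v_shape <- function(ensemble) {
  X <- as_sample_matrix(ensemble)
  r <- t(apply(X, 1L, function(d) {
    ev <- dt_eigenvalues(d)
    tol <- 1e-12 * max(abs(ev[1]), 1)
    if (ev[1] <= tol) return(c(1, 1))
    r1 <- ev[2] / ev[1]
    r2 <- if (ev[2] <= tol) 1 else ev[3] / ev[2]
    c(r1, r2)
  }))
  sqrt(max(var(r[, 1]), 0) + max(var(r[, 2]), 0))
}

#' Orientation heterogeneity stain
#'
#' For each eigenvector label i = 1, 2, 3 (eigenvalues sorted decreasing),
#' the mean dyadic tensor of the i-th eigenvector over the ensemble is formed
#' and its eigenvalues `beta1 > beta2 > beta3` summarize the dispersion:
#' `sqrt((beta2 + beta3) / (2 beta1))`, minimized over i. Zero for
#' coherently oriented tensors, one for uniformly random orientations,
#' independent of size and shape.
#'
#' Degeneracy conventions (a member with equal eigenvalues has no unique
#' eigenvectors): members that are isotropic within tolerance carry no
#' orientation information and are excluded from the averages (all excluded:
#' the stain is 0); a degenerate eigenvalue pair contributes its eigenspace
#' projector divided by 2 to both labels instead of two arbitrary vectors.
#'
#' @param ensemble a `dtd_ensemble`, `dtd_motif` or n x 6 matrix.
#' @param tol relative eigenvalue-degeneracy tolerance.
#' @return scalar in `[0, 1]`.
#' @export
v_orient <- function(ensemble, tol = 1e-6) {
  X <- as_sample_matrix(ensemble)
  dy <- array(0, c(3L, 3L, 3L))  # mean dyadic per label
  n_used <- 0L
  degenerate_seen <- FALSE
  for (s in seq_len(nrow(X))) {
    eg <- .eig_groups(dt_matrix(X[s, ]), tol)
    if (eg$groups[3] == 1L) next       # isotropic member: no orientation info
    if (max(table(eg$groups)) > 1L) degenerate_seen <- TRUE
    for (g in unique(eg$groups)) {
      ix <- which(eg$groups == g)
      P <- tcrossprod(eg$vectors[, ix, drop = FALSE]) / length(ix)
      for (i in ix) dy[, , i] <- dy[, , i] + P
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(0)
  vals <- vapply(1:3, function(i) {
    beta <- eigen(dy[, , i] / n_used, symmetric = TRUE,
                  only.values = TRUE)$values
    if (beta[1] <= 0) return(1)
    sqrt(max(0, (beta[2] + beta[3]) / (2 * beta[1])))
  }, 1)
  min(vals)
}

#' Microstructural stain report
#'
#' Computes the full panel of microstructure stains for an ensemble (and, for
#' the density-based entropy, its CNTVD parameters): micro-FA, FA of the mean
#' tensor, size/shape/orientation heterogeneity stains, DTD entropy and mean
#' per-tensor ODF entropy.
#'
#' @param x a `dtd_motif`, `dtd_ensemble`, n x 6 matrix, [cntvd] or
#'   [dtd_fit] (the latter two draw an ensemble first).
#' @param grid [sphere_grid] for the ODF entropy (NULL skips it for speed).
#' @param entropy compute the density-based DTD entropy (needs parameters).
#' @param n,seed ensemble size/seed when drawing from parameters.
#' @return object of class `"dtd_stains"`: named list with `mu_fa`,
#'   `fa_of_mean`, `v_size`, `v_shape`, `v_orient`, `entropy`,
#'   `odf_entropy_micro`.
#' @examples
#' m <- dtd_motif("iso_emulsion", n = 4000, seed = 1)
#' dtd_stains(m)
#' @export
dtd_stains <- function(x, grid = NULL, entropy = FALSE, n = 20000L,
                       seed = 1L) {
  params <- NULL
  if (inherits(x, "dtd_fit")) x <- x$params
  if (inherits(x, "cntvd")) {
    params <- x
    x <- sample_cntvd(x, n = n, seed = seed)
  }
  if (inherits(x, "dtd_motif")) {
    params <- x$params
    x <- x$ensemble
  }
  X <- as_sample_matrix(x)
  mom <- empirical_moments(X)
  out <- list(
    mu_fa = micro_average(X, "fa"),
    fa_of_mean = fa(mom$mean),
    v_size = if (!is.null(params)) v_size(params$omega) else v_size(mom$omega),
    v_shape = v_shape(X),
    v_orient = v_orient(X),
    entropy = if (entropy && !is.null(params))
      micro_average(X, "neg_log_density", params = params) else NA_real_,
    odf_entropy_micro = if (!is.null(grid))
      micro_average(X, "odf_entropy", grid = grid) else NA_real_)
  structure(out, class = "dtd_stains")
}

#' @export
print.dtd_stains <- function(x, ...) {
  cat("Microstructural stains\n")
  cat("  micro-FA:    ", format(round(x$mu_fa, 4)),
      "   FA(mean):", format(round(x$fa_of_mean, 4)), "\n")
  cat("  V_size:      ", format(round(x$v_size, 4)), "um^2/ms\n")
  cat("  V_shape:     ", format(round(x$v_shape, 4)), "\n")
  cat("  V_orient:    ", format(round(x$v_orient, 4)), "\n")
  if (!is.na(x$entropy)) cat("  DTD entropy: ", format(round(x$entropy, 4)), "\n")
  if (!is.na(x$odf_entropy_micro))
    cat("  mean ODF entropy:", format(round(x$odf_entropy_micro, 4)), "\n")
  invisible(x)
}
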