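#' Synthetic diffusion-tensor-distribution motifs
#'
#' Builds the micro-tensor ensembles used throughout the package as ground
#' truth: gray-matter motifs (isotropic emulsion, shape-heterogeneous,
#' fully heterogeneous) and white-matter motifs (anisotropic emulsion,
#' transverse-size-heterogeneous fiber bundle, 90-degree crossing fibers),
#' plus a uniform (single-tensor) voxel. Each motif returns its ensemble
#' together with the empirical mean/covariance packaged as [cntvd] parameters,
#' which is how signals are generated from it.
#'
#' Motif construction (all diffusivities in micrometre^2/ms):
#' \describe{
#' \item{uniform}{every tensor equals the base tensor; covariance exactly 0.}
#' \item{iso_emulsion}{isotropic tensors `d * I` with `d` normal around
#'   `base_md`, coefficient of variation `cv`, truncated at 0 by rejection.}
#' \item{shape_het}{`mode = "mixture"` (default): equal thirds of prolate
#'   `(0.45, 0.45, 1.5)`, oblate `(1.15, 1.15, 0.1)` and spherical
#'   `(0.8, 0.8, 0.8)` tensors, all axisymmetric about z with shared trace, so
#'   the mixture mean is exactly isotropic. `mode = "ordered"`: a continuum of
#'   strictly-ordered triaxial tensors with fixed trace and fixed eigenframe
#'   (pure shape heterogeneity: size and orientation stains are exactly zero).}
#' \item{full_het}{random trace (cv), random eigenvalue fractions, uniformly
#'   random orientations.}
#' \item{aniso_emulsion}{scaled copies `c * P` of the prolate template
#'   (`c` normal, cv, truncated at 0): anisotropic size heterogeneity.}
#' \item{transverse_size}{fixed longitudinal eigenvalue, jointly varying
#'   transverse eigenvalues (a bundle of fibers of varying diameter).}
#' \item{crossing_90}{two equal populations of identical prolate tensors with
#'   principal axes along x and y. Angles other than 90 degrees are generated
#'   on request but flagged: a single constrained Gaussian cannot represent
#'   them.}
#' }
#'
#' @param kind one of `"uniform"`, `"iso_emulsion"`, `"shape_het"`,
#'   `"full_het"`, `"aniso_emulsion"`, `"transverse_size"`, `"crossing_90"`.
#' @param n number of micro tensors.
#' @param seed integer seed (motifs are reproducible bit-for-bit).
#' @param base_md base mean diffusivity for isotropic kinds.
#' @param cv coefficient of variation of the varying quantity.
#' @param prolate prolate template eigenvalues `(x, y, z)`, principal axis z.
#' @param mode `shape_het` sub-kind, `"mixture"` or `"ordered"`.
#' @param crossing_angle angle between crossing fiber populations (degrees).
#' @return object of class `"dtd_motif"`: list with `kind`, `ensemble` (a
#'   `dtd_ensemble` of the generated tensors), and `params` (a [cntvd] with
#'   the ensemble's empirical moments).
#' @examples
#' m <- dtd_motif("crossing_90", n = 2000, seed = 7)
#' m$params
#' @export
dtd_motif <- function(kind, n = 10000L, seed = 1L, base_md = 0.8, cv = 0.25,
                      prolate = c(0.2, 0.2, 1.7),
                      mode = c("mixture", "ordered"), crossing_angle = 90) {
  kinds <- c("uniform", "iso_emulsion", "shape_het", "full_het",
             "aniso_emulsion", "transverse_size", "crossing_90")
  if (!kind %in% kinds) stop("unknown motif kind: ", kind)
  mode <- match.arg(mode)
  stopifnot(n >= 2L, base_md >= 0, cv >= 0, all(prolate >= 0))
  set.seed(as.integer(seed))
  samples <- switch(kind,
    uniform = matrix(rep(c(base_md, base_md, base_md, 0, 0, 0), n),
                     n, 6L, byrow = TRUE),
    iso_emulsion = {
      d <- .rnorm_trunc0(n, base_md, cv * base_md)
      cbind(d, d, d, 0, 0, 0)
    },
    shape_het = if (mode == "mixture") .shape_mixture(n, base_md)
                else .shape_ordered(n, base_md),
    full_het = .full_het(n, base_md, cv),
    aniso_emulsion = {
      c_ <- .rnorm_trunc0(n, 1, cv)
      cbind(c_ * prolate[1], c_ * prolate[2], c_ * prolate[3], 0, 0, 0)
    },
    transverse_size = {
      t_ <- .rnorm_trunc0(n, prolate[1], cv * prolate[1])
      cbind(t_, t_, prolate[3], 0, 0, 0)
    },
    crossing_90 = .crossing(n, prolate, crossing_angle)
  )
  colnames(samples) <- .d6_names
  stopifnot(all(is_physical(samples)))
  ens <- structure(list(samples = samples, n_proposed = n, acc_frac = 1,
                        seed = as.integer(seed)), class = "dtd_ensemble")
  mom <- empirical_moments(ens)
  params <- cntvd(mom$mean, .psd_clip(mom$omega), s0 = 1)
  structure(list(kind = kind, mode = if (kind == "shape_het") mode else NULL,
                 n = n, seed = as.integer(seed), ensemble = ens,
                 params = params), class = "dtd_motif")
}

#' @export
print.dtd_motif <- function(x, ...) {
  cat("DTD motif '", x$kind, "' (n = ", x$n, ", seed = ", x$seed, ")\n",
      sep = "")
  print(x$params)
  invisible(x)
}

# univariate normal truncated at 0 by rejection (mirrors the 6-D PSD filter)
.rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 16L, mean, sd)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}

# prolate/oblate/sphere mixture, axisymmetric about z, shared trace 3*base_md,
# eigenvalues chosen so the mixture mean is exactly isotropic base_md * I
.shape_mixture <- function(n, base_md) {
  s <- base_md / 0.8   # templates below are written for base_md = 0.8
  pro <- s * c(0.45, 0.45, 1.50)
  obl <- s * c(1.15, 1.15, 0.10)
  sph <- s * c(0.80, 0.80, 0.80)
  lab <- sample(rep_len(1:3, n))
  ev <- rbind(pro, obl, sph)[lab, , drop = FALSE]
  cbind(ev, 0, 0, 0)
}

# strictly-ordered triaxial continuum: fixed trace, fixed frame, ratios vary
.shape_ordered <- function(n, base_md) {
  s <- base_md / 0.8
  lo <- s * c(0.90, 0.80, 0.70)
  hi <- s * c(1.50, 0.50, 0.40)
  t_ <- runif(n)
  ev <- outer(1 - t_, lo) + outer(t_, hi)
  cbind(ev, 0, 0, 0)
}

# random size, shape and orientation
.full_het <- function(n, base_md, cv) {
  tr <- .rnorm_trunc0(n, 3 * base_md, cv * 3 * base_md)
  w <- matrix(rgamma(3L * n, shape = 2), n, 3L)  # eigenvalue fractions
  w <- w / rowSums(w)
  out <- matrix(0, n, 6L)
  for (i in seq_len(n)) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    out[i, ] <- dt_vector(Q %*% diag(tr[i] * w[i, ]) %*% t(Q))
  }
  out
}

.crossing <- function(n, prolate, angle_deg) {
  if (abs(angle_deg - 90) > 1e-8)
    warning("crossing angle ", angle_deg, " degrees: outside what a single ",
            "constrained Gaussian can represent (only 90-degree crossings ",
            "have a matching covariance structure)")
  lam <- sort(prolate, decreasing = TRUE)    # (long, trans, trans)
  A <- diag(c(lam[1], lam[2], lam[3]))       # principal axis x
  th <- angle_deg * pi / 180
  R <- euler_rotation(0, 0, th, order = "XYZ")  # rotate about z by the angle
  B <- R %*% A %*% t(R)
  half <- rep_len(c(TRUE, FALSE), n)
  out <- matrix(0, n, 6L)
  out[half, ] <- matrix(rep(dt_vector(A), sum(half)), ncol = 6L, byrow = TRUE)
  out[!half, ] <- matrix(rep(dt_vector(B), sum(!half)), ncol = 6L, byrow = TRUE)
  out
}

#' Continuously mixed motif ensembles
#'
#' Interpolates between two motifs by mixing fraction: for each weight `w` the
#' ensemble contains a fraction `1 - w` of tensors from motif A and `w` from
#' motif B. Stains evaluated along the grid vary monotonically in the mixed
#' property, which is how the heterogeneity stains' selectivity is probed.
#'
#' @param motif_a,motif_b two [dtd_motif] objects with the same ensemble size.
#' @param weights numeric vector of mixing fractions in `[0, 1]`.
#' @return list of `dtd_motif`-like objects (kind `"continuous_mix"`), one per
#'   weight; weight 0 reproduces motif A exactly, weight 1 motif B.
#' @export
continuous_mix <- function(motif_a, motif_b, weights) {
  stopifnot(inherits(motif_a, "dtd_motif"), inherits(motif_b, "dtd_motif"))
  if (length(weights) == 0L) stop("empty weight grid")
  stopifnot(all(weights >= 0), all(weights <= 1))
  A <- motif_a$ensemble$samples
  B <- motif_b$ensemble$samples
  n <- min(nrow(A), nrow(B))
  lapply(weights, function(w) {
    nb <- round(w * n)
    samples <- rbind(A[seq_len(n - nb), , drop = FALSE],
                     B[seq_len(nb), , drop = FALSE])
    ens <- structure(list(samples = samples, n_proposed = n, acc_frac = 1,
                          seed = NA_integer_), class = "dtd_ensemble")
    mom <- empirical_moments(ens)
    structure(list(kind = "continuous_mix", weight = w, n = n, seed = NA,
                   ensemble = ens,
                   params = cntvd(mom$mean, .psd_clip(mom$omega))),
              class = "dtd_motif")
  })
}
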