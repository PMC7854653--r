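#' Spherical quadrature / glyph grid
#'
#' Product rule on the sphere: Gauss-Legendre nodes in `cos(theta)` crossed
#' with equally spaced `phi`, spectrally accurate for smooth integrands.
#' Weights sum to `4 * pi`. The same object doubles as the vertex grid for
#' exported glyph meshes (theta-major ordering).
#'
#' @param n_theta Gauss-Legendre nodes in colatitude (default 48).
#' @param n_phi equally spaced longitudes (default 96).
#' @return object of class `"sphere_grid"`: list with `dirs` (G x 3 unit
#'   vectors), `w` (quadrature weights), `theta`, `phi`, `n_theta`, `n_phi`.
#' @examples
#' g <- sphere_grid(16, 32)
#' sum(g$w) / (4 * pi)
#' @export
sphere_grid <- function(n_theta = 48L, n_phi = 96L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x                      # cos(theta)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  dphi <- 2 * pi / n_phi
  dirs <- matrix(0, n_theta * n_phi, 3L)
  w <- numeric(n_theta * n_phi)
  k <- 1L
  for (i in seq_len(n_theta)) for (j in seq_len(n_phi)) {
    dirs[k, ] <- c(st[i] * cos(phi[j]), st[i] * sin(phi[j]), ct[i])
    w[k] <- gl$w[i] * dphi
    k <- k + 1L
  }
  structure(list(dirs = dirs, w = w, theta = acos(ct), phi = phi,
                 n_theta = n_theta, n_phi = n_phi), class = "sphere_grid")
}

# G x 6 matrix of quadratic-form coefficients u(r) with t(u) %*% d6 = r' D r
.dir_quadform <- function(grid) {
  r <- grid$dirs
  cbind(r[, 1]^2, r[, 2]^2, r[, 3]^2,
        2 * r[, 1] * r[, 2], 2 * r[, 1] * r[, 3], 2 * r[, 2] * r[, 3])
}

#' Orientation distribution function of a diffusion tensor
#'
#' Gaussian ODF: `ODF(r) = 1 / (4 pi sqrt(det D) (r' D^-1 r)^(3/2))`, which
#' integrates to 1 over the sphere. Requires a strictly positive-definite
#' tensor.
#'
#' @param D length-6 tensor or 3x3 matrix.
#' @param grid a [sphere_grid].
#' @return ODF values on the grid directions.
#' @export
odf <- function(D, grid) {
  M <- if (is.matrix(D)) D else dt_matrix(D)
  dt <- det(M)
  if (dt <= 0) stop("singular or non-positive-definite tensor: ODF undefined")
  Minv <- solve(M)
  q <- as.numeric(.dir_quadform(grid) %*% dt_vector(Minv))
  1 / (4 * pi * sqrt(dt) * q^1.5)
}

#' ODF entropy of a diffusion tensor
#'
#' `- integral over the sphere of ODF * log(ODF)`: `log(4 pi) ~ 2.531` for an
#' isotropic tensor, smaller for anisotropic ones.
#' @inheritParams odf
#' @return scalar entropy.
#' @export
odf_entropy <- function(D, grid) {
  v <- odf(D, grid)
  -sum(grid$w * v * log(v))
}

#' Micro- and macro-ODF of a tensor ensemble
#'
#' The micro-ODF is the ensemble average of the per-tensor ODFs (so it keeps
#' the distinct coherent populations: a 90-degree crossing gives four lobes);
#' the macro-ODF is the ODF of the mean tensor (a single-tensor peanut).
#' Members that are numerically singular are skipped with a counted warning.
#'
#' @param ensemble a `dtd_ensemble`, `dtd_motif` or n x 6 matrix.
#' @param grid a [sphere_grid].
#' @return ODF values on the grid.
#' @export
micro_odf <- function(ensemble, grid) {
  X <- as_sample_matrix(ensemble)
  U <- .dir_quadform(grid)
  # vectorized inverse via adjugate: inv = adj / det
  a <- X[, 1]; b <- X[, 2]; c_ <- X[, 3]
  f <- X[, 4]; g <- X[, 5]; h <- X[, 6]
  det3 <- a * (b * c_ - h * h) - f * (f * c_ - h * g) + g * (f * h - b * g)
  ok <- det3 > 1e-12
  if (!all(ok)) warning(sum(!ok), " singular member tensor(s) skipped")
  inv6 <- cbind(b * c_ - h * h, a * c_ - g * g, a * b - f * f,
                g * h - f * c_, f * h - b * g, f * g - a * h) / det3
  Q <- U %*% t(inv6[ok, , drop = FALSE])          # G x n, r' D^-1 r
  vals <- sweep(Q^-1.5, 2L, 1 / (4 * pi * sqrt(det3[ok])), "*")
  rowMeans(vals)
}

#' @rdname micro_odf
#' @param mean length-6 mean tensor (or a `cntvd` object).
#' @export
macro_odf <- function(mean, grid) {
  if (inherits(mean, "cntvd")) mean <- mean$mean
  odf(mean, grid)
}

#' Covariance glyph radii
#'
#' Projects the fourth-order covariance onto the sphere by the contraction
#' `r_i r_j r_k r_l C_ijkl`, i.e. the variance of `r' D r` along each
#' direction: large radii mark directions of large mean-tensor uncertainty.
#'
#' @param omega symmetric PSD 6x6 covariance (or 3x3x3x3 array, or `cntvd`).
#' @param grid a [sphere_grid].
#' @return non-negative radii on the grid.
#' @export
covariance_glyph <- function(omega, grid) {
  if (inherits(omega, "cntvd")) omega <- omega$omega
  if (is.array(omega) && length(dim(omega)) == 4L)
    omega <- ctensor_to_omega(omega)
  U <- .dir_quadform(grid)
  pmax(rowSums((U %*% omega) * U), 0)
}

#' Export a glyph surface as a mesh file
#'
#' Writes the spherical surface with vertex positions `radius * r(theta, phi)`
#' as an ASCII PLY (default) or OBJ file, triangulating the grid's
#' theta-major latitude/longitude topology.
#'
#' @param radii non-negative radii, one per grid direction.
#' @param grid the [sphere_grid] the radii were evaluated on.
#' @param path output file path.
#' @param format `"ply"` or `"obj"`.
#' @return `path`, invisibly.
#' @export
export_glyph_mesh <- function(radii, grid, path, format = c("ply", "obj")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "sphere_grid"), length(radii) == nrow(grid$dirs))
  if (any(radii < 0)) stop("radii must be non-negative")
  if (max(radii) <= 0) stop("all radii are zero: degenerate mesh refused")
  V <- grid$dirs * radii
  nt <- grid$n_theta; np <- grid$n_phi
  ii <- rep(seq_len(nt - 1L), each = np)
  jj <- rep(seq_len(np), nt - 1L)
  idx <- function(i, j) (i - 1L) * np + ((j - 1L) %% np) + 1L
  v00 <- idx(ii, jj); v01 <- idx(ii, jj + 1L)
  v10 <- idx(ii + 1L, jj); v11 <- idx(ii + 1L, jj + 1L)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
  } else {
    writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  }
  invisible(path)
}

#' Read vertices back from an ASCII PLY file
#'
#' Minimal reader for round-tripping meshes written by [export_glyph_mesh].
#' @param path PLY file path.
#' @return matrix of vertex coordinates.
#' @export
read_ply_vertices <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  start <- which(lines == "end_header")[1] + 1L
  vs <- trimws(lines[start:(start + nv - 1L)])
  do.call(rbind, lapply(strsplit(vs, " +"), function(x) as.numeric(x[1:3])))
}
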