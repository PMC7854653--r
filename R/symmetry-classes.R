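# Nested model classes for the mean tensor and the fourth-order covariance.
#
# Covariance templates are expressed in a local frame whose z-axis is the
# crystallographic unique axis; at fit time the local frame is tied to the
# estimated mean tensor (local z = principal eigenvector; lab frame for
# isotropic/noise means). Component ordering is the package's
# (xx, yy, zz, xy, xz, yz); note this differs from elasticity Voigt order
# (which puts yz, xz, xy last), so the familiar elasticity constants map as
# V44 -> (6,6), V55 -> (5,5), V66 -> (4,4), V16 -> (1,4), V14 -> (1,6), etc.

.sym6 <- function(entries) {
  # entries: list of c(i, j, value)
  M <- matrix(0, 6, 6)
  for (e in entries) {
    M[e[1], e[2]] <- M[e[1], e[2]] + e[3]
    if (e[1] != e[2]) M[e[2], e[1]] <- M[e[2], e[1]] + e[3]
  }
  M
}

# template basis matrices per covariance symmetry class (unique axis = local z)
.cov_templates <- local({
  iso <- list(
    lambda = .sym6(list(c(1,1,1), c(2,2,1), c(3,3,1), c(1,2,1), c(1,3,1), c(2,3,1))),
    mu     = .sym6(list(c(1,1,2), c(2,2,2), c(3,3,2), c(4,4,1), c(5,5,1), c(6,6,1))))
  cub <- list(
    C11 = .sym6(list(c(1,1,1), c(2,2,1), c(3,3,1))),
    C12 = .sym6(list(c(1,2,1), c(1,3,1), c(2,3,1))),
    C44 = .sym6(list(c(4,4,1), c(5,5,1), c(6,6,1))))
  hex <- list(
    C11 = .sym6(list(c(1,1,1), c(2,2,1), c(4,4,0.5))),
    C33 = .sym6(list(c(3,3,1))),
    C12 = .sym6(list(c(1,2,1), c(4,4,-0.5))),
    C13 = .sym6(list(c(1,3,1), c(2,3,1))),
    C44 = .sym6(list(c(6,6,1), c(5,5,1))))
  tet6 <- list(
    C11 = .sym6(list(c(1,1,1), c(2,2,1))),
    C33 = .sym6(list(c(3,3,1))),
    C12 = .sym6(list(c(1,2,1))),
    C13 = .sym6(list(c(1,3,1), c(2,3,1))),
    C44 = .sym6(list(c(6,6,1), c(5,5,1))),
    C66 = .sym6(list(c(4,4,1))))
  tet7 <- c(tet6, list(C16 = .sym6(list(c(1,4,1), c(2,4,-1)))))
  tri6 <- c(hex,  list(C14 = .sym6(list(c(1,6,1), c(2,6,-1), c(5,4,1)))))
  tri7 <- c(tri6, list(C15 = .sym6(list(c(1,5,1), c(2,5,-1), c(6,4,-1)))))
  ort <- list(
    C11 = .sym6(list(c(1,1,1))), C22 = .sym6(list(c(2,2,1))),
    C33 = .sym6(list(c(3,3,1))), C12 = .sym6(list(c(1,2,1))),
    C13 = .sym6(list(c(1,3,1))), C23 = .sym6(list(c(2,3,1))),
    C44 = .sym6(list(c(6,6,1))), C55 = .sym6(list(c(5,5,1))),
    C66 = .sym6(list(c(4,4,1))))
  mon <- c(ort, list(
    C16 = .sym6(list(c(1,4,1))), C26 = .sym6(list(c(2,4,1))),
    C36 = .sym6(list(c(3,4,1))), C45 = .sym6(list(c(6,5,1)))))
  tri <- local({
    nm <- character(0); out <- list()
    for (a in 1:6) for (b in a:6) {
      out[[length(out) + 1L]] <- .sym6(list(c(a, b, 1)))
      nm <- c(nm, paste0("V", a, b))
    }
    names(out) <- nm
    out
  })
  list(none = list(), isotropic = iso, cubic = cub, hexagonal = hex,
       trigonal6 = tri6, trigonal7 = tri7, tetragonal6 = tet6,
       tetragonal7 = tet7, orthorhombic = ort, monoclinic = mon,
       triclinic = tri)
})

#' Covariance symmetry classes
#'
#' Names and parameter counts of the eight nested covariance classes (plus the
#' zero-covariance baseline). The trigonal and tetragonal classes come in
#' their 6- and 7-constant variants, both offered as separate candidates.
#' @return data frame with `class` and `n_params`.
#' @export
cov_classes <- function() {
  data.frame(class = names(.cov_templates),
             n_params = vapply(.cov_templates, length, 1L),
             row.names = NULL)
}

#' Mean tensor classes
#' @return data frame with `class` and `n_params` (counts include `s0`).
#' @export
mean_classes <- function() {
  data.frame(class = c("noise", "isotropic", "prolate", "oblate", "general"),
             n_params = c(1L, 2L, 5L, 5L, 7L), row.names = NULL)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic completion of a unit vector to a right-handed frame,
# anchored at the lab axes so phantom-aligned fits land on the lab frame
.complete_frame <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  cbind(u, .cross3(w, u), w)   # columns: local x, y, z = w
}

.unit_from_angles <- function(th, ph)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))

.angles_from_unit <- function(n) c(acos(max(-1, min(1, n[3]))), atan2(n[2], n[1]))

# mean-class parameterization: theta -> list(dbar, frame) where frame's third
# column is the covariance templates' local z (unique axis)
.mean_map <- function(class, theta) {
  switch(class,
    noise = list(dbar = numeric(6), frame = diag(3)),
    isotropic = {
      d <- exp(theta[1])
      list(dbar = c(d, d, d, 0, 0, 0), frame = diag(3))
    },
    prolate = {
      lperp <- exp(theta[1]); lpar <- lperp + exp(theta[2])
      n <- .unit_from_angles(theta[3], theta[4])
      D <- lperp * diag(3) + (lpar - lperp) * tcrossprod(n)
      F <- .complete_frame(n)                  # local z = fiber axis
      list(dbar = dt_vector(D), frame = F)
    },
    oblate = {
      l3 <- exp(theta[1]); lpar <- l3 + exp(theta[2])
      n <- .unit_from_angles(theta[3], theta[4])   # unique (small) axis
      D <- lpar * diag(3) - (lpar - l3) * tcrossprod(n)
      # principal directions are transverse to n; local z = the lab-anchored
      # transverse direction, so phantom-aligned fits land on the lab frame
      a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- a - sum(a * n) * n
      w <- w / sqrt(sum(w^2))
      F <- cbind(n, .cross3(w, n), w)
      list(dbar = dt_vector(D), frame = F)
    },
    general = {
      ev <- exp(theta[1:3])
      R <- euler_rotation(theta[4], theta[5], theta[6], order = "XYZ")
      D <- R %*% diag(ev) %*% t(R)
      # local z = axis of the first eigenvalue slot (initialized largest)
      F <- cbind(R[, 2], R[, 3], R[, 1])
      list(dbar = dt_vector(D), frame = F)
    },
    stop("unknown mean class: ", class))
}

.mean_npar_theta <- c(noise = 0L, isotropic = 1L, prolate = 4L, oblate = 4L,
                      general = 6L)

# initial mean theta from an unconstrained tensor estimate (e.g. log-linear
# DTI fit); eigenvalues floored at a small positive diffusivity
.mean_init <- function(class, Dhat) {
  e <- eigen(dt_matrix(Dhat), symmetric = TRUE)
  ev <- pmax(e$values, 1e-4)
  switch(class,
    noise = numeric(0),
    isotropic = log(mean(ev)),
    prolate = {
      lperp <- max(mean(ev[2:3]), 1e-4)
      gap <- max(ev[1] - lperp, 1e-4)
      c(log(lperp), log(gap), .angles_from_unit(e$vectors[, 1]))
    },
    oblate = {
      l3 <- ev[3]
      lpar <- max(mean(ev[1:2]), l3 + 1e-4)
      c(log(l3), log(max(lpar - l3, 1e-4)), .angles_from_unit(e$vectors[, 3]))
    },
    general = {
      R <- e$vectors
      if (det(R) < 0) R[, 3] <- -R[, 3]
      b <- asin(max(-1, min(1, R[1, 3])))
      a <- atan2(-R[2, 3], R[3, 3])
      g <- atan2(-R[1, 2], R[1, 1])
      c(log(ev), a, b, g)
    })
}

# axis-assignment variants of the mean initialization: for (near-)degenerate
# apparent tensors the eigen-axis ordering is arbitrary but fixes the
# covariance template frame, so all three assignments are offered and the
# caller picks the one that best explains the covariance starting estimate
.mean_init_variants <- function(class, Dhat) {
  e <- eigen(dt_matrix(Dhat), symmetric = TRUE)
  ev <- pmax(e$values, 1e-4)
  out <- list()
  for (j in 1:3) {
    axis <- .angles_from_unit(e$vectors[, j])
    th <- switch(class,
      prolate = {
        lperp <- max(mean(ev[-j]), 1e-4)
        c(log(lperp), log(max(ev[j] - lperp, 1e-4)), axis)
      },
      oblate = {
        l3 <- ev[j]
        lpar <- max(mean(ev[-j]), l3 + 1e-4)
        c(log(l3), log(max(lpar - l3, 1e-4)), axis)
      },
      general = {
        R <- e$vectors[, c(j, setdiff(1:3, j)), drop = FALSE]
        if (det(R) < 0) R[, 3] <- -R[, 3]
        b <- asin(max(-1, min(1, R[1, 3])))
        a <- atan2(-R[2, 3], R[3, 3])
        g <- atan2(-R[1, 2], R[1, 1])
        c(log(ev[c(j, setdiff(1:3, j))]), a, b, g)
      },
      NULL)
    if (!is.null(th)) out[[j]] <- th
  }
  out
}

# covariance map: constants + frame -> (omega_lab clipped PSD, factor L,
# clipped mass = sum of squared negative Mandel eigenvalues, used as a smooth
# penalty keeping the optimizer out of the zero-gradient non-PSD region)
.cov_map <- function(class, const, frame) {
  tpl <- .cov_templates[[class]]
  if (length(tpl) == 0L)
    return(list(omega = matrix(0, 6, 6), L = matrix(0, 6, 6), clipped = 0))
  om_loc <- matrix(0, 6, 6)
  for (a in seq_along(tpl)) om_loc <- om_loc + const[a] * tpl[[a]]
  M <- rotation_matrix_d6(frame)      # local -> lab
  om_lab <- M %*% om_loc %*% t(M)
  om_lab <- (om_lab + t(om_lab)) / 2
  # one eigendecomposition (Mandel scaling) serves the PSD clip, the
  # sampling factor, and the clipped-mass penalty
  s <- c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))
  e <- eigen(om_lab * tcrossprod(s), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lam[lam < 1e-12 * max(lam, 0)] <- 0
  Vt <- t(e$vectors)
  om_psd <- crossprod(Vt * sqrt(lam)) / tcrossprod(s)
  Lm <- crossprod(Vt * lam^0.25)      # symmetric sqrt of clipped Mandel form
  list(omega = om_psd, L = (1 / s) * Lm,
       clipped = sum(pmin(e$values, 0)^2))
}

# least-squares projection of a lab-frame covariance estimate onto a class's
# constants in the given frame (used for initialization)
.cov_init <- function(class, omega_lab, frame) {
  tpl <- .cov_templates[[class]]
  if (length(tpl) == 0L) return(numeric(0))
  Minv <- rotation_matrix_d6(t(frame))  # lab -> local
  om_loc <- Minv %*% omega_lab %*% t(Minv)
  X <- vapply(tpl, as.numeric, numeric(36))
  qr.solve(X, as.numeric(om_loc), tol = 1e-12)
}
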