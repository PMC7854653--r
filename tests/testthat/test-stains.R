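test_that("micro-FA equals FA for uniform ensembles and exceeds it for shape mixtures", {
  pro <- dtd_motif("uniform", n = 50, seed = 1)
  expect_equal(micro_average(pro$ensemble, "fa"), fa(pro$params$mean))
  iso <- matrix(rep(c(0.8, 0.8, 0.8, 0, 0, 0), 20), 20, 6, byrow = TRUE)
  expect_equal(micro_average(iso, "fa"), 0)
  sh <- dtd_motif("shape_het", n = 6000, seed = 2)
  st <- dtd_stains(sh)
  expect_gt(st$mu_fa, st$fa_of_mean)
  # size-only heterogeneity: micro-FA does not exceed FA of the mean
  em <- dtd_stains(dtd_motif("iso_emulsion", n = 6000, seed = 3))
  expect_lt(abs(em$mu_fa - em$fa_of_mean), 1e-9)
})

test_that("V_size follows the covariance block identity", {
  expect_equal(v_size(matrix(0, 6, 6)), 0)
  lam <- 0.04
  expect_equal(v_size(omega_isotropic(lam, 0)), sqrt(lam))
  mu <- 0.015
  expect_equal(v_size(omega_isotropic(lam, mu)), sqrt(lam + 2 * mu / 3))
  # sampling oracle: SD of mean ADC over untruncated draws
  set.seed(61)
  n <- 200000
  L <- cntvd:::.psd_factor(omega_isotropic(lam, mu))
  D <- matrix(rnorm(n * 6), n, 6) %*% t(L)
  madc <- rowMeans(D[, 1:3])
  v <- sqrt(lam + 2 * mu / 3)
  expect_lt(abs(sd(madc) - v), 5 * v * sqrt(0.5 / n))
  A <- matrix(0, 6, 6); A[1, 1] <- 1; A[2, 2] <- 1; A[1, 2] <- A[2, 1] <- -1.5
  expect_error(v_size(A), "not PSD")
})

test_that("V_shape is zero for shared shapes, rotation-invariant, exact for two-point mixtures", {
  u <- dtd_motif("uniform", n = 50, seed = 1)
  expect_equal(v_shape(u$ensemble), 0)
  # randomly rotated copies of one prolate tensor
  set.seed(71)
  P <- diag(c(1.7, 0.2, 0.2))
  X <- t(vapply(1:200, function(i) {
    R <- random_rotation()
    dt_vector(R %*% P %*% t(R))
  }, numeric(6)))
  expect_lt(v_shape(X), 1e-10)
  # 50/50 spheres and prolates: hand-computed two-point variances
  n <- 400
  Xm <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), n / 2), ncol = 6, byrow = TRUE),
              matrix(rep(c(1.7, 0.2, 0.2, 0, 0, 0), n / 2), ncol = 6,
                     byrow = TRUE))
  r1 <- c(1, 2 / 17)    # lambda2/lambda1 per population
  r2 <- c(1, 1)         # lambda3/lambda2
  ref <- sqrt(var(rep(r1, each = n / 2)) + var(rep(r2, each = n / 2)))
  expect_equal(v_shape(Xm), ref, tolerance = 1e-12)
})

test_that("V_orient spans coherent (0) to uniformly random (1)", {
  coh <- dtd_motif("aniso_emulsion", n = 400, seed = 3)
  expect_lt(v_orient(coh$ensemble), 1e-8)
  set.seed(81)
  P <- diag(c(1.7, 0.2, 0.2))
  X <- t(vapply(1:4000, function(i) {
    R <- random_rotation()
    dt_vector(R %*% P %*% t(R))
  }, numeric(6)))
  expect_equal(v_orient(X), 1, tolerance = 0.02)
  # isotropic members carry no orientation information
  iso <- matrix(rep(c(0.8, 0.8, 0.8, 0, 0, 0), 30), 30, 6, byrow = TRUE)
  expect_equal(v_orient(iso), 0)
  # crossing fibers: nonzero dispersion (value sqrt(1/2) for equal populations)
  cr <- dtd_motif("crossing_90", n = 400, seed = 4)
  expect_equal(v_orient(cr$ensemble), sqrt(0.5), tolerance = 1e-6)
})

test_that("V_orient matches the brute-force dyadic oracle on partial fanning", {
  set.seed(91)
  P <- diag(c(1.7, 0.25, 0.15))   # distinct eigenvalues: no degeneracy path
  angles <- runif(3000, 0, pi / 2)
  X <- t(vapply(angles, function(a) {
    R <- euler_rotation(0, 0, a, order = "XYZ")
    dt_vector(R %*% P %*% t(R))
  }, numeric(6)))
  expect_equal(v_orient(X), oracle_v_orient(X), tolerance = 1e-10)
  # planar fans share the rotation axis as a coherent eigenvector family, so
  # the min-over-labels rule reports zero dispersion: the formula as printed
  expect_equal(v_orient(X), 0, tolerance = 1e-10)
  # genuinely 3-D dispersion: partial wobble in all angles
  X2 <- t(vapply(1:2000, function(i) {
    R <- euler_rotation(rnorm(1, 0, 0.4), rnorm(1, 0, 0.4), rnorm(1, 0, 0.4))
    dt_vector(R %*% P %*% t(R))
  }, numeric(6)))
  expect_equal(v_orient(X2), oracle_v_orient(X2), tolerance = 1e-10)
  expect_gt(v_orient(X2), 0.05)
  expect_lt(v_orient(X2), 0.95)
  # degenerate-pair path agrees with the oracle too
  cr <- dtd_motif("crossing_90", n = 500, seed = 5)
  expect_equal(v_orient(cr$ensemble), oracle_v_orient(cr$ensemble$samples),
               tolerance = 1e-10)
})

test_that("stains are selective: each pure motif lights up exactly one stain", {
  size_m <- dtd_stains(dtd_motif("iso_emulsion", n = 8000, seed = 6))
  shape_m <- dtd_stains(dtd_motif("shape_het", n = 8000, seed = 6,
                                  mode = "ordered"))
  orient_m <- dtd_stains(dtd_motif("crossing_90", n = 8000, seed = 6))
  # matching stain positive
  expect_gt(size_m$v_size, 0.05)
  expect_gt(shape_m$v_shape, 0.05)
  expect_gt(orient_m$v_orient, 0.5)
  # off-target stains below 5% of the active one (scale-free comparison per
  # stain across motifs)
  expect_lt(shape_m$v_size / size_m$v_size, 0.05)
  expect_lt(orient_m$v_size / size_m$v_size, 0.05)
  expect_lt(size_m$v_shape / shape_m$v_shape, 0.05)
  expect_lt(orient_m$v_shape / shape_m$v_shape, 0.05)
  expect_lt(size_m$v_orient / orient_m$v_orient, 0.05)
  expect_lt(shape_m$v_orient / orient_m$v_orient, 0.05)
})

test_that("stains are invariant under a global rotation of the ensemble", {
  m <- dtd_motif("crossing_90", n = 600, seed = 7)
  set.seed(101)
  R <- random_rotation()
  Xr <- t(apply(m$ensemble$samples, 1, function(d)
    dt_vector(R %*% dt_matrix(d) %*% t(R))))
  expect_equal(v_shape(Xr), v_shape(m$ensemble), tolerance = 1e-9)
  expect_equal(v_orient(Xr), v_orient(m$ensemble), tolerance = 1e-9)
  expect_equal(micro_average(Xr, "fa"), micro_average(m$ensemble, "fa"),
               tolerance = 1e-9)
  expect_equal(v_size(empirical_moments(Xr)$omega),
               v_size(empirical_moments(m$ensemble)$omega), tolerance = 1e-9)
})

test_that("DTD entropy is higher for heterogeneous than uniform motifs", {
  # density-based entropy via the subspace log-density on sampled ensembles
  p_u <- cntvd(0.8 * diag(3), omega_isotropic(1e-4))
  p_h <- cntvd(0.8 * diag(3), omega_isotropic(0.02, 0.01))
  e_u <- sample_cntvd(p_u, 3000, seed = 8)
  e_h <- sample_cntvd(p_h, 3000, seed = 8)
  s_u <- micro_average(e_u, "neg_log_density", params = p_u)
  s_h <- micro_average(e_h, "neg_log_density", params = p_h)
  expect_gt(s_h, s_u)
})
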