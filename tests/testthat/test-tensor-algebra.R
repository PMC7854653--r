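test_that("6-vector / 3x3 conversions are exact and ordered (xx,yy,zz,xy,xz,yz)", {
  expect_equal(dt_matrix(c(1, 1, 1, 0, 0, 0)), diag(3))
  M <- diag(c(1, 2, 3)); M[1, 2] <- M[2, 1] <- 0.3
  expect_equal(unname(dt_vector(M)), c(1, 2, 3, 0.3, 0, 0))
  set.seed(42)
  for (i in 1:100) {
    A <- matrix(rnorm(9), 3, 3); A <- (A + t(A)) / 2
    expect_identical(dt_matrix(dt_vector(A)), (A + t(A)) / 2)
  }
  expect_error(dt_vector(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("b-vector doubling makes the inner product the full contraction", {
  expect_equal(bvec_from_bmatrix(diag(c(1, 2, 3))), c(1, 2, 3, 0, 0, 0))
  B <- matrix(0, 3, 3); B[1, 2] <- B[2, 1] <- 0.5
  # pure off-diagonal b is indefinite; build the PSD part via outer products
  Bp <- tcrossprod(c(1, 1, 0)) / 2           # bxy entry 0.5, PSD
  b6 <- bvec_from_bmatrix(Bp)
  d6 <- c(0, 0, 0, 0.7, 0, 0)
  expect_equal(sum(b6 * d6), oracle_double_contraction(Bp, dt_matrix(d6)))
  set.seed(7)
  for (i in 1:50) {
    R <- random_rotation()
    Bm <- R %*% diag(runif(3, 0, 3)) %*% t(R)
    D <- matrix(rnorm(9), 3, 3); D <- (D + t(D)) / 2
    expect_equal(sum(bvec_from_bmatrix(Bm) * dt_vector(D)),
                 oracle_double_contraction(Bm, D), tolerance = 1e-12)
  }
  expect_error(bvec_from_bmatrix(diag(c(1, 1, -0.5))), "negative eigenvalue")
})

test_that("physical b.D contraction is non-negative for PSD pairs", {
  set.seed(8)
  for (i in 1:50) {
    R1 <- random_rotation(); R2 <- random_rotation()
    Bm <- R1 %*% diag(runif(3, 0, 3)) %*% t(R1)
    Dm <- R2 %*% diag(runif(3, 0, 2)) %*% t(R2)
    expect_gte(sum(bvec_from_bmatrix(Bm) * dt_vector(Dm)), -1e-12)
  }
})

test_that("omega <-> fourth-order tensor mapping round-trips with all symmetries", {
  expect_equal(omega_to_ctensor(matrix(0, 6, 6)), array(0, c(3, 3, 3, 3)))
  # isotropic class expanded index-by-index from the delta formula
  lambda <- 0.3; mu <- 0.1
  Cref <- array(0, c(3, 3, 3, 3))
  d <- diag(3)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    Cref[i, j, k, l] <- lambda * d[i, j] * d[k, l] +
      mu * (d[i, k] * d[j, l] + d[i, l] * d[j, k])
  om <- ctensor_to_omega(Cref)
  expect_equal(om[1:3, 1:3], matrix(lambda, 3, 3) + diag(2 * mu, 3))
  expect_equal(om[4:6, 4:6], diag(mu, 3))
  expect_equal(om, omega_isotropic(lambda, mu))
  set.seed(3)
  for (i in 1:50) {
    O <- matrix(rnorm(36), 6, 6); O <- (O + t(O)) / 2
    C <- omega_to_ctensor(O)
    # minor and major symmetries of the expansion
    expect_equal(C[1, 2, 1, 3], C[2, 1, 1, 3])
    expect_equal(C[1, 2, 1, 3], C[1, 3, 1, 2])
    expect_identical(ctensor_to_omega(C), O)
  }
  Cbad <- array(rnorm(81), c(3, 3, 3, 3))
  expect_error(ctensor_to_omega(Cbad), "minor symmetries")
})

test_that("Euler rotations are proper and compose as written", {
  expect_equal(euler_rotation(0, 0, 0), diag(3))
  R <- euler_rotation(pi / 2, 0, 0, order = "XYZ")
  expect_equal(as.numeric(R %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:100) {
    a <- runif(3, -2 * pi, 2 * pi)
    R <- euler_rotation(a[1], a[2], a[3],
                        order = paste(sample(c("X", "Y", "Z")), collapse = ""))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  expect_error(euler_rotation(0, 0, 0, order = "XXY"), "permutation")
})

test_that("fourth-order rotation matches the direct 4-index contraction", {
  set.seed(9)
  O <- random_psd6(1)
  R <- random_rotation()
  Cp <- oracle_rotate_c4(omega_to_ctensor(O), R)
  expect_equal(rotate_fourth_order(O, R), ctensor_to_omega(Cp),
               tolerance = 1e-10)
  # array form in, array form out
  expect_equal(rotate_fourth_order(omega_to_ctensor(O), R), Cp,
               tolerance = 1e-10)
  # identity and isotropy
  expect_equal(rotate_fourth_order(O, diag(3)), O)
  expect_equal(rotate_fourth_order(omega_isotropic(0.2, 0.07), R),
               omega_isotropic(0.2, 0.07), tolerance = 1e-10)
})

test_that("rotation preserves the Mandel spectrum and composes", {
  set.seed(10)
  for (i in 1:10) {
    O <- random_psd6(1)
    R1 <- random_rotation(); R2 <- random_rotation()
    Or <- rotate_fourth_order(O, R1)
    expect_equal(sort(eigen(mandel_form(Or), symmetric = TRUE)$values),
                 sort(eigen(mandel_form(O), symmetric = TRUE)$values),
                 tolerance = 1e-10)
    expect_equal(rotate_fourth_order(rotate_fourth_order(O, R1), R2),
                 rotate_fourth_order(O, R2 %*% R1), tolerance = 1e-10)
  }
})

test_that("PSD checks use a relative eigenvalue tolerance", {
  expect_true(is_psd_omega(omega_isotropic(0.1, 0.05)))
  expect_true(is_psd_omega(matrix(0, 6, 6)))
  A <- diag(6); A[6, 6] <- -1e-3
  expect_false(is_psd_omega(A))
  expect_true(is_physical(c(1, 1, 1, 0, 0, 0)))
  expect_false(is_physical(c(1, 1, -0.2, 0, 0, 0)))
  X <- rbind(c(1, 1, 1, 0, 0, 0), c(0.1, 0.1, -0.5, 0, 0, 0))
  expect_identical(is_physical(X), c(TRUE, FALSE))
})
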