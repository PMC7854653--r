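test_that("the MC signal reduces to the DTI closed form at zero covariance", {
  des <- tiny_design()
  p <- cntvd(dt_matrix(c(1.2, 0.7, 0.4, 0.1, 0, 0)))
  expect_equal(mc_signal(p, des, n = 2000, seed = 1),
               dti_signal(p$mean, 1, des), tolerance = 1e-12)
  expect_equal(mc_signal(p, des, n = 2000, seed = 1)[1], 1)  # b = 0 anchor
})

test_that("DTI signal is monotone in trace for fixed shape and isotropic means", {
  des <- tiny_design()
  s1 <- dti_signal(0.5 * diag(3), 1, des)
  expect_equal(s1, exp(-0.5 * des$trace), tolerance = 1e-12)
})

test_that("MC signal is bounded by [0, s0] and non-increasing under b scaling", {
  set.seed(21)
  p <- cntvd(0.8 * diag(3), omega_isotropic(0.02, 0.008), s0 = 2)
  for (rep in 1:10) {
    des <- dtd_design(n = 30, seed = rep)
    S1 <- mc_signal(p, des, n = 4000, seed = 5)
    expect_true(all(S1 >= 0 & S1 <= p$s0 * (1 + 1e-12)))
    des2 <- des
    for (cc in c("bxx", "byy", "bzz", "bxy", "bxz", "byz", "trace"))
      des2[[cc]] <- des2[[cc]] * 1.7
    S2 <- mc_signal(p, des2, n = 4000, seed = 5)
    expect_true(all(S2 <= S1 + 1e-12))
  }
})

test_that("isotropic emulsion MC signal matches 1-D quadrature to < 0.5%", {
  m <- dtd_motif("iso_emulsion", n = 200000, seed = 31)
  des <- tiny_design()
  S <- mc_signal(m$params, des, n = 200000, seed = 32)
  dbar <- m$params$mean[1]
  sig <- sqrt(m$params$omega[1, 1])
  Sref <- vapply(des$trace, function(b) {
    num <- integrate(function(d) dnorm(d, dbar, sig) * exp(-b * d), 0, Inf,
                     rel.tol = 1e-10)$value
    den <- integrate(function(d) dnorm(d, dbar, sig), 0, Inf,
                     rel.tol = 1e-10)$value
    num / den
  }, 1)
  expect_lt(max(abs(S - Sref) / Sref), 0.005)
})

test_that("cumulant model agrees to second order and turns unphysical at large b", {
  # covariance small enough that truncation is negligible: the cumulant form
  # carries the untruncated moments, so agreement at small b requires the
  # constrained law to essentially coincide with the Gaussian
  p <- cntvd(0.8 * diag(3), omega_isotropic(0.005, 0.002))
  mk_des <- function(b) {
    d <- dtd_design(n = 30, seed = 9)[2, , drop = FALSE]
    scale <- b / d$trace
    for (cc in c("bxx", "byy", "bzz", "bxy", "bxz", "byz", "trace"))
      d[[cc]] <- d[[cc]] * scale
    d
  }
  # Richardson-style ratio: deviation from MC shrinks as O(b^3)
  dev <- vapply(c(0.01, 0.02, 0.04), function(b) {
    des <- mk_des(b)
    abs(cumulant_signal(p, des) - mc_signal(p, des, n = 400000, seed = 3))
  }, 1)
  # each doubling of b should roughly cube the deviation; allow MC noise slack
  expect_lt(dev[1], 1e-4)
  expect_lt(dev[2], 1e-3)
  # unphysical growth: signal exceeds s0 at large enough b
  des_big <- mk_des(300)
  expect_gt(cumulant_signal(p, des_big), p$s0)
  expect_gt(kurtosis_signal(p, des_big), p$s0)
  expect_lte(mc_signal(p, des_big, n = 20000, seed = 4), p$s0)
})

test_that("kurtosis tensor is the brute-force symmetrization of the covariance", {
  set.seed(41)
  O <- random_psd6(0.3)
  p <- cntvd(dt_matrix(c(1, 0.8, 0.6, 0.1, 0, 0.05)), O)
  K <- kurtosis_from_covariance(p)
  Kref <- oracle_kurtosis(omega_to_ctensor(O), sum(p$mean[1:3]))
  expect_equal(K, Kref, tolerance = 1e-12)
  # full permutation symmetry
  for (i in 1:10) {
    ix <- sample(1:3, 4, replace = TRUE)
    pm <- sample(1:4)
    expect_equal(K[ix[1], ix[2], ix[3], ix[4]],
                 K[ix[pm][1], ix[pm][2], ix[pm][3], ix[pm][4]])
  }
  expect_equal(kurtosis_from_covariance(cntvd(diag(3) * 0.5)),
               array(0, c(3, 3, 3, 3)))
  expect_error(kurtosis_from_covariance(
    structure(list(mean = numeric(6), omega = O, s0 = 1), class = "cntvd")),
    "positive")
})

test_that("projection identity: quadratic form equals the contraction variance", {
  set.seed(51)
  O <- random_psd6(0.15)
  p <- cntvd(2 * diag(3), O)   # mean far inside the cone: no truncation
  n <- 200000
  L <- cntvd:::.psd_factor(O)
  D <- matrix(rnorm(n * 6), n, 6) %*% t(L)
  D <- sweep(D, 2, p$mean, "+")
  des <- tiny_design()
  Bv <- cbind(des$bxx, des$byy, des$bzz, 2 * des$bxy, 2 * des$bxz, 2 * des$byz)
  for (i in c(5, 20, 40)) {
    b6 <- Bv[i, ]
    v_pred <- as.numeric(t(b6) %*% O %*% b6)
    proj <- as.numeric(D %*% b6)
    se <- v_pred * sqrt(2 / n)
    expect_lt(abs(var(proj) - v_pred), 5 * se + 1e-12)
  }
})

test_that("Rician noise has the right marginals and SNR anchoring", {
  des <- dtd_design(n = 200, seed = 6)
  p <- cntvd(0.8 * diag(3), omega_isotropic(0.01))
  S <- mc_signal(p, des, n = 20000, seed = 7)
  ds <- dtd_dataset(des, S)
  expect_identical(add_noise(ds, Inf, seed = 1), ds)
  noisy <- add_noise(ds, 10, seed = 2)
  sigma <- noisy$noise_sigma
  top <- ds$design$trace >= quantile(ds$design$trace, 0.95)
  expect_equal(sigma, mean(S[top]) / 10)
  # zero-signal magnitude is Rayleigh with mean sigma * sqrt(pi/2)
  set.seed(3)
  n <- 100000
  mag0 <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  expect_lt(abs(mean(mag0) - sigma * sqrt(pi / 2)),
            3 * sigma * sqrt((2 - pi / 2) / n))
  # S = 5 sigma: empirical magnitudes follow the Rician CDF
  A <- 5 * sigma
  mag <- sqrt((A + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  rice_cdf <- local({
    xs <- seq(0, A + 8 * sigma, length.out = 4000)
    pdf <- xs / sigma^2 * exp(-(xs^2 + A^2) / (2 * sigma^2)) *
      besselI(xs * A / sigma^2, 0, expon.scaled = TRUE) *
      exp(xs * A / sigma^2)
    cdf <- cumsum(pdf) * diff(xs[1:2])
    approxfun(xs, pmin(cdf / max(cdf), 1), yleft = 0, yright = 1)
  })
  expect_gt(ks.test(mag, rice_cdf)$p.value, 0.01)
})
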