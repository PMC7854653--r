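test_that("BIC algebra behaves as an information criterion should", {
  b0 <- bic(2, 100, 5)
  expect_equal(bic(1, 100, 5), b0 - 100 * log(2))      # halve rss at fixed k
  expect_equal(bic(2, 100, 6), b0 + log(100))          # useless extra param
  expect_warning(b <- bic(0, 100, 5), "zero residual")
  expect_identical(b, -Inf)
  expect_error(bic(1, 5, 10))
})

test_that("the parsimony selector honors the delta-BIC = 2 boundary", {
  tab <- data.frame(k = c(2, 5), bic = c(-100, -101.9))
  expect_equal(cntvd:::.select_parsimonious(tab, 2), 1L)   # within 2: simpler
  tab2 <- data.frame(k = c(2, 5), bic = c(-100, -102.1))
  expect_equal(cntvd:::.select_parsimonious(tab2, 2), 2L)  # beats it by > 2
  tab3 <- data.frame(k = c(4, 4), bic = c(-100, -100))
  expect_equal(cntvd:::.select_parsimonious(tab3, 2), 1L)  # exact tie: order
})

test_that("Frobenius error is the relative norm in percent", {
  A <- matrix(rnorm(36), 6, 6)
  expect_equal(frobenius_error(A, A), 0)
  expect_equal(frobenius_error(A, 1.1 * A), 10, tolerance = 1e-12)
  E <- matrix(rnorm(36), 6, 6)
  E <- E * (0.3 * sqrt(sum(A^2)) / sqrt(sum(E^2)))
  expect_equal(frobenius_error(A, A + E), 30, tolerance = 1e-9)
  expect_error(frobenius_error(matrix(0, 3, 3), diag(3)), "zero")
})

test_that("model classes carry the published parameter counts", {
  mc <- mean_classes()
  expect_equal(mc$n_params[mc$class == "noise"], 1L)
  expect_equal(mc$n_params[mc$class == "isotropic"], 2L)
  expect_equal(mc$n_params[mc$class == "prolate"], 5L)
  expect_equal(mc$n_params[mc$class == "general"], 7L)
  cc <- cov_classes()
  expect_equal(cc$n_params[cc$class == "isotropic"], 2L)
  expect_equal(cc$n_params[cc$class == "cubic"], 3L)
  expect_equal(cc$n_params[cc$class == "hexagonal"], 5L)
  expect_equal(cc$n_params[cc$class == "trigonal6"], 6L)
  expect_equal(cc$n_params[cc$class == "trigonal7"], 7L)
  expect_equal(cc$n_params[cc$class == "tetragonal6"], 6L)
  expect_equal(cc$n_params[cc$class == "tetragonal7"], 7L)
  expect_equal(cc$n_params[cc$class == "orthorhombic"], 9L)
  expect_equal(cc$n_params[cc$class == "monoclinic"], 13L)
  expect_equal(cc$n_params[cc$class == "triclinic"], 21L)
  # most general model: 7 mean (incl s0) + 21 covariance = 28 unknowns
  expect_equal(mc$n_params[mc$class == "general"] +
               cc$n_params[cc$class == "triclinic"], 28L)
})

test_that("covariance templates have the advertised structure", {
  # isotropic template with (lambda = 1, mu = 0): upper block of ones,
  # eigenvalues {3, 0, 0, 0, 0, 0}
  tpl <- cntvd:::.cov_templates$isotropic$lambda
  expect_equal(tpl[1:3, 1:3], matrix(1, 3, 3))
  expect_equal(sort(eigen(tpl, symmetric = TRUE)$values),
               c(0, 0, 0, 0, 0, 3))
  # every template basis matrix is symmetric
  for (cl in names(cntvd:::.cov_templates))
    for (Tm in cntvd:::.cov_templates[[cl]])
      expect_identical(Tm, t(Tm))
  # template counts match the class table
  cc <- cov_classes()
  for (i in seq_len(nrow(cc)))
    expect_length(cntvd:::.cov_templates[[cc$class[i]]], cc$n_params[i])
})

test_that("mean parameterizations produce physical tensors with proper frames", {
  set.seed(12)
  for (cl in c("isotropic", "prolate", "oblate", "general")) {
    for (i in 1:10) {
      th <- rnorm(cntvd:::.mean_npar_theta[[cl]], 0, 1)
      mm <- cntvd:::.mean_map(cl, th)
      expect_true(is_physical(mm$dbar))
      expect_lt(max(abs(crossprod(mm$frame) - diag(3))), 1e-12)
      expect_equal(det(mm$frame), 1, tolerance = 1e-12)
    }
  }
  # init/map round trip for a general tensor
  d6 <- dt_vector(dt_matrix(c(1.4, 0.7, 0.3, 0.1, -0.05, 0.08)))
  th <- cntvd:::.mean_init("general", d6)
  expect_equal(unname(cntvd:::.mean_map("general", th)$dbar), unname(d6),
               tolerance = 1e-8)
})

test_that("noiseless DTI data is recovered essentially exactly", {
  des <- dtd_design(n = 80, seed = 21)
  Dtrue <- dt_vector(dt_matrix(c(1.3, 0.6, 0.4, 0.15, 0, 0)))
  S <- dti_signal(Dtrue, 1.2, des)
  fit <- fit_dtd_model(dtd_dataset(des, S), "general", "none",
                       n_mc = 1000, seed = 1, n_restarts = 1, maxit = 300)
  expect_lt(frobenius_error(dt_matrix(Dtrue), dt_matrix(fit$params$mean)),
            1e-4)
  expect_equal(fit$params$s0, 1.2, tolerance = 1e-5)
  expect_equal(max(abs(fit$params$omega)), 0)
})

test_that("pure-noise data selects the one-parameter noise model", {
  des <- dtd_design(n = 100, seed = 22)
  set.seed(23)
  S <- abs(rnorm(100, 0.5, 0.05))
  fit <- dtd_fit(dtd_dataset(des, S), n_mc = 1000, seed = 3, n_restarts = 1,
                 maxit = 50, cov_shortlist = "isotropic")
  expect_equal(fit$selected$mean_class, "noise")
  expect_equal(fit$selected$cov_class, "none")
})

test_that("fitted parameters always satisfy the model invariants", {
  des <- dtd_design(n = 60, seed = 24)
  m <- dtd_motif("iso_emulsion", n = 4000, seed = 25)
  S <- mc_signal(m$params, des, n = 4000, seed = 26)
  fit <- fit_dtd_model(dtd_dataset(des, S), "isotropic", "isotropic",
                       n_mc = 4000, seed = 26, n_restarts = 1, maxit = 80)
  expect_true(is_psd_omega(fit$params$omega))
  expect_true(is_physical(fit$params$mean))
  expect_gte(fit$params$s0, 0)
  # reproducibility of the whole ladder under identical seeds
  f1 <- dtd_fit(dtd_dataset(des, S), n_mc = 2000, seed = 5, n_restarts = 1,
                maxit = 40, mean_shortlist = "isotropic",
                cov_shortlist = c("isotropic", "cubic"))
  f2 <- dtd_fit(dtd_dataset(des, S), n_mc = 2000, seed = 5, n_restarts = 1,
                maxit = 40, mean_shortlist = "isotropic",
                cov_shortlist = c("isotropic", "cubic"))
  expect_identical(f1$stage2$bic, f2$stage2$bic)
  expect_identical(coef(f1), coef(f2))
})

test_that("dtd_fit methods expose the usual modelling interface", {
  des <- dtd_design(n = 60, seed = 27)
  p <- cntvd(0.8 * diag(3), omega_isotropic(0.02), s0 = 1)
  S <- mc_signal(p, des, n = 4000, seed = 28)
  fit <- dtd_fit(dtd_dataset(des, S), n_mc = 4000, seed = 28, n_restarts = 1,
                 maxit = 60, mean_shortlist = "isotropic",
                 cov_shortlist = "isotropic")
  expect_s3_class(fit, "dtd_fit")
  expect_output(print(fit), "covariance class")
  expect_output(print(summary(fit)), "Stage 1")
  co <- coef(fit)
  expect_length(co, 1 + 6 + 21)
  expect_equal(unname(co["s0"]), fit$params$s0)
  expect_length(fitted(fit), 60)
  expect_equal(residuals(fit), S - fitted(fit))
  pr <- predict(fit, n = 2000, seed = 1)
  expect_length(pr, 60)
  sims <- simulate(fit, nsim = 2, seed = 9, n = 500)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "dtd_ensemble")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, type = "bic"))
})
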