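#' Monte Carlo MR signal of a CNTVD
#'
#' The signal at b-matrix b is `s0 * E[exp(-b6 . d6)]` over the constrained
#' distribution, approximated by the accepted-sample mean: one ensemble of `n`
#' proposals is drawn, filtered to the PSD cone, and reused across every
#' b-matrix of the design. `S(0) = s0` exactly, the signal lies in `[0, s0]`,
#' and it is monotone non-increasing under scaling of any b-matrix.
#'
#' @param params a [cntvd] object.
#' @param design a [dtd_design] (or anything accepted by [design_bvecs]).
#' @param n Monte Carlo proposals (default 200000; at least 1000 recommended).
#' @param seed integer seed for the proposal block.
#' @param z optional pre-drawn n x 6 standard normal matrix (common random
#'   numbers).
#' @return numeric signal vector, one value per design row.
#' @examples
#' p <- cntvd(0.8 * diag(3), omega_isotropic(0.01))
#' des <- dtd_design(n = 40, seed = 2)
#' S <- mc_signal(p, des, n = 20000, seed = 1)
#' @export
mc_signal <- function(params, design, n = 200000L, seed = 1L, z = NULL) {
  stopifnot(inherits(params, "cntvd"))
  Bv <- design_bvecs(design)
  if (all(params$omega == 0)) return(dti_signal(params$mean, params$s0, design))
  if (is.null(z)) {
    set.seed(as.integer(seed))
    z <- matrix(rnorm(n * 6L), n, 6L)
  }
  L <- .psd_factor(params$omega)
  D <- sweep(z %*% t(L), 2L, params$mean, "+")
  res <- cpp_mc_signal(D, Bv, .psd_tol)
  if (res$acc_frac < 1e-4)
    stop("distribution mass almost entirely outside the PSD cone ",
         "(acceptance fraction ", format(res$acc_frac), ")")
  if (res$acc_frac < 0.05)
    warning("low acceptance fraction (", format(res$acc_frac), ")")
  params$s0 * as.numeric(res$m)
}

#' Closed-form DTI signal (zero-covariance limit)
#'
#' `S = s0 * exp(-b6 . mean_d6)`, the mono-exponential tensor model.
#'
#' @param mean_d6 length-6 mean tensor (or 3x3 matrix).
#' @param s0 signal amplitude at b = 0.
#' @param design a [dtd_design].
#' @return numeric signal vector.
#' @export
dti_signal <- function(mean_d6, s0, design) {
  if (is.matrix(mean_d6)) mean_d6 <- dt_vector(mean_d6)
  Bv <- design_bvecs(design)
  as.numeric(s0 * exp(-Bv %*% mean_d6))
}

#' Second-order cumulant signal approximation
#'
#' `log(S/s0) = -b6 . mean + 0.5 * t(b6) %*% omega %*% b6`. Exact to second
#' order in b; for any direction with positive covariance projection the
#' predicted signal eventually *increases* with b and exceeds `s0` - the
#' unphysical large-b behaviour that motivates the constrained MC model.
#'
#' @inheritParams mc_signal
#' @return numeric signal vector.
#' @export
cumulant_signal <- function(params, design) {
  stopifnot(inherits(params, "cntvd"))
  Bv <- design_bvecs(design)
  lin <- as.numeric(Bv %*% params$mean)
  quad <- rowSums((Bv %*% params$omega) * Bv)
  params$s0 * exp(-lin + 0.5 * quad)
}

#' Kurtosis tensor from the covariance tensor
#'
#' Full symmetrization of the fourth-order covariance normalized by the
#' squared mean trace:
#' `K_ijkl = (C_ijkl + C_ikjl + C_iljk) / mean_trace^2`. `K` is symmetric
#' under all 24 index permutations and is the part of the covariance the
#' kurtosis model retains.
#'
#' @param params a [cntvd] object with positive mean trace.
#' @return 3x3x3x3 fully symmetric array (dimensionless).
#' @export
kurtosis_from_covariance <- function(params) {
  stopifnot(inherits(params, "cntvd"))
  tr <- sum(params$mean[1:3])
  if (tr <= 0) stop("mean trace must be positive for the kurtosis normalization")
  C <- omega_to_ctensor(params$omega)
  K <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    K[i, j, k, l] <- (C[i, j, k, l] + C[i, k, j, l] + C[i, l, j, k]) / tr^2
  K
}

#' Kurtosis-model signal
#'
#' The cumulant form evaluated with the fully symmetrized covariance, i.e.
#' with omega replaced by the covariance rebuilt from the kurtosis tensor
#' times the squared mean trace. This isolates exactly the information the
#' kurtosis symmetrization discards (a convention: the kurtosis literature
#' writes no unique signal equation for general b-matrices).
#'
#' @inheritParams mc_signal
#' @return numeric signal vector.
#' @export
kurtosis_signal <- function(params, design) {
  stopifnot(inherits(params, "cntvd"))
  tr <- sum(params$mean[1:3])
  K <- kurtosis_from_covariance(params)
  omega_sym <- ctensor_to_omega(K * tr^2) / 3  # symmetrized covariance
  Bv <- design_bvecs(design)
  lin <- as.numeric(Bv %*% params$mean)
  quad <- rowSums((Bv %*% omega_sym) * Bv)
  params$s0 * exp(-lin + 0.5 * quad)
}

#' Signal dataset
#'
#' Pairs an acquisition design with the magnitude signal per b-matrix and the
#' noise level it was (or will be) corrupted with.
#'
#' @param design a [dtd_design].
#' @param signal numeric vector, one non-negative magnitude per design row.
#' @param snr signal-to-noise ratio at the largest b-values (`Inf` for
#'   noiseless).
#' @param noise_sigma Gaussian channel standard deviation, if already known.
#' @return object of class `"dtd_dataset"`.
#' @export
dtd_dataset <- function(design, signal, snr = Inf, noise_sigma = NA_real_) {
  stopifnot(nrow(design) == length(signal), all(signal >= 0), snr > 0)
  structure(list(design = design, signal = as.numeric(signal), snr = snr,
                 noise_sigma = noise_sigma), class = "dtd_dataset")
}

#' @export
print.dtd_dataset <- function(x, ...) {
  cat("DTD signal dataset:", nrow(x$design), "b-matrices, SNR =",
      format(x$snr), "\n")
  invisible(x)
}

#' Add Rician noise to a signal dataset
#'
#' Adds i.i.d. Gaussian noise of standard deviation sigma to the real and
#' imaginary channels and takes the magnitude:
#' `|S + e1 + i e2|` with `e ~ N(0, sigma^2)`. The noise scale is referenced
#' to the high-b signal level: `sigma` is the mean noiseless signal over the
#' b-matrices in the top 5% of trace, divided by `snr` ("SNR at the largest
#' b-value"). `snr = Inf` returns the dataset unchanged.
#'
#' @param dataset a [dtd_dataset] holding the noiseless signal.
#' @param snr target signal-to-noise ratio (> 0, or `Inf`).
#' @param seed integer seed.
#' @return a new [dtd_dataset] with noisy magnitudes and `noise_sigma` set.
#' @export
add_noise <- function(dataset, snr, seed = 1L) {
  stopifnot(inherits(dataset, "dtd_dataset"), snr > 0)
  if (!is.finite(snr)) return(dataset)
  tr <- dataset$design$trace
  top <- tr >= quantile(tr, 0.95)
  sigma <- mean(dataset$signal[top]) / snr
  set.seed(as.integer(seed))
  n <- length(dataset$signal)
  mag <- sqrt((dataset$signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  dtd_dataset(dataset$design, mag, snr = snr, noise_sigma = sigma)
}
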