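#' @export
print.dtd_fit <- function(x, ...) {
  cat("Diffusion tensor distribution fit (constrained tensor-variate model)\n")
  cat("  selected mean class:      ", x$selected$mean_class, "\n")
  cat("  selected covariance class:", x$selected$cov_class, "\n")
  cat("  parameters:", x$selected$n_params, " | RSS:", format(x$rss),
      " | BIC:", format(round(x$bic, 2)), "\n")
  cat("  s0:", format(round(x$params$s0, 4)), "\n")
  cat("  mean eigenvalues (um^2/ms):",
      paste(format(round(dt_eigenvalues(x$params$mean), 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Summary of a DTD fit
#'
#' Prints the selected classes, the full BIC ladder of both selection stages,
#' and the fitted parameters.
#' @param object a `dtd_fit`.
#' @param ... unused.
#' @export
summary.dtd_fit <- function(object, ...) {
  out <- list(selected = object$selected,
              stage1 = object$stage1, stage2 = object$stage2,
              params = object$params, rss = object$rss, bic = object$bic,
              converged = object$converged)
  class(out) <- "summary.dtd_fit"
  out
}

#' @export
print.summary.dtd_fit <- function(x, ...) {
  cat("Two-stage nested-model selection\n\nStage 1 (mean class, covariance = 0):\n")
  print(x$stage1, row.names = FALSE)
  cat("\nStage 2 (covariance class):\n")
  print(x$stage2, row.names = FALSE)
  cat("\nSelected:", x$selected$mean_class, "+", x$selected$cov_class,
      "(", x$selected$n_params, "parameters )\n\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.dtd_fit <- function(object, ...) {
  om <- object$params$omega
  ut <- which(upper.tri(om, diag = TRUE), arr.ind = TRUE)
  cov_par <- om[upper.tri(om, diag = TRUE)]
  names(cov_par) <- paste0("omega_", .d6_names[ut[, 1]], ".", .d6_names[ut[, 2]])
  c(s0 = object$params$s0,
    setNames(object$params$mean, paste0("mean_", .d6_names)), cov_par)
}

#' Predict the MR signal of a fitted DTD
#'
#' @param object a `dtd_fit`.
#' @param newdesign a [dtd_design]; defaults to the training design.
#' @param n Monte Carlo proposals.
#' @param seed seed for the forward simulation.
#' @param ... unused.
#' @return numeric signal vector.
#' @export
predict.dtd_fit <- function(object, newdesign = NULL, n = 50000L, seed = 1L,
                            ...) {
  if (is.null(newdesign)) newdesign <- object$dataset$design
  mc_signal(object$params, newdesign, n = n, seed = seed)
}

#' @export
fitted.dtd_fit <- function(object, ...) object$fitted_values

#' @export
residuals.dtd_fit <- function(object, ...)
  object$dataset$signal - object$fitted_values

#' Draw micro-tensor ensembles from a fitted DTD
#'
#' @param object a `dtd_fit`.
#' @param nsim number of ensembles.
#' @param seed integer seed.
#' @param n tensors proposed per ensemble.
#' @param ... unused.
#' @return list of `dtd_ensemble` objects (length `nsim`).
#' @export
simulate.dtd_fit <- function(object, nsim = 1, seed = 1L, n = 10000L, ...) {
  lapply(seq_len(nsim), function(i)
    sample_cntvd(object$params, n = n, seed = as.integer(seed) + i - 1L))
}

#' Plot a DTD fit
#'
#' `type = "signal"` plots observed and fitted signal against b-matrix trace;
#' `type = "bic"` shows the stage-2 BIC ladder across covariance classes.
#' @param x a `dtd_fit`.
#' @param type `"signal"` or `"bic"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.dtd_fit <- function(x, type = c("signal", "bic"), ...) {
  type <- match.arg(type)
  if (type == "signal") {
    tr <- x$dataset$design$trace
    plot(tr, x$dataset$signal, pch = 1, xlab = "b-matrix trace (ms/um^2)",
         ylab = "signal", main = "observed vs fitted MR signal", ...)
    points(tr, x$fitted_values, pch = 16, col = "red3", cex = 0.6)
    legend("topright", legend = c("observed", "fitted"), pch = c(1, 16),
           col = c("black", "red3"), bty = "n")
  } else {
    b <- x$stage2$bic
    names(b) <- x$stage2$cov_class
    barplot(b - min(b[is.finite(b)]), las = 2, ylab = "delta BIC",
            main = "covariance class ladder", ...)
    abline(h = x$config$delta_bic, lty = 2)
  }
  invisible(x)
}
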