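# CSV/JSON serialization. All files carry explicit unit and convention
# headers; loaders validate them so the factor-2 off-diagonal convention can
# never silently flip.

.design_marker <- "# bmatrix_convention: plain_offdiag; units: ms/um^2"
.signal_marker <- "# signal_units: arbitrary"
.ensemble_marker <- "# tensor_convention: d6 plain; units: um^2/ms"

#' Write / read an acquisition design CSV
#'
#' Columns `id, rank, bxx, byy, bzz, bxy, bxz, byz, trace` with *plain*
#' matrix entries (the factor-2 doubling of off-diagonals is applied on load
#' when b-vectors are formed). A convention marker line is required in the
#' header and written automatically.
#'
#' @param design a [dtd_design].
#' @param path CSV path.
#' @return `read_design_csv` returns a `dtd_design`.
#' @export
write_design_csv <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.design_marker, con)
  write.csv(as.data.frame(design), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, .design_marker))
    stop("design CSV missing its convention marker line '", .design_marker,
         "': refusing to guess whether off-diagonals are doubled")
  df <- read.csv(path, skip = 1L)
  need <- c("id", "rank", "bxx", "byy", "bzz", "bxy", "bxz", "byz", "trace")
  if (!all(need %in% names(df))) stop("design CSV missing columns: ",
                                      paste(setdiff(need, names(df)),
                                            collapse = ", "))
  if (anyNA(df[need])) stop("design CSV contains NA values")
  if (anyDuplicated(df$id)) stop("design CSV contains duplicate ids")
  structure(df[need], b_range = range(df$trace), rank_mix = mean(df$rank == 1),
            seed = NA_integer_, class = c("dtd_design", "data.frame"))
}

#' Write / read a signal CSV
#'
#' Columns `id, signal`, paired to a design by `id`.
#' @param signal numeric vector or [dtd_dataset].
#' @param design the paired [dtd_design] (for ids).
#' @param path CSV path.
#' @export
write_signal_csv <- function(signal, design, path) {
  if (inherits(signal, "dtd_dataset")) {
    design <- signal$design
    signal <- signal$signal
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.signal_marker, con)
  write.csv(data.frame(id = design$id, signal = signal), con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, .signal_marker))
    stop("signal CSV missing its marker line '", .signal_marker, "'")
  df <- read.csv(path, skip = 1L)
  if (!all(c("id", "signal") %in% names(df))) stop("signal CSV needs id, signal")
  if (anyNA(df)) stop("signal CSV contains NA values")
  if (anyDuplicated(df$id)) stop("signal CSV contains duplicate ids")
  df
}

#' Write a tensor ensemble CSV
#'
#' One row per micro tensor: the six components plus the sorted eigenvalues.
#' @param ensemble `dtd_ensemble`, `dtd_motif` or n x 6 matrix.
#' @param path CSV path.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  X <- as_sample_matrix(ensemble)
  ev <- t(apply(X, 1L, dt_eigenvalues))
  colnames(ev) <- c("lambda1", "lambda2", "lambda3")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.ensemble_marker, con)
  write.csv(cbind(as.data.frame(X), as.data.frame(ev)), con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, .ensemble_marker))
    stop("ensemble CSV missing its marker line '", .ensemble_marker, "'")
  df <- read.csv(path, skip = 1L)
  X <- as.matrix(df[, .d6_names])
  structure(list(samples = X, n_proposed = nrow(X), acc_frac = 1,
                 seed = NA_integer_), class = "dtd_ensemble")
}

#' Serialize CNTVD parameters / fit results as JSON
#'
#' Versioned JSON with explicit units; `read_params_json` validates the
#' parameter invariants on load.
#'
#' @param params a [cntvd] object (or [dtd_fit] for `write_fit_json`).
#' @param path JSON path.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "cntvd"))
  jsonlite::write_json(list(
    schema = "cntvd-params-v1",
    units = list(mean = "um^2/ms", omega = "(um^2/ms)^2"),
    s0 = params$s0, mean_d6 = as.numeric(params$mean),
    omega = params$omega), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "cntvd-params-v1"))
    stop("unrecognized parameter JSON schema: ", x$schema)
  cntvd(as.numeric(x$mean_d6), as.matrix(x$omega), x$s0)
}

#' @rdname write_params_json
#' @param fit a [dtd_fit].
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dtd_fit"))
  jsonlite::write_json(list(
    schema = "dtd-fit-v1",
    package_version = as.character(utils::packageVersion("cntvd")),
    selected = fit$selected,
    s0 = fit$params$s0, mean_d6 = as.numeric(fit$params$mean),
    omega = fit$params$omega, rss = fit$rss, bic = fit$bic,
    stage1 = fit$stage1, stage2 = fit$stage2,
    config = fit$config, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "dtd-fit-v1"))
    stop("unrecognized fit JSON schema: ", x$schema)
  x$params <- cntvd(as.numeric(x$mean_d6), as.matrix(x$omega), x$s0)
  x
}
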