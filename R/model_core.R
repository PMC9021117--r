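# Domain objects: continuous-time and discrete-time VAR models and
# irregularly sampled time series.

#' Continuous-time VAR (Ornstein-Uhlenbeck) model
#'
#' Constructs a continuous-time first-order vector autoregression, i.e. the
#' linear stochastic differential equation
#' \deqn{dY(t)/dt = A (Y(t) - \mu) + W(t),}
#' where `A` is the p x p *drift matrix* of moment-to-moment effects
#' (diagonal auto-effects, off-diagonal cross-effects), `W(t)` is a Wiener
#' input with covariance rate `diffusion`, and `mu` is the equilibrium.
#' By the centered convention the equilibrium defaults to zero.
#'
#' Drift rates are per unit time; the time unit (e.g. hours) is the user's
#' responsibility and must match the timestamps of any data the model is
#' combined with.
#'
#' @param drift p x p numeric drift matrix `A`.
#' @param diffusion p x p symmetric positive semi-definite covariance rate of
#'   the Wiener input. Defaults to the identity.
#' @param equilibrium length-p equilibrium vector; defaults to zeros.
#' @param labels character vector of p variable names.
#' @param tol relative tolerance for the symmetry/PSD checks on `diffusion`.
#' @return An object of class `"ctmodel"`.
#' @seealso [validate_ct()], [lagged_params()], [sample_ou_path()]
#' @examples
#' m <- ct_model(matrix(c(-1, 1.5, 0, -1), 2, 2, byrow = TRUE),
#'               labels = c("stress", "anxiety"))
#' is_stable(m)
#' @export
ct_model <- function(drift, diffusion = NULL, equilibrium = NULL,
                     labels = NULL, tol = 1e-8) {
  drift <- as.matrix(drift)
  if (nrow(drift) != ncol(drift)) stop("'drift' must be a square matrix")
  if (!all(is.finite(drift))) stop("'drift' must be finite")
  p <- nrow(drift)
  if (is.null(diffusion)) diffusion <- diag(p)
  diffusion <- as.matrix(diffusion)
  if (!identical(dim(diffusion), dim(drift)))
    stop("'diffusion' must be ", p, " x ", p)
  if (!is_symmetric_tol(diffusion, tol))
    stop("'diffusion' is not symmetric within tolerance")
  diffusion <- (diffusion + t(diffusion)) / 2
  if (!is_psd_tol(diffusion))
    stop("'diffusion' has a negative eigenvalue beyond tolerance")
  if (is.null(equilibrium)) equilibrium <- rep(0, p)
  if (length(equilibrium) != p || !all(is.finite(equilibrium)))
    stop("'equilibrium' must be a finite length-", p, " vector")
  if (is.null(labels)) labels <- colnames(drift)
  if (is.null(labels)) labels <- paste0("Y", seq_len(p))
  if (length(labels) != p) stop("'labels' must have length ", p)
  labels <- as.character(labels)
  dimnames(drift) <- dimnames(diffusion) <- list(labels, labels)
  structure(
    list(drift = drift, diffusion = diffusion,
         equilibrium = stats::setNames(as.numeric(equilibrium), labels),
         labels = labels),
    class = "ctmodel")
}

#' Discrete-time VAR(1) model
#'
#' Constructs a first-order discrete-time vector autoregression
#' \deqn{Y_\tau = c + \Phi Y_{\tau-1} + \epsilon_\tau,}
#' with lagged-parameter matrix `lagged` referring to one fixed
#' measurement interval, residual covariance `residual_cov`, and intercept
#' `c` (zero under the centered convention).
#'
#' @param lagged p x p lagged regression matrix `Phi`.
#' @param interval positive time-interval the lagged matrix refers to.
#' @param residual_cov p x p symmetric PSD residual covariance; defaults to
#'   the identity.
#' @param intercept length-p intercept vector; defaults to zeros.
#' @param labels character vector of p variable names.
#' @param tol relative tolerance for symmetry/PSD checks.
#' @return An object of class `"dtmodel"`.
#' @examples
#' d <- dt_model(matrix(c(0.5, 0.1, 0, 0.6), 2, 2), interval = 1)
#' is_stationary(d)
#' dt_equilibrium(d)
#' @export
dt_model <- function(lagged, interval = 1, residual_cov = NULL,
                     intercept = NULL, labels = NULL, tol = 1e-8) {
  lagged <- as.matrix(lagged)
  if (nrow(lagged) != ncol(lagged)) stop("'lagged' must be a square matrix")
  if (!all(is.finite(lagged))) stop("'lagged' must be finite")
  p <- nrow(lagged)
  if (!is.numeric(interval) || length(interval) != 1L ||
      !is.finite(interval) || interval <= 0)
    stop("'interval' must be a positive number")
  if (is.null(residual_cov)) residual_cov <- diag(p)
  residual_cov <- as.matrix(residual_cov)
  if (!identical(dim(residual_cov), dim(lagged)))
    stop("'residual_cov' must be ", p, " x ", p)
  if (!is_symmetric_tol(residual_cov, tol))
    stop("'residual_cov' is not symmetric within tolerance")
  residual_cov <- (residual_cov + t(residual_cov)) / 2
  if (!is_psd_tol(residual_cov))
    stop("'residual_cov' has a negative eigenvalue beyond tolerance")
  if (is.null(intercept)) intercept <- rep(0, p)
  if (length(intercept) != p || !all(is.finite(intercept)))
    stop("'intercept' must be a finite length-", p, " vector")
  if (is.null(labels)) labels <- colnames(lagged)
  if (is.null(labels)) labels <- paste0("Y", seq_len(p))
  if (length(labels) != p) stop("'labels' must have length ", p)
  labels <- as.character(labels)
  dimnames(lagged) <- dimnames(residual_cov) <- list(labels, labels)
  structure(
    list(lagged = lagged, interval = as.numeric(interval),
         residual_cov = residual_cov,
         intercept = stats::setNames(as.numeric(intercept), labels),
         labels = labels),
    class = "dtmodel")
}

#' Irregularly sampled multivariate time series
#'
#' Bundles timestamped multivariate observations. Times must be strictly
#' increasing and share the time unit of any model the data are used with.
#' Missing entries are allowed as `NA`.
#'
#' @param times length-n strictly increasing numeric timestamps.
#' @param values n x p numeric matrix of observations (rows = occasions).
#' @param labels character vector of p variable names.
#' @return An object of class `"irts"` with elements `times`, `values`,
#'   `labels`.
#' @export
irregular_ts <- function(times, values, labels = NULL) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (!all(is.finite(times))) stop("'times' must be finite")
  if (is.unsorted(times, strictly = TRUE)) {
    d <- which(diff(times) <= 0)[1]
    stop("'times' must be strictly increasing; violation at time ",
         format(times[d + 1]))
  }
  if (nrow(values) != length(times))
    stop("'values' must have one row per time point")
  storage.mode(values) <- "double"
  p <- ncol(values)
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("Y", seq_len(p))
  if (length(labels) != p) stop("'labels' must have length ", p)
  colnames(values) <- labels
  structure(list(times = times, values = values,
                 labels = as.character(labels)),
            class = "irts")
}

#' Stability of a continuous-time model
#'
#' A CT model is stable (mean-reverting) iff every eigenvalue of the drift
#' matrix has strictly negative real part.
#'
#' @param model a `"ctmodel"`.
#' @return logical.
#' @export
is_stable <- function(model) {
  stopifnot(inherits(model, "ctmodel"))
  all(Re(eigen(model$drift, only.values = TRUE)$values) < 0)
}

#' Stationarity of a discrete-time model
#'
#' A DT-VAR(1) is stationary iff the spectral radius of the lagged matrix is
#' below one.
#'
#' @param model a `"dtmodel"`.
#' @return logical.
#' @export
is_stationary <- function(model) {
  stopifnot(inherits(model, "dtmodel"))
  max(Mod(eigen(model$lagged, only.values = TRUE)$values)) < 1
}

#' Validate a continuous-time model
#'
#' Reports the drift eigenvalues, the stability flag, and soft warnings:
#' non-negative diagonal drift entries (auto-effects are typically negative
#' for mean-reverting psychological processes) are flagged but not treated
#' as errors.
#'
#' @param model a `"ctmodel"`.
#' @return A list with `stable` (logical), `eigenvalues` (complex), and
#'   `warnings` (character vector, possibly empty).
#' @examples
#' validate_ct(ct_model(-diag(2)))
#' @export
validate_ct <- function(model) {
  stopifnot(inherits(model, "ctmodel"))
  ev <- eigen(model$drift, only.values = TRUE)$values
  warnings <- character(0)
  nonneg <- which(diag(model$drift) >= 0)
  if (length(nonneg))
    warnings <- c(warnings, paste0(
      "non-negative auto-effect(s) for: ",
      paste(model$labels[nonneg], collapse = ", ")))
  stable <- all(Re(ev) < 0)
  if (!stable)
    warnings <- c(warnings,
                  "drift has an eigenvalue with non-negative real part: model is not stable")
  list(stable = stable, eigenvalues = ev, warnings = warnings)
}

#' Equilibrium (mean) of a discrete-time VAR model
#'
#' Returns the fixed point \eqn{\mu = (I - \Phi)^{-1} c} of the mean
#' recursion; under the centered convention (`c = 0`) this is the zero
#' vector.
#'
#' @param model a `"dtmodel"`; must be stationary.
#' @return length-p named numeric vector.
#' @export
dt_equilibrium <- function(model) {
  stopifnot(inherits(model, "dtmodel"))
  if (!is_stationary(model))
    stop("model is not stationary (spectral radius of lagged matrix >= 1); ",
         "equilibrium undefined")
  p <- length(model$labels)
  stats::setNames(
    as.numeric(solve(diag(p) - model$lagged, model$intercept)),
    model$labels)
}

#' @export
print.ctmodel <- function(x, ...) {
  p <- length(x$labels)
  cat("Continuous-time VAR model (", p, " variables: ",
      paste(x$labels, collapse = ", "), ")\n", sep = "")
  cat("Drift matrix A:\n")
  print(round(x$drift, 4))
  cat("Stable:", is_stable(x), "\n")
  invisible(x)
}

#' @export
print.dtmodel <- function(x, ...) {
  p <- length(x$labels)
  cat("Discrete-time VAR(1) model (", p, " variables, interval = ",
      x$interval, ")\n", sep = "")
  cat("Lagged matrix Phi:\n")
  print(round(x$lagged, 4))
  cat("Stationary:", is_stationary(x), "\n")
  invisible(x)
}

#' @export
print.irts <- function(x, ...) {
  cat("Irregular time series: ", length(x$times), " occasions, ",
      length(x$labels), " variables (", paste(x$labels, collapse = ", "),
      ")\n", sep = "")
  cat("Time range: [", format(min(x$times)), ", ", format(max(x$times)),
      "]; median interval ", format(stats::median(diff(x$times))),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a model to JSON
#'
#' CT models are written as `{kind, labels, drift, diffusion, equilibrium}`;
#' DT models as `{kind, labels, lagged, interval, residual_cov, intercept}`.
#'
#' @param model a `"ctmodel"` or `"dtmodel"`.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ctmodel")) {
    obj <- list(kind = "ct", labels = model$labels,
                drift = unname(model$drift),
                diffusion = unname(model$diffusion),
                equilibrium = unname(model$equilibrium))
  } else if (inherits(model, "dtmodel")) {
    obj <- list(kind = "dt", labels = model$labels,
                lagged = unname(model$lagged), interval = model$interval,
                residual_cov = unname(model$residual_cov),
                intercept = unname(model$intercept))
  } else stop("'model' must be a ctmodel or dtmodel")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path file written by [write_model()].
#' @return a `"ctmodel"` or `"dtmodel"`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tomat <- function(x) {
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  if (identical(obj$kind, "ct")) {
    ct_model(tomat(obj$drift), tomat(obj$diffusion),
             obj$equilibrium, obj$labels)
  } else if (identical(obj$kind, "dt")) {
    dt_model(tomat(obj$lagged), obj$interval, tomat(obj$residual_cov),
             obj$intercept, obj$labels)
  } else stop("unknown model kind in ", path)
}

#' Write a labeled matrix as CSV
#'
#' Header row and index column carry the variable labels, so the file is
#' self-describing.
#'
#' @param M labeled square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' Read a labeled matrix from CSV
#'
#' @param path file written by [write_matrix_csv()].
#' @return a labeled matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
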