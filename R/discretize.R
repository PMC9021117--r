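# Exact mappings between the continuous-time and discrete-time
# representations of a first-order linear system.

#' Lagged parameters implied at a given time-interval
#'
#' The lagged regression matrix linking observations a time-interval `dt`
#' apart is the matrix exponential of the drift matrix scaled by the
#' interval, \eqn{\Phi(\Delta t) = e^{A \Delta t}}. At `dt = 0` this is the
#' identity; for a stable model it decays to the zero matrix as `dt` grows.
#'
#' @param model a `"ctmodel"` (or a bare drift matrix).
#' @param dt a single non-negative time-interval.
#' @return p x p labeled lagged matrix.
#' @examples
#' m <- ct_model(diag(c(-1, -2)))
#' lagged_params(m, 1)  # diag(exp(-1), exp(-2))
#' @export
lagged_params <- function(model, dt) {
  A <- if (inherits(model, "ctmodel")) model$drift else as.matrix(model)
  dt <- check_dt(dt)
  if (length(dt) != 1L) stop("'dt' must be a single value")
  E <- matexp(A * dt)
  dimnames(E) <- dimnames(A)
  E
}

#' Stationary covariance of a stable continuous-time model
#'
#' Returns the unique solution `G` of the continuous Lyapunov equation
#' \eqn{A \Gamma + \Gamma A' + Q = 0}, the covariance of the process in its
#' stationary (equilibrium) distribution.
#'
#' @param model a stable `"ctmodel"`.
#' @return p x p labeled PSD matrix.
#' @export
stationary_cov <- function(model) {
  stopifnot(inherits(model, "ctmodel"))
  if (!is_stable(model))
    stop("drift is not stable: stationary covariance undefined")
  G <- lyap_ct(model$drift, model$diffusion)
  dimnames(G) <- dimnames(model$drift)
  G
}

#' Residual covariance implied at a given time-interval
#'
#' The covariance of the CT-VAR residual over an interval `dt`,
#' \eqn{\Sigma(\Delta t) = \Gamma - e^{A\Delta t}\,\Gamma\,e^{A'\Delta t}}
#' with `Gamma` the stationary covariance. It is the zero matrix at
#' `dt = 0` and grows (in the Loewner order) to `Gamma` as `dt` increases.
#'
#' @param model a stable `"ctmodel"`.
#' @param dt a single non-negative time-interval.
#' @return p x p labeled PSD matrix.
#' @export
residual_cov <- function(model, dt) {
  stopifnot(inherits(model, "ctmodel"))
  dt <- check_dt(dt)
  if (length(dt) != 1L) stop("'dt' must be a single value")
  G <- stationary_cov(model)
  E <- matexp(model$drift * dt)
  S <- G - E %*% G %*% t(E)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(model$drift)
  S
}

#' Convert a discrete-time model to its continuous-time counterpart
#'
#' Inverts the discretization: the drift is the principal matrix logarithm
#' of the lagged matrix divided by its reference interval, and the
#' diffusion is recovered from the residual covariance through the
#' stationary covariance. Only lagged matrices with no eigenvalue on the
#' closed negative real axis (i.e. positive auto-regression systems) have a
#' real CT counterpart; others raise an error. Because the complex
#' logarithm is multivalued, several drift matrices can be consistent with
#' one lagged matrix (aliasing); only the principal branch is returned and
#' a warning is attached when the lagged matrix has complex eigenvalues.
#'
#' @param model a `"dtmodel"` with nonsingular lagged matrix.
#' @return a `"ctmodel"`.
#' @examples
#' d <- dt_model(matrix(0.5), interval = 1)
#' dt_to_ct(d)$drift  # log(0.5)
#' @export
dt_to_ct <- function(model) {
  stopifnot(inherits(model, "dtmodel"))
  Phi <- model$lagged
  ev <- eigen(Phi, only.values = TRUE)$values
  if (any(Mod(ev) < 1e-12))
    stop("lagged matrix is singular: no CT representation")
  A <- matlog(Phi) / model$interval
  resid <- max(abs(matexp(A * model$interval) - Phi))
  if (resid > 1e-6)
    stop("matrix logarithm failed to invert the discretization ",
         "(residual ", format(resid), "); possible aliasing")
  if (any(abs(Im(ev)) > 1e-12 * (Mod(ev) + 1)))
    warning("lagged matrix has complex eigenvalues: the principal-branch ",
            "drift returned is one of several CT models consistent with it ",
            "(aliasing)")
  # Map the DT residual covariance back to a diffusion rate via the
  # stationary covariance of the DT recursion.
  Q <- NULL
  if (max(Mod(ev)) < 1) {
    G <- lyap_dt(Phi, model$residual_cov)
    Q <- -(A %*% G + G %*% t(A))
    Q <- (Q + t(Q)) / 2
    if (!is_psd_tol(Q, tol = 1e-6)) Q <- nearest_psd(Q)
  }
  mu <- tryCatch(dt_equilibrium(model), error = function(e) rep(0, nrow(Phi)))
  ct_model(A, diffusion = Q, equilibrium = mu, labels = model$labels)
}

#' Lagged-parameter curves over a grid of time-intervals
#'
#' Evaluates \eqn{\Phi(\Delta t) = e^{A\Delta t}} on a grid and summarizes,
#' per entry, the interval of maximum absolute value -- the interval at
#' which that lagged relationship is expected to peak.
#'
#' @param model a `"ctmodel"`.
#' @param grid strictly increasing vector of non-negative intervals;
#'   defaults to 0 to 5 time units in steps of 0.05.
#' @return An object of class `"phi_curve"`: a list with `grid`, `matrices`
#'   (p x p x length(grid) array), `labels`, and `peak_dt` (p x p matrix of
#'   intervals of maximum absolute value). Convert with
#'   [as.data.frame.phi_curve()] for a tidy layout.
#' @export
phi_curve <- function(model, grid = seq(0, 5, by = 0.05)) {
  stopifnot(inherits(model, "ctmodel"))
  grid <- check_grid(grid)
  p <- length(model$labels)
  mats <- vapply(grid, function(dt) matexp(model$drift * dt),
                 matrix(0, p, p))
  peak <- matrix(grid[apply(abs(mats), c(1, 2), which.max)], p, p,
                 dimnames = dimnames(model$drift))
  structure(list(grid = grid, matrices = mats, labels = model$labels,
                 peak_dt = peak, model = model),
            class = "phi_curve")
}

#' @export
print.phi_curve <- function(x, ...) {
  cat("Lagged-parameter curve on", length(x$grid), "intervals in [",
      format(min(x$grid)), ",", format(max(x$grid)), "]\n")
  cat("Peak |value| intervals per entry (row = to, col = from):\n")
  print(x$peak_dt)
  invisible(x)
}

#' Tidy layout of a lagged-parameter curve
#'
#' @param x a `"phi_curve"`.
#' @param ... unused.
#' @return data frame with columns `dt`, `from`, `to`, `value`, where
#'   `value` is the lagged effect of `from` on `to` at interval `dt`.
#' @export
as.data.frame.phi_curve <- function(x, ...) {
  p <- length(x$labels)
  n <- length(x$grid)
  data.frame(
    dt = rep(x$grid, each = p * p),
    from = rep(rep(x$labels, each = p), times = n),
    to = rep(x$labels, times = p * n),
    value = as.vector(x$matrices),
    stringsAsFactors = FALSE)
}

#' Sign switches of lagged parameters over the time-interval
#'
#' Scans every entry of a lagged-parameter curve for sign changes between
#' adjacent grid points and refines each crossing by bisection on the
#' closed-form curve to a bracket of width 1e-4. A sign switch indicates an
#' effect that is, e.g., negative at short intervals (dominated by a direct
#' pathway) and positive at longer intervals (dominated by indirect
#' pathways).
#'
#' @param curve a `"phi_curve"` with at least two grid points.
#' @param tol bracket width for the bisection refinement.
#' @return data frame with columns `from`, `to`, `dt_lower`, `dt_upper`,
#'   `dt` (bracket midpoint); zero rows when no entry switches sign.
#' @export
sign_switch_report <- function(curve, tol = 1e-4) {
  stopifnot(inherits(curve, "phi_curve"))
  if (length(curve$grid) < 2L) stop("curve needs at least 2 grid points")
  A <- curve$model$drift
  labels <- curve$labels
  p <- length(labels)
  out <- list()
  entry_fun <- function(i, j) function(dt) matexp(A * dt)[j, i]
  for (i in seq_len(p)) for (j in seq_len(p)) {
    v <- curve$matrices[j, i, ]
    s <- sign(v)
    # treat exact zeros as the sign of the previous point to avoid
    # double-counting a tangential touch
    chg <- which(s[-1] * s[-length(s)] < 0)
    f <- entry_fun(i, j)
    for (k in chg) {
      lo <- curve$grid[k]; hi <- curve$grid[k + 1]
      flo <- f(lo)
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        fm <- f(mid)
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      out[[length(out) + 1L]] <- data.frame(
        from = labels[i], to = labels[j],
        dt_lower = lo, dt_upper = hi, dt = (lo + hi) / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(from = character(0), to = character(0),
                  dt_lower = numeric(0), dt_upper = numeric(0),
                  dt = numeric(0), stringsAsFactors = FALSE)
}
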