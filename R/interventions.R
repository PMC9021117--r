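# Pulse and press do-interventions: expected trajectories, clamped
# dynamics, post-press equilibria and pressed-system stability.
#
# Trajectories here are expected values of the (linear) system; stochastic
# sample paths live in sample_ou_path().

#' Intervention specification
#'
#' Describes a do-intervention: a *pulse* sets the target variables to the
#' given values at a single instant; a *press* holds them at those values
#' over a window (indefinitely by default).
#'
#' @param mode `"pulse"` or `"press"`.
#' @param targets labels or indices of intervened variables (non-empty,
#'   distinct).
#' @param values numeric values, one per target (recycled if scalar).
#' @param start intervention start time (default 0).
#' @param duration press duration; `Inf` for an indefinite press. Ignored
#'   for pulses.
#' @return Object of class `"intervention"`.
#' @export
intervention <- function(mode = c("pulse", "press"), targets, values,
                         start = 0, duration = Inf) {
  mode <- match.arg(mode)
  if (length(values) == 1L) values <- rep(values, length(targets))
  if (length(values) != length(targets))
    stop("'values' must have one entry per target")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(start) || length(start) != 1L || !is.finite(start))
    stop("'start' must be a finite number")
  if (mode == "press" &&
      (!is.numeric(duration) || length(duration) != 1L || duration <= 0))
    stop("'duration' must be a positive number or Inf")
  structure(list(mode = mode, targets = targets,
                 values = as.numeric(values), start = start,
                 duration = duration),
            class = "intervention")
}

new_trajectory <- function(times, states, labels, spec) {
  colnames(states) <- labels
  structure(list(times = times, states = states, spec = spec,
                 labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Expected trajectory under a ", x$spec$mode, " intervention (",
      length(x$times), " time points in [", format(min(x$times)), ", ",
      format(max(x$times)), "])\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  p <- length(x$labels)
  data.frame(t = rep(x$times, times = p),
             node = rep(x$labels, each = length(x$times)),
             value = as.vector(x$states),
             stringsAsFactors = FALSE)
}

#' Expected trajectory after a pulse intervention
#'
#' Sets the target variables to the pulse values at time 0 (all other
#' variables at equilibrium) and propagates the expected state,
#' \eqn{E[Y(t)] = \mu + e^{At}(y_0 - \mu)}. For a stable model every
#' component returns to equilibrium as `t` grows.
#'
#' @param model a `"ctmodel"`. An unstable model triggers a warning (the
#'   divergent expected trajectory is still well defined).
#' @param spec a pulse [intervention()].
#' @param grid increasing time grid starting at 0.
#' @return a `"trajectory"`.
#' @export
pulse_trajectory <- function(model, spec, grid = seq(0, 5, by = 0.02)) {
  stopifnot(inherits(model, "ctmodel"), inherits(spec, "intervention"))
  if (spec$mode != "pulse") stop("'spec' must be a pulse intervention")
  grid <- check_grid(grid)
  if (!is_stable(model))
    warning("model is not stable: pulse trajectory diverges")
  S <- resolve_nodes(spec$targets, model$labels, "targets")
  mu <- model$equilibrium
  y0 <- mu
  y0[S] <- spec$values
  res <- vapply(grid, function(t)
    as.numeric(mu + matexp(model$drift * t) %*% (y0 - mu)),
    numeric(length(mu)))
  states <- matrix(t(res), length(grid), length(mu))
  new_trajectory(grid, states, model$labels, spec)
}

#' Equilibrium of the system under an indefinite press
#'
#' With targets `S` held at values `v`, the free variables settle at the
#' solution of \eqn{A_{-S,-S}(y - \mu_{-S}) + A_{-S,S}(v - \mu_S) = 0}.
#' Returns the full state vector (pressed components at their set values).
#'
#' @param model a `"ctmodel"` whose free-subsystem drift is nonsingular.
#' @param targets pressed variables (labels or indices).
#' @param values press values, one per target (recycled if scalar).
#' @return named length-p numeric vector.
#' @examples
#' m <- ct_model(matrix(c(-1, 0, 0.5, -1), 2, 2))
#' press_equilibrium(m, 2, 1)  # free variable settles at 0.5
#' @export
press_equilibrium <- function(model, targets, values) {
  stopifnot(inherits(model, "ctmodel"))
  S <- resolve_nodes(targets, model$labels, "targets")
  p <- length(model$labels)
  if (length(S) >= p) stop("press on all variables leaves no free subsystem")
  if (length(values) == 1L) values <- rep(values, length(S))
  stopifnot(length(values) == length(S), all(is.finite(values)))
  A <- model$drift
  mu <- model$equilibrium
  Aff <- A[-S, -S, drop = FALSE]
  if (abs(det(Aff)) < 1e-12) {
    ev <- eigen(Aff, only.values = TRUE)$values
    stop("free-subsystem drift is singular (eigenvalues: ",
         paste(format(ev, digits = 3), collapse = ", "),
         "): no press equilibrium")
  }
  out <- mu
  out[S] <- values
  out[-S] <- mu[-S] -
    as.numeric(solve(Aff, A[-S, S, drop = FALSE] %*% (values - mu[S])))
  out
}

#' Stability of the free subsystem under a press
#'
#' An indefinite press removes the pressed variables from the dynamics;
#' the remaining variables evolve under the principal submatrix
#' \eqn{A_{-S,-S}}. A system that is stable as a whole can have an
#' unstable pressed subsystem (and vice versa), so pressing can
#' destabilize the rest of the network.
#'
#' @param model a `"ctmodel"`.
#' @param targets pressed variables; a non-empty proper subset of nodes.
#' @return list with `eigenvalues` (of the free-subsystem drift) and
#'   `stable` (logical).
#' @export
press_stability <- function(model, targets) {
  stopifnot(inherits(model, "ctmodel"))
  S <- resolve_nodes(targets, model$labels, "targets")
  p <- length(model$labels)
  if (length(S) >= p) stop("press on all variables leaves no free subsystem")
  ev <- eigen(model$drift[-S, -S, drop = FALSE], only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0))
}

#' Expected trajectory under a press intervention
#'
#' Holds the targets at their press values from time 0; the free variables
#' follow \eqn{y_f(t) = y^* + e^{A_{ff} t}(y_{0f} - y^*)} where `y*` is the
#' [press_equilibrium()]. For a finite-duration press the full unpressed
#' dynamics resume from the release state.
#'
#' @param model a `"ctmodel"`.
#' @param spec a press [intervention()].
#' @param grid increasing time grid starting at 0.
#' @param init optional initial state (default: the model equilibrium).
#' @return a `"trajectory"`; pressed components are constant at their set
#'   values over the press window.
#' @export
press_trajectory <- function(model, spec, grid = seq(0, 5, by = 0.02),
                             init = NULL) {
  stopifnot(inherits(model, "ctmodel"), inherits(spec, "intervention"))
  if (spec$mode != "press") stop("'spec' must be a press intervention")
  grid <- check_grid(grid)
  S <- resolve_nodes(spec$targets, model$labels, "targets")
  p <- length(model$labels)
  if (length(S) >= p) stop("press on all variables leaves no free subsystem")
  mu <- model$equilibrium
  if (is.null(init)) init <- mu
  stopifnot(length(init) == p, all(is.finite(init)))
  ystar <- press_equilibrium(model, S, spec$values)
  Aff <- model$drift[-S, -S, drop = FALSE]
  t_rel <- spec$duration
  states <- matrix(NA_real_, length(grid), p)
  y_rel <- NULL
  state_at <- function(t) {
    y <- ystar
    y[-S] <- ystar[-S] +
      as.numeric(matexp(Aff * t) %*% (init[-S] - ystar[-S]))
    y
  }
  for (k in seq_along(grid)) {
    t <- grid[k]
    if (t <= t_rel) {
      states[k, ] <- state_at(t)
    } else {
      if (is.null(y_rel)) y_rel <- state_at(t_rel)
      states[k, ] <- mu +
        as.numeric(matexp(model$drift * (t - t_rel)) %*% (y_rel - mu))
    }
  }
  new_trajectory(grid, states, model$labels, spec)
}

#' Trajectory of a pulse with mediators clamped at equilibrium
#'
#' Combines a pulse on the given targets with press interventions holding
#' the clamp set at its equilibrium values: the clamped components stay
#' fixed for all `t` while the free components evolve under the
#' free-subsystem drift from the pulsed initial state. Component `j` of
#' this trajectory at time `dt`, for a unit pulse on `i`, equals
#' [direct_effect()]`(model, i, j, clamp, dt)`; the function therefore
#' doubles as the intervention-semantics oracle for the path-effect
#' module.
#'
#' @param model a `"ctmodel"`.
#' @param targets pulsed variables (disjoint from `clamp`).
#' @param values pulse values, one per target (recycled if scalar).
#' @param clamp variables press-held at equilibrium (may be empty, giving
#'   a plain pulse trajectory).
#' @param grid increasing time grid starting at 0.
#' @return a `"trajectory"`.
#' @export
clamped_trajectory <- function(model, targets, values, clamp,
                               grid = seq(0, 5, by = 0.02)) {
  stopifnot(inherits(model, "ctmodel"))
  grid <- check_grid(grid)
  S <- resolve_nodes(targets, model$labels, "targets")
  M <- resolve_nodes(clamp, model$labels, "clamp", allow_empty = TRUE)
  if (any(S %in% M)) stop("pulse targets must be disjoint from the clamp set")
  if (length(values) == 1L) values <- rep(values, length(S))
  stopifnot(length(values) == length(S), all(is.finite(values)))
  spec <- intervention("pulse", S, values)
  if (!length(M)) return(pulse_trajectory(model, spec, grid))
  p <- length(model$labels)
  mu <- model$equilibrium
  y0 <- mu
  y0[S] <- values
  Aff <- model$drift[-M, -M, drop = FALSE]
  states <- matrix(rep(mu, each = length(grid)), length(grid), p)
  res <- vapply(grid, function(t)
    as.numeric(matexp(Aff * t) %*% (y0[-M] - mu[-M])),
    numeric(p - length(M)))
  states[, -M] <- states[, -M] + matrix(t(res), length(grid), p - length(M))
  new_trajectory(grid, states, model$labels, spec)
}
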