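# Time-interval-resolved total, direct and indirect effects.
#
# All three effects are expected-value contrasts under do-interventions on a
# linear system: the total effect of a unit pulse on the cause; the direct
# effect of the same pulse with the mediators press-held at equilibrium; and
# the indirect effect as their difference.

#' Total effect of one variable on another at a time-interval
#'
#' The total effect of a unit pulse `do(Y_i(t) = 1)` (versus leaving the
#' system at equilibrium) on the expected value of `Y_j(t + dt)` equals the
#' `(j, i)` entry of the lagged matrix \eqn{e^{A \Delta t}}.
#'
#' @param model a `"ctmodel"`.
#' @param cause,effect variable labels or 1-based indices.
#' @param dt vector of non-negative time-intervals.
#' @return numeric vector of total effects, one per `dt`.
#' @examples
#' m <- ct_model(matrix(c(-1, 1.5, 0, -1), 2, 2))
#' total_effect(m, 1, 2, 1)  # 1.5 * 1 * exp(-1)
#' @export
total_effect <- function(model, cause, effect, dt) {
  stopifnot(inherits(model, "ctmodel"))
  i <- resolve_nodes(cause, model$labels, "cause")
  j <- resolve_nodes(effect, model$labels, "effect")
  stopifnot(length(i) == 1L, length(j) == 1L)
  dt <- check_dt(dt)
  vapply(dt, function(d) matexp(model$drift * d)[j, i], numeric(1))
}

#' Drift matrix with mediators blocked
#'
#' Encodes a press intervention holding the mediator set at equilibrium:
#' every off-diagonal entry in a row or column indexed by a mediator is set
#' to zero (inputs to the mediators are severed and their outputs, pinned
#' at equilibrium, contribute nothing), while the diagonal is untouched.
#'
#' @param model a `"ctmodel"`.
#' @param mediators labels or indices of the blocked variables (may be
#'   empty, in which case the drift is returned unchanged).
#' @return A list of class `"mediator_block"` with elements `mediators`
#'   (integer indices) and `modified_drift`.
#' @export
blocked_drift <- function(model, mediators) {
  stopifnot(inherits(model, "ctmodel"))
  M <- resolve_nodes(mediators, model$labels, "mediators", allow_empty = TRUE)
  A <- model$drift
  if (length(M)) {
    d <- diag(A)
    A[M, ] <- 0
    A[, M] <- 0
    diag(A) <- d
  }
  structure(list(mediators = M, modified_drift = A),
            class = "mediator_block")
}

#' Direct effect at a time-interval, holding mediators fixed
#'
#' The direct effect of a unit pulse on the cause, combined with press
#' interventions keeping the mediators fixed at equilibrium, is the
#' `(j, i)` entry of the exponential of the blocked drift matrix
#' (see [blocked_drift()]). With an empty mediator set it coincides with
#' [total_effect()].
#'
#' @inheritParams total_effect
#' @param mediators labels or indices of press-held variables; must not
#'   contain the cause or the effect.
#' @return numeric vector of direct effects, one per `dt`.
#' @export
direct_effect <- function(model, cause, effect, mediators, dt) {
  stopifnot(inherits(model, "ctmodel"))
  i <- resolve_nodes(cause, model$labels, "cause")
  j <- resolve_nodes(effect, model$labels, "effect")
  M <- resolve_nodes(mediators, model$labels, "mediators", allow_empty = TRUE)
  if (any(M %in% c(i, j)))
    stop("'mediators' must not contain the cause or the effect")
  dt <- check_dt(dt)
  AD <- blocked_drift(model, M)$modified_drift
  vapply(dt, function(d) matexp(AD * d)[j, i], numeric(1))
}

#' Indirect effect at a time-interval
#'
#' The indirect effect through a mediator set is the difference between the
#' total and the direct effect at the same interval,
#' `IE(dt) = TE(dt) - DE(dt)`. A positive value means press-holding the
#' mediators *decreases* the effect of the pulse; a negative value means
#' the press *increases* it (as happens when the mediators carry a
#' compensating negative feedback path).
#'
#' @inheritParams direct_effect
#' @param mediators non-empty mediator set.
#' @return numeric vector of indirect effects, one per `dt`.
#' @export
indirect_effect <- function(model, cause, effect, mediators, dt) {
  M <- resolve_nodes(mediators,
                     if (inherits(model, "ctmodel")) model$labels else NULL,
                     "mediators", allow_empty = FALSE)
  total_effect(model, cause, effect, dt) -
    direct_effect(model, cause, effect, M, dt)
}

#' Effect curve over a grid of time-intervals
#'
#' Evaluates a total, direct or indirect effect on a grid of intervals.
#'
#' @inheritParams direct_effect
#' @param kind one of `"total"`, `"direct"`, `"indirect"`.
#' @param mediators mediator set; required non-empty for `"indirect"`,
#'   ignored for `"total"`.
#' @param grid strictly increasing non-negative intervals.
#' @return Object of class `"effect_curve"`: list with `kind`, `cause`,
#'   `effect`, `mediators` (labels), `grid`, `values`.
#' @export
effect_curve <- function(model, kind = c("total", "direct", "indirect"),
                         cause, effect, mediators = NULL,
                         grid = seq(0, 5, by = 0.05)) {
  stopifnot(inherits(model, "ctmodel"))
  kind <- match.arg(kind)
  grid <- check_grid(grid)
  i <- resolve_nodes(cause, model$labels, "cause")
  j <- resolve_nodes(effect, model$labels, "effect")
  M <- resolve_nodes(mediators, model$labels, "mediators", allow_empty = TRUE)
  values <- switch(kind,
    total = total_effect(model, i, j, grid),
    direct = direct_effect(model, i, j, M, grid),
    indirect = indirect_effect(model, i, j, M, grid))
  structure(list(kind = kind, cause = model$labels[i],
                 effect = model$labels[j], mediators = model$labels[M],
                 grid = grid, values = values),
            class = "effect_curve")
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(x$kind, "effect of", x$cause, "on", x$effect)
  if (length(x$mediators))
    cat(" (mediators: ", paste(x$mediators, collapse = ", "), ")", sep = "")
  cat("\n")
  peak <- which.max(abs(x$values))
  cat("Peak |effect| ", format(x$values[peak], digits = 4), " at dt = ",
      format(x$grid[peak]), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.effect_curve <- function(x, ...) {
  data.frame(dt = x$grid, kind = x$kind, cause = x$cause, effect = x$effect,
             mediators = paste(x$mediators, collapse = ";"),
             value = x$values, stringsAsFactors = FALSE)
}

#' Product-limit (path-tracing) approximation of an effect
#'
#' Brute-force check of the matrix-exponential effects: divide the interval
#' into `n_steps` latent waves, form the one-step matrix
#' \eqn{I + A\,dt/n} (with the mediator block applied for direct effects),
#' raise it to the n-th power, and read off the `(j, i)` entry. As
#' `n_steps` grows this converges to the closed-form
#' [total_effect()] / [direct_effect()] values; it is exposed as an
#' independent oracle for testing, not for production use.
#'
#' @inheritParams direct_effect
#' @param kind one of `"total"`, `"direct"`, `"indirect"`.
#' @param dt a single non-negative interval.
#' @param n_steps number of latent waves (>= 1).
#' @return a single numeric approximation.
#' @export
path_trace_oracle <- function(model, kind = c("total", "direct", "indirect"),
                              cause, effect, mediators = NULL, dt,
                              n_steps = 1e4) {
  stopifnot(inherits(model, "ctmodel"))
  kind <- match.arg(kind)
  i <- resolve_nodes(cause, model$labels, "cause")
  j <- resolve_nodes(effect, model$labels, "effect")
  M <- resolve_nodes(mediators, model$labels, "mediators", allow_empty = TRUE)
  dt <- check_dt(dt)
  stopifnot(length(dt) == 1L, n_steps >= 1)
  n_steps <- as.integer(n_steps)
  step_mat <- function(A) diag(nrow(A)) + A * dt / n_steps
  # binary exponentiation
  mat_pow <- function(B, n) {
    R <- diag(nrow(B))
    while (n > 0) {
      if (n %% 2 == 1) R <- R %*% B
      B <- B %*% B
      n <- n %/% 2
    }
    R
  }
  tot <- function() unname(mat_pow(step_mat(model$drift), n_steps)[j, i])
  dir <- function() {
    AD <- blocked_drift(model, M)$modified_drift
    unname(mat_pow(step_mat(AD), n_steps)[j, i])
  }
  switch(kind, total = tot(), direct = dir(), indirect = tot() - dir())
}
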