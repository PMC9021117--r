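# Maximum-likelihood estimation of the continuous-time VAR on irregularly
# sampled data, the pooled-OLS discrete-time baseline, and likelihood-based
# uncertainty propagation.

# Extract consecutive fully-observed transition pairs from an irregular
# series. Pairs are formed only between adjacent occasions; a pair with any
# missing entry in either row is dropped (listwise by pair).
transition_pairs <- function(data) {
  stopifnot(inherits(data, "irts"))
  n <- length(data$times)
  if (n < 2L) stop("need at least 2 observations to form transition pairs")
  ok_row <- stats::complete.cases(data$values)
  use <- which(ok_row[-n] & ok_row[-1])
  if (!length(use)) stop("no usable consecutive fully-observed pairs")
  list(y0 = data$values[use, , drop = FALSE],
       y1 = data$values[use + 1L, , drop = FALSE],
       dt = data$times[use + 1L] - data$times[use])
}

# Parameter vector <-> (A, Q) with Q = L L', log-diagonal on L.
par_encode <- function(A, Q) {
  L <- t(chol((Q + t(Q)) / 2))
  diag(L) <- log(diag(L))
  c(as.vector(A), L[lower.tri(L, diag = TRUE)])
}

par_decode <- function(par, p, labels = NULL) {
  A <- matrix(par[seq_len(p * p)], p, p)
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par[-seq_len(p * p)]
  diag(L) <- exp(diag(L))
  Q <- L %*% t(L)
  if (!is.null(labels)) dimnames(A) <- dimnames(Q) <- list(labels, labels)
  list(drift = A, diffusion = Q)
}

par_labels <- function(labels) {
  p <- length(labels)
  a <- as.vector(outer(labels, labels, function(r, c) paste0("a_", r, ".", c)))
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  l <- paste0("chol_", labels[idx[, 1]], ".", labels[idx[, 2]])
  c(a, l)
}

#' Log-likelihood of the continuous-time VAR
#'
#' Evaluates the exact transition likelihood of the CT-VAR at a parameter
#' vector: conditioning on the first observation, each consecutive
#' fully-observed pair `(tau - 1, tau)` contributes a Gaussian term with
#' mean \eqn{e^{A \Delta t_\tau} Y(t_{\tau-1})} and interval-dependent
#' covariance \eqn{\Sigma(\Delta t_\tau)}. Data are assumed centered
#' (equilibrium zero); see [fit_ct_var()] for the centering convention.
#'
#' The parameter vector holds the drift matrix (column-major, `p^2`
#' entries) followed by the lower-triangular Cholesky factor of the
#' diffusion rate with logged diagonal (`p(p+1)/2` entries). Parameter
#' points with an unstable drift or a degenerate transition covariance get
#' a large negative value rather than an error, so optimizers can pass
#' through them.
#'
#' @param par numeric parameter vector of length `p^2 + p(p+1)/2`.
#' @param data an [irregular_ts()] object.
#' @return the log-likelihood (a single number).
#' @export
ct_loglik <- function(par, data) {
  pr <- transition_pairs(data)
  -ctvar_nll_cpp(as.numeric(par), pr$y0, pr$y1, pr$dt)
}

#' Fit a continuous-time VAR by maximum likelihood
#'
#' Maximizes the exact CT-VAR transition likelihood over the drift matrix
#' and diffusion rate using quasi-Newton optimization from multiple
#' starts. The first start is a warm start obtained by converting the
#' pooled-OLS discrete-time fit at the median interval back to continuous
#' time (when the matrix logarithm exists); the remaining starts are
#' random perturbations of it. Unequal intervals, including long overnight
#' gaps, are handled exactly: the likelihood automatically downweights
#' long gaps because the implied lagged matrix is then close to zero.
#'
#' Variables are mean-centered before fitting (the centered convention);
#' the sample means are stored as the equilibrium of the returned model.
#'
#' @param data an [irregular_ts()] object.
#' @param n_starts number of optimizer starts (default 10).
#' @param seed optional integer seed for the random starts.
#' @param center mean-center each variable before fitting (default TRUE).
#' @param control passed to [stats::optim()] (method BFGS); `maxit`
#'   defaults to 500.
#' @return Object of class `"ctvar_fit"`: list with `model` (the estimated
#'   `"ctmodel"`), `par`, `vcov` (inverse numerical Hessian), `loglik`,
#'   `converged`, `n_pairs`, and per-start diagnostics in `starts`.
#' @export
fit_ct_var <- function(data, n_starts = 10, seed = NULL, center = TRUE,
                       control = list()) {
  stopifnot(inherits(data, "irts"))
  p <- length(data$labels)
  means <- colMeans(data$values, na.rm = TRUE)
  work <- data
  if (center)
    work$values <- sweep(data$values, 2, means)
  pr <- transition_pairs(work)
  n_pairs <- nrow(pr$y0)
  if (n_pairs < p * (p + 1))
    warning("only ", n_pairs, " usable pairs for ", p,
            " variables: estimates may be poorly identified")
  nll <- function(par) ctvar_nll_cpp(par, pr$y0, pr$y1, pr$dt)

  # Warm start: DT-OLS at the pooled intervals mapped back to CT.
  theta0 <- tryCatch({
    dfit <- fit_dt_var(work, intercept = FALSE)
    ctm <- suppressWarnings(dt_to_ct(dfit$model))
    if (!is_stable(ctm)) stop("warm start unstable")
    Q0 <- ctm$diffusion
    if (is.null(Q0) || !is_psd_tol(Q0)) Q0 <- diag(p)
    ev <- eigen((Q0 + t(Q0)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) Q0 <- Q0 + diag(1e-6, p)
    par_encode(ctm$drift, Q0)
  }, error = function(e) par_encode(-diag(p), diag(p)))

  if (!is.null(seed)) set.seed(seed)
  npar <- p * p + p * (p + 1) / 2
  starts <- vector("list", n_starts)
  ctrl <- utils::modifyList(list(maxit = 500), control)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th <- if (s == 1L) theta0 else theta0 + stats::rnorm(npar, sd = 0.25)
    fit <- tryCatch(
      stats::optim(th, nll, method = "BFGS", control = ctrl),
      error = function(e) NULL)
    starts[[s]] <- if (is.null(fit)) list(value = NA_real_, convergence = NA)
                   else list(value = fit$value, convergence = fit$convergence)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < BIG_NLL &&
        (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed; per-start values: ",
         paste(vapply(starts, function(s) format(s$value), ""), collapse = ", "))

  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  vcov <- matrix(NA_real_, npar, npar)
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) {
      warning("numerical Hessian is singular; using pseudo-inverse")
      MASS::ginv(H)
    })
    vcov <- (vcov + t(vcov)) / 2
  }
  pl <- par_labels(data$labels)
  dimnames(vcov) <- list(pl, pl)
  dec <- par_decode(best$par, p, data$labels)
  model <- ct_model(dec$drift, dec$diffusion,
                    equilibrium = if (center) means else rep(0, p),
                    labels = data$labels)
  if (!is_stable(model))
    warning("fitted drift matrix is not stable")
  structure(list(model = model,
                 par = stats::setNames(best$par, pl),
                 vcov = vcov,
                 loglik = -best$value,
                 converged = best$convergence == 0,
                 n_pairs = n_pairs,
                 starts = starts,
                 centered = center),
            class = "ctvar_fit")
}

BIG_NLL <- 1e10 - 1

#' Fit a discrete-time VAR(1) by pooled OLS
#'
#' Per-equation ordinary least squares of each occasion on the previous
#' occasion, pooling *all* consecutive pairs regardless of the interval
#' between them -- the conventional discrete-time analysis that ignores
#' unequal spacing. When intervals vary, the resulting lagged matrix is a
#' blend of the lagged relationships at the different intervals present in
#' the data; the reference interval recorded is the median observed
#' interval.
#'
#' @param data an [irregular_ts()] object.
#' @param intercept include an intercept in each equation (default TRUE).
#' @return Object of class `"dtvar_fit"`: list with `model` (a
#'   `"dtmodel"`), `coef_se` (standard errors of the lagged entries),
#'   `vcov` (covariance of `vec(Phi)`), `n_pairs`, `loglik` (Gaussian).
#' @export
fit_dt_var <- function(data, intercept = TRUE) {
  stopifnot(inherits(data, "irts"))
  pr <- transition_pairs(data)
  p <- ncol(pr$y0)
  n <- nrow(pr$y0)
  if (n < p + 2L) stop("need at least p + 2 usable pairs for OLS")
  X <- if (intercept) cbind(`(Intercept)` = 1, pr$y0) else pr$y0
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("regressor matrix is rank deficient (constant or collinear column)")
  B <- qr.coef(qrx, pr$y1)           # ncol(X) x p
  res <- pr$y1 - X %*% B
  dfree <- n - ncol(X)
  Psi <- crossprod(res) / dfree
  Phi <- t(B[(nrow(B) - p + 1):nrow(B), , drop = FALSE])
  cvec <- if (intercept) as.numeric(B[1, ]) else rep(0, p)
  XtXinv <- chol2inv(qr.R(qrx))
  # vcov of vec(B) is Psi (x) (X'X)^-1 ; extract the lagged block per eq.
  lag_idx <- (nrow(B) - p + 1):nrow(B)
  vcovPhi <- kronecker(Psi, XtXinv)[
    rep((seq_len(p) - 1) * ncol(X), each = p) + lag_idx,
    rep((seq_len(p) - 1) * ncol(X), each = p) + lag_idx]
  se <- matrix(sqrt(diag(vcovPhi)), p, p)
  # diag(vcovPhi) ordered by equation (row of Phi) then regressor
  se <- t(se)
  dimnames(se) <- list(data$labels, data$labels)
  md <- stats::median(pr$dt)
  model <- dt_model(Phi, interval = md, residual_cov = Psi,
                    intercept = cvec, labels = data$labels)
  ll <- sum(vapply(seq_len(n), function(i)
    mvn_logdens(pr$y1[i, ] - X[i, ] %*% B, Psi), numeric(1)))
  structure(list(model = model, coef_se = se, vcov = vcovPhi,
                 n_pairs = n, loglik = ll),
            class = "dtvar_fit")
}

mvn_logdens <- function(r, S) {
  p <- length(r)
  ch <- chol(S)
  z <- backsolve(ch, as.numeric(r), transpose = TRUE)
  -0.5 * (p * log(2 * pi) + sum(z^2)) - sum(log(diag(ch)))
}

#' @export
print.ctvar_fit <- function(x, ...) {
  cat("CT-VAR maximum-likelihood fit: ", x$n_pairs, " transition pairs, ",
      "logLik = ", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
print.dtvar_fit <- function(x, ...) {
  cat("DT-VAR pooled-OLS fit: ", x$n_pairs, " pairs, reference interval ",
      format(x$model$interval, digits = 4), "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
logLik.ctvar_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' @export
coef.ctvar_fit <- function(object, ...) object$par

#' @export
vcov.ctvar_fit <- function(object, ...) object$vcov

#' Likelihood-based uncertainty bands for derived curves
#'
#' Propagates estimation uncertainty to any functional of the fitted model
#' (a lagged-parameter entry over a grid, a centrality curve, an effect
#' curve, ...) by re-sampling parameter vectors from the large-sample
#' normal approximation `N(theta_hat, vcov)` and mapping each draw through
#' the functional. Pointwise 2.5/97.5 percentile bands are returned.
#'
#' @param fit a converged `"ctvar_fit"` with finite `vcov`.
#' @param functional a function taking a `"ctmodel"` and returning a
#'   numeric vector (constant length across draws).
#' @param n_draws number of parameter draws (default 1000).
#' @param seed optional integer seed; the same seed reproduces the same
#'   bands exactly.
#' @return list with `est` (functional at the point estimate), `lower`,
#'   `upper` (pointwise 2.5% and 97.5% bands), and `n_draws`.
#' @export
propagate_uncertainty <- function(fit, functional, n_draws = 1000,
                                  seed = NULL) {
  stopifnot(inherits(fit, "ctvar_fit"), is.function(functional))
  if (!all(is.finite(fit$vcov))) stop("fit has no finite vcov")
  V <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    warning("vcov is not positive semi-definite; repaired to nearest PSD")
    V <- nearest_psd(V)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- length(fit$model$labels)
  draws <- MASS::mvrnorm(n_draws, mu = fit$par, Sigma = V)
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1)
  apply_one <- function(th) {
    dec <- par_decode(th, p, fit$model$labels)
    Q <- dec$diffusion
    if (!is_psd_tol(Q)) Q <- nearest_psd(Q)
    m <- ct_model(dec$drift, Q, fit$model$equilibrium, fit$model$labels)
    functional(m)
  }
  est <- functional(fit$model)
  vals <- vapply(seq_len(n_draws), function(k) apply_one(draws[k, ]),
                 numeric(length(est)))
  vals <- matrix(vals, nrow = length(est))
  list(est = est,
       lower = apply(vals, 1, stats::quantile, probs = 0.025, names = FALSE),
       upper = apply(vals, 1, stats::quantile, probs = 0.975, names = FALSE),
       n_draws = n_draws)
}
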