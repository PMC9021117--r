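# Internal linear-algebra helpers shared by all modules.

#' Matrix exponential
#'
#' Thin wrapper around the Pade scaling-and-squaring implementation in the
#' Matrix package, returning a plain dense matrix.
#'
#' @param A square numeric matrix.
#' @return `exp(A)` as a base matrix.
#' @keywords internal
#' @noRd
matexp <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !all(is.finite(A)))
    stop("matexp() needs a finite square matrix")
  if (nrow(A) == 1L) return(matrix(exp(A[1L, 1L]), 1L, 1L))
  unname(as.matrix(Matrix::expm(Matrix::Matrix(A))))
}

# Principal matrix logarithm by inverse scaling-and-squaring:
# repeated square roots until close to I, truncated Mercator series, then
# Newton refinement against the (accurate) matrix exponential.
# Errors when no real principal logarithm exists (eigenvalue on the closed
# negative real axis).
matlog <- function(X, tol = 1e-12) {
  if (!is.matrix(X) || nrow(X) != ncol(X) || !all(is.finite(X)))
    stop("matlog() needs a finite square matrix")
  p <- nrow(X)
  ev <- eigen(X, only.values = TRUE)$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12 * (abs(ev) + 1)))
    stop("matrix has a zero or negative real eigenvalue: ",
         "no real principal logarithm exists (positive auto-regression violated)")
  I <- diag(p)
  if (p == 1L) return(matrix(log(X[1L, 1L]), 1L, 1L))
  Z <- X
  k <- 0L
  while (max(abs(Z - I)) > 0.25 && k < 60L) {
    Z <- pracma::sqrtm(Z)$B
    k <- k + 1L
  }
  Y <- Z - I
  L <- matrix(0, p, p)
  P <- Y
  for (m in 1:25) {
    L <- L + (-1)^(m + 1) / m * P
    P <- P %*% Y
  }
  L <- L * 2^k
  # Newton refinement: solves expm(L) = X to machine precision.
  for (it in 1:20) {
    R <- matexp(-L) %*% X - I
    if (max(abs(R)) < tol) break
    L <- L + R - R %*% R / 2
  }
  L
}

# Solve the continuous Lyapunov equation A G + G A' + Q = 0 for G
# (Kronecker vectorization; p is small throughout this package).
lyap_ct <- function(A, Q) {
  p <- nrow(A)
  I <- diag(p)
  M <- kronecker(I, A) + kronecker(A, I)
  G <- matrix(solve(M, -as.vector(Q)), p, p)
  (G + t(G)) / 2
}

# Solve the discrete Lyapunov equation G = Phi G Phi' + Psi for G.
lyap_dt <- function(Phi, Psi) {
  p <- nrow(Phi)
  M <- diag(p * p) - kronecker(Phi, Phi)
  G <- matrix(solve(M, as.vector(Psi)), p, p)
  (G + t(G)) / 2
}

# Symmetry check with relative tolerance.
is_symmetric_tol <- function(M, tol = 1e-8) {
  max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

# Check positive semi-definiteness allowing eigenvalues down to -1e-10.
is_psd_tol <- function(M, tol = 1e-10) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, max(abs(ev))))
}

# Clip negative eigenvalues to produce the nearest PSD matrix.
nearest_psd <- function(M) {
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  S <- es$vectors %*% (lam * t(es$vectors))
  (S + t(S)) / 2
}

# Resolve user-supplied nodes (labels or 1-based indices) to integer indices.
resolve_nodes <- function(nodes, labels, arg = "nodes", allow_empty = FALSE) {
  if (is.null(nodes) || length(nodes) == 0L) {
    if (allow_empty) return(integer(0))
    stop("'", arg, "' must not be empty")
  }
  p <- length(labels)
  if (is.character(nodes)) {
    idx <- match(nodes, labels)
    if (anyNA(idx))
      stop("unknown variable label(s) in '", arg, "': ",
           paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (anyNA(idx) || any(idx < 1L) || any(idx > p))
      stop("'", arg, "' indices must be in 1..", p)
  }
  if (anyDuplicated(idx)) stop("'", arg, "' contains duplicated variables")
  idx
}

check_grid <- function(grid, arg = "grid") {
  if (length(grid) == 0L) stop("'", arg, "' must not be empty")
  if (!is.numeric(grid) || !all(is.finite(grid)))
    stop("'", arg, "' must be finite numeric")
  if (any(grid < 0)) stop("'", arg, "' values must be >= 0")
  if (is.unsorted(grid, strictly = TRUE))
    stop("'", arg, "' must be strictly increasing")
  as.numeric(grid)
}

check_dt <- function(dt, arg = "dt") {
  if (!is.numeric(dt) || length(dt) < 1L || !all(is.finite(dt)) || any(dt < 0))
    stop("'", arg, "' must be finite and >= 0")
  as.numeric(dt)
}
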