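# Independent numerical oracles used to cross-check the closed-form
# implementations. These deliberately take a different computational route
# (ODE integration, exhaustive path enumeration) from the package code.

# Expected trajectory of dy/dt = A (y - mu) from y0, with the components in
# `clamp` held fixed (their derivatives forced to zero), integrated by
# classical fixed-step 4th-order Runge-Kutta via deSolve.
rk4_trajectory <- function(A, y0, t_end, clamp = integer(0), n_steps = 1000,
                           mu = rep(0, nrow(A))) {
  deriv <- function(t, y, parms) {
    dy <- as.numeric(A %*% (y - mu))
    if (length(clamp)) dy[clamp] <- 0
    list(dy)
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  unname(out[nrow(out), -1])
}

# Exhaustive betweenness centrality on a weighted directed graph given as a
# lagged matrix (entry [j, i] = edge i -> j): enumerate every simple path
# between each ordered pair, path length = sum of 1/|weight|, count paths
# through intermediate nodes fractionally among the shortest.
brute_force_bc <- function(Phi, tol = 1e-9) {
  p <- nrow(Phi)
  W <- abs(Phi)
  diag(W) <- 0
  adj <- lapply(seq_len(p), function(i) which(W[, i] > 0))  # out-neighbors
  bc <- numeric(p)
  for (s in seq_len(p)) for (t in seq_len(p)) {
    if (s == t) next
    paths <- list()
    lens <- numeric(0)
    walk <- function(node, visited, len) {
      if (node == t) {
        paths[[length(paths) + 1L]] <<- visited
        lens[length(lens) + 1L] <<- len
        return(invisible())
      }
      for (nb in adj[[node]]) {
        if (nb %in% visited) next
        walk(nb, c(visited, nb), len + 1 / W[nb, node])
      }
    }
    walk(s, s, 0)
    if (!length(lens)) next
    dmin <- min(lens)
    short <- paths[lens <= dmin * (1 + tol) + tol]
    nshort <- length(short)
    for (pa in short) {
      inner <- setdiff(pa, c(s, t))
      bc[inner] <- bc[inner] + 1 / nshort
    }
  }
  bc
}

# Product-limit approximation (I + A dt / n)^n of the matrix exponential,
# by binary exponentiation.
product_limit_matrix <- function(A, dt, n) {
  P <- diag(nrow(A)) + A * dt / n
  R <- diag(nrow(A))
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  R
}

# Random stable test model: stable drift plus a random PSD diffusion rate.
random_ct_model <- function(p, seed = NULL, margin = 0.2, scale = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  A <- random_stable_drift(p, spectral_margin = margin, scale = scale)
  R <- matrix(stats::rnorm(p * p, sd = 0.3), p, p)
  Q <- crossprod(R) + diag(0.2, p)
  ct_model(A, diffusion = Q)
}
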