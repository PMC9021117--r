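# Centrality measures: interval-resolved measures for continuous-time
# networks (total effect centrality, indirect effect centrality) and the
# classical discrete-time measures computed on any lagged matrix.

#' Total effect centrality at a time-interval
#'
#' The total effect centrality of a node sums its total effects on all
#' other variables at interval `dt`,
#' \eqn{TEC_i(\Delta t) = \sum_{j \ne i} TE_{ij}(\Delta t)}: the cumulative
#' network-wide consequence of a unit pulse on node `i` felt `dt` later.
#' It equals the one-step expected influence computed on the lagged matrix
#' \eqn{\Phi(\Delta t)}, and identifies promising pulse-intervention
#' targets.
#'
#' @param model a `"ctmodel"`.
#' @param node variable label or index.
#' @param dt vector of non-negative intervals.
#' @return numeric vector, one value per `dt`.
#' @export
tec <- function(model, node, dt) {
  stopifnot(inherits(model, "ctmodel"))
  i <- resolve_nodes(node, model$labels, "node")
  stopifnot(length(i) == 1L)
  dt <- check_dt(dt)
  vapply(dt, function(d) {
    E <- matexp(model$drift * d)
    sum(E[, i]) - E[i, i]
  }, numeric(1))
}

#' Indirect effect centrality at a time-interval
#'
#' The indirect effect centrality of a mediator node sums the indirect
#' effects between all ordered pairs of *other* variables when that node is
#' the sole press-held mediator:
#' \eqn{IEC_i(\Delta t) = \sum_{j \ne k,\; j,k \ne i}
#' IE_{jk|i}(\Delta t)}. A large positive value means press-holding the
#' node weakens how other variables activate one another (an attractive
#' press-intervention target); a negative value means the press amplifies
#' those effects, as happens when the node carries a negative feedback
#' loop.
#'
#' @inheritParams tec
#' @return numeric vector, one value per `dt`. Identically zero for systems
#'   with fewer than three variables.
#' @export
iec <- function(model, node, dt) {
  stopifnot(inherits(model, "ctmodel"))
  i <- resolve_nodes(node, model$labels, "node")
  stopifnot(length(i) == 1L)
  dt <- check_dt(dt)
  p <- length(model$labels)
  if (p < 3) return(rep(0, length(dt)))
  AD <- blocked_drift(model, i)$modified_drift
  vapply(dt, function(d) {
    D <- matexp(model$drift * d) - matexp(AD * d)
    Dsub <- D[-i, -i, drop = FALSE]
    sum(Dsub) - sum(diag(Dsub))
  }, numeric(1))
}

#' Centrality curves for a continuous-time network
#'
#' Evaluates total effect centrality or indirect effect centrality for
#' every node over a grid of intervals, and records the interval at which
#' each node's centrality peaks in absolute value.
#'
#' @param model a `"ctmodel"`.
#' @param measure `"TEC"` or `"IEC"`.
#' @param grid strictly increasing non-negative intervals.
#' @return Object of class `"centrality_curve"`: list with `measure`,
#'   `grid`, `node_values` (length(grid) x p matrix), `labels`, `peak_dt`
#'   (named vector), `source` (`"CT"`).
#' @export
centrality_curve <- function(model, measure = c("TEC", "IEC"),
                             grid = seq(0, 5, by = 0.05)) {
  stopifnot(inherits(model, "ctmodel"))
  measure <- match.arg(measure)
  grid <- check_grid(grid)
  p <- length(model$labels)
  fun <- if (measure == "TEC") tec else iec
  vals <- vapply(seq_len(p), function(i) fun(model, i, grid),
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid), ncol = p,
                 dimnames = list(NULL, model$labels))
  peak <- grid[apply(abs(vals), 2, which.max)]
  structure(list(measure = measure, grid = grid, node_values = vals,
                 labels = model$labels,
                 peak_dt = stats::setNames(peak, model$labels),
                 source = "CT"),
            class = "centrality_curve")
}

#' Classical centrality measures on a lagged matrix
#'
#' Computes discrete-time network centralities on a lagged-parameter
#' matrix, with entry `(j, i)` read as the edge from `i` to `j`:
#' \describe{
#'   \item{EI1}{one-step expected influence: signed sum of outgoing edges,
#'     \eqn{\sum_{j \ne i} \phi_{ji}}.}
#'   \item{OutStrength}{sum of absolute outgoing edges.}
#'   \item{EI2}{two-step expected influence: one-step direct effects plus
#'     lag-two total effects, \eqn{\sum_{j \ne i} \phi_{ji} +
#'     \sum_{j \ne i} [\Phi^2]_{ji}}.}
#'   \item{BC}{betweenness centrality on the weighted directed graph with
#'     edge lengths `1/|weight|`, shortest paths by Dijkstra, fractional
#'     counting of ties; self-loops ignored.}
#' }
#'
#' @param lagged square lagged matrix (e.g. from [lagged_params()]).
#' @param measure one of `"EI1"`, `"EI2"`, `"OutStrength"`, `"BC"`.
#' @return named numeric vector of length p.
#' @export
dt_centrality <- function(lagged,
                          measure = c("EI1", "EI2", "OutStrength", "BC")) {
  measure <- match.arg(measure)
  Phi <- as.matrix(lagged)
  if (nrow(Phi) != ncol(Phi)) stop("'lagged' must be square")
  p <- nrow(Phi)
  labels <- colnames(Phi)
  if (is.null(labels)) labels <- paste0("Y", seq_len(p))
  off_colsum <- function(M) colSums(M) - diag(M)
  out <- switch(measure,
    EI1 = off_colsum(Phi),
    OutStrength = off_colsum(abs(Phi)),
    EI2 = off_colsum(Phi) + off_colsum(Phi %*% Phi),
    BC = {
      W <- abs(Phi)
      diag(W) <- 0
      # adjacency convention of igraph: entry [i, j] is edge i -> j
      g <- igraph::graph_from_adjacency_matrix(t(W), mode = "directed",
                                               weighted = TRUE)
      b <- rep(0, p)
      if (igraph::ecount(g) > 0)
        b <- igraph::betweenness(g, directed = TRUE,
                                 weights = 1 / igraph::E(g)$weight)
      as.numeric(b)
    })
  stats::setNames(as.numeric(out), labels)
}

#' Discrete-time centrality curves over the time-interval
#'
#' Applies [dt_centrality()] to the lagged matrix \eqn{\Phi(\Delta t)}
#' implied by a continuous-time model at every grid interval, showing how
#' the classical centrality measures (and hence the intervention targets
#' they suggest) depend on the measurement interval.
#'
#' @param model a `"ctmodel"`.
#' @param measure one of `"EI1"`, `"EI2"`, `"OutStrength"`, `"BC"`.
#' @param grid strictly increasing non-negative intervals.
#' @return a `"centrality_curve"` with `source = "DT"`.
#' @export
dt_centrality_curve <- function(model,
                                measure = c("EI1", "EI2", "OutStrength", "BC"),
                                grid = seq(0, 5, by = 0.05)) {
  stopifnot(inherits(model, "ctmodel"))
  measure <- match.arg(measure)
  grid <- check_grid(grid)
  p <- length(model$labels)
  vals <- t(vapply(grid, function(d)
    dt_centrality(lagged_params(model, d), measure), numeric(p)))
  colnames(vals) <- model$labels
  peak <- grid[apply(abs(vals), 2, which.max)]
  structure(list(measure = measure, grid = grid, node_values = vals,
                 labels = model$labels,
                 peak_dt = stats::setNames(peak, model$labels),
                 source = "DT"),
            class = "centrality_curve")
}

#' @export
print.centrality_curve <- function(x, ...) {
  cat(x$measure, " centrality (", x$source, ") on ", length(x$grid),
      " intervals in [", format(min(x$grid)), ", ", format(max(x$grid)),
      "]\n", sep = "")
  cat("Peak |value| interval per node:\n")
  print(x$peak_dt)
  invisible(x)
}

#' @export
as.data.frame.centrality_curve <- function(x, ...) {
  p <- length(x$labels)
  data.frame(dt = rep(x$grid, times = p),
             measure = x$measure,
             node = rep(x$labels, each = length(x$grid)),
             value = as.vector(x$node_values),
             stringsAsFactors = FALSE)
}
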