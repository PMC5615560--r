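#' ICAR full-conditional moments for one county
#'
#' Under the intrinsic conditional autoregressive prior, the spatial effect of
#' county `i` given all others is Gaussian with mean equal to the average of
#' its neighbours' effects and variance `sigma2_s / L_i`, where `L_i` is the
#' neighbour count.
#'
#' @param i node identifier (or 1-based index into `graph$node_ids`).
#' @param s numeric vector of spatial effects, aligned with `graph$node_ids`.
#' @param graph a [county_graph()].
#' @param sigma2_s conditional variance parameter (> 0).
#' @returns list with elements `mean` and `variance`.
#' @examples
#' g <- grid_graph(1, 3)
#' icar_conditional_params("r1c2", c(1, 0, 3), g, sigma2_s = 2)
#' @export
icar_conditional_params <- function(i, s, graph, sigma2_s) {
  stopifnot(inherits(graph, "county_graph"), sigma2_s > 0,
            length(s) == n_nodes(graph))
  if (is.numeric(i)) i <- graph$node_ids[i]
  if (!i %in% graph$node_ids) stop("unknown node '", i, "'")
  L <- graph$L[[i]]
  if (L == 0)
    stop("node '", i, "' has no neighbours; island counties have their ",
         "spatial effect pinned to zero (see the island policy in the ",
         "package vignette) and no ICAR conditional")
  idx <- match(graph$neighbours[[i]], graph$node_ids)
  list(mean = mean(s[idx]), variance = sigma2_s / L)
}

#' ICAR joint log density (up to a constant)
#'
#' The pairwise-difference kernel of the intrinsic prior:
#' `-(1 / (2 * sigma2_s)) * sum over adjacent pairs (s_i - s_j)^2`,
#' evaluated after projecting `s` onto the sum-to-zero subspace (the kernel
#' itself is invariant to adding a constant). The graph must be connected so
#' that the sum-to-zero constraint is the only rank deficiency.
#'
#' @inheritParams icar_conditional_params
#' @param s numeric vector of spatial effects summing (approximately) to zero.
#' @returns scalar log density up to an additive constant.
#' @export
icar_log_density <- function(s, graph, sigma2_s) {
  stopifnot(inherits(graph, "county_graph"), sigma2_s > 0,
            length(s) == n_nodes(graph))
  if (!graph_connected(graph))
    stop("graph is disconnected: the intrinsic prior is rank-deficient ",
         "beyond the single sum-to-zero constraint")
  s <- s - mean(s)
  e <- graph_edges(graph)
  ia <- match(e$from, graph$node_ids)
  ib <- match(e$to, graph$node_ids)
  -sum((s[ia] - s[ib])^2) / (2 * sigma2_s)
}

#' Simulate a draw from the intrinsic CAR prior
#'
#' Draws the spatial effect vector from the ICAR distribution restricted to
#' the sum-to-zero subspace: with graph Laplacian `Q`, the draw is
#' `sqrt(sigma2_s) * V diag(1/sqrt(ev)) z` over the non-null eigenpairs
#' `(ev, V)` of `Q`, recentred to mean zero. Rook lattices built by
#' [grid_graph()] use the closed-form cosine eigenbasis of the path-graph
#' Laplacian (separable 2-D transform), so large lattices are cheap; other
#' graphs fall back to a dense eigendecomposition.
#'
#' @param graph a connected [county_graph()].
#' @param sigma2_s conditional variance parameter (> 0).
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is called.
#' @returns numeric vector of spatial effects (names = node ids), mean zero.
#' @export
simulate_spatial_effects <- function(graph, sigma2_s, seed = NULL) {
  stopifnot(inherits(graph, "county_graph"), sigma2_s > 0)
  if (!graph_connected(graph)) stop("graph is disconnected")
  if (!is.null(seed)) set.seed(seed)
  rows <- attr(graph, "grid_rows")
  if (!is.null(rows) && identical(attr(graph, "grid_scheme"), "rook")) {
    s <- icar_draw_grid(rows, attr(graph, "grid_cols"), sigma2_s)
  } else {
    Q <- graph_laplacian(graph)
    eg <- eigen(Q, symmetric = TRUE)
    n <- nrow(Q)
    keep <- seq_len(n - 1)  # drop the single zero eigenvalue (connected)
    z <- stats::rnorm(n - 1)
    s <- sqrt(sigma2_s) * as.vector(eg$vectors[, keep, drop = FALSE] %*%
                                      (z / sqrt(eg$values[keep])))
  }
  s <- s - mean(s)
  stats::setNames(s, graph$node_ids)
}

# Separable spectral ICAR draw on a rows x cols rook lattice.  The path-graph
# Laplacian P_m has eigenvalues 2 - 2cos(pi k / m), k = 0..m-1, with cosine
# eigenvectors; the lattice Laplacian is P_rows (+) P_cols (Kronecker sum).
icar_draw_grid <- function(rows, cols, sigma2_s) {
  path_basis <- function(m) {
    k <- seq_len(m) - 1
    V <- sqrt(2 / m) * cos(outer((seq_len(m) - 0.5), k) * pi / m)
    V[, 1] <- sqrt(1 / m)
    list(V = V, ev = 2 - 2 * cos(pi * k / m))
  }
  br <- path_basis(rows); bc <- path_basis(cols)
  lam <- outer(br$ev, bc$ev, `+`)
  Z <- matrix(stats::rnorm(rows * cols), rows, cols)
  Z <- Z / sqrt(lam)
  Z[1, 1] <- 0  # null eigenpair (constant vector) removed
  field <- br$V %*% Z %*% t(bc$V) * sqrt(sigma2_s)
  as.vector(t(field))  # row-major, matching grid_graph() node order
}
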