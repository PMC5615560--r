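# Independent oracles used across the suite.  Everything here is deliberately
# written against the mathematical definitions, not the package's code paths.

path_graph <- function(n) {
  ids <- as.character(seq_len(n))
  nb <- lapply(seq_len(n), function(i)
    ids[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 & c(i - 1, i + 1) <= n]])
  county_graph(ids, nb)
}

graph_from_adjmat <- function(A) {
  n <- nrow(A)
  ids <- as.character(seq_len(n))
  nb <- lapply(seq_len(n), function(i) ids[A[i, ] > 0])
  county_graph(ids, nb)
}

# random connected graph on n nodes: spanning tree plus random extra edges
random_connected_graph <- function(n, extra = 2) {
  A <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    A[i, j] <- A[j, i] <- 1
  }
  pairs <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  if (nrow(pairs) && extra > 0) {
    pick <- pairs[sample.int(nrow(pairs), min(extra, nrow(pairs))), ,
                  drop = FALSE]
    A[pick] <- 1
    A[pick[, c(2, 1), drop = FALSE]] <- 1
  }
  graph_from_adjmat(A)
}

# Exhaustive enumeration of connected graphs on 2..nmax nodes up to
# isomorphism: all labeled edge subsets, connectivity by algebraic
# connectivity, candidate grouping by (degree sequence, Laplacian spectrum),
# exact deduplication by igraph isomorphism within groups.
enumerate_connected_graphs <- function(nmax = 6) {
  out <- list()
  for (n in 2:nmax) {
    pairs <- t(utils::combn(n, 2))
    m <- nrow(pairs)
    reps <- list()        # adjacency matrices of representatives
    keys <- character(0)  # their invariant keys
    igs <- list()         # igraph objects of representatives
    for (mask in seq_len(2^m) - 1L) {
      bits <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
      if (!any(bits)) next
      A <- matrix(0, n, n)
      sel <- pairs[bits, , drop = FALSE]
      A[sel] <- 1
      A[sel[, c(2, 1), drop = FALSE]] <- 1
      Lap <- diag(rowSums(A)) - A
      ev <- eigen(Lap, symmetric = TRUE, only.values = TRUE)$values
      if (ev[n - 1] < 1e-9) next  # disconnected
      key <- paste(c(sort(rowSums(A)), round(ev, 8)), collapse = ",")
      gi <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      dup <- FALSE
      for (k in which(keys == key)) {
        if (igraph::is_isomorphic_to(gi, igs[[k]])) { dup <- TRUE; break }
      }
      if (!dup) {
        reps[[length(reps) + 1]] <- A
        keys <- c(keys, key)
        igs[[length(igs) + 1]] <- gi
      }
    }
    out[[as.character(n)]] <- reps
  }
  out
}

# Grid-quadrature moments of the ICAR pairwise-difference density restricted
# to the sum-to-zero subspace of a connected graph.
icar_quadrature_moments <- function(A, sigma2 = 1, npts = NULL) {
  n <- nrow(A)
  Q <- (diag(rowSums(A)) - A) / sigma2
  B <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  Aq <- t(B) %*% Q %*% B
  sds <- sqrt(diag(solve(Aq)))
  d <- n - 1
  if (is.null(npts)) npts <- c(2001, 201, 61, 21, 13)[d]
  grid <- seq(-4.5, 4.5, length.out = npts)
  Z <- as.matrix(expand.grid(rep(list(grid), d)))
  Z <- sweep(Z, 2, sds, `*`)
  U <- chol(Aq)
  w <- exp(-0.5 * rowSums((Z %*% t(U))^2))
  sw <- sum(w)
  mz <- colSums(w * Z) / sw
  m2z <- crossprod(Z * sqrt(w)) / sw
  list(mean = as.vector(B %*% mz),
       second_moment = B %*% m2z %*% t(B))
}

# Gibbs-sampled moments of the ICAR prior via the package's conditional
# updates (the path under test for criterion-style moment comparisons)
icar_gibbs_prior_moments <- function(graph, sigma2 = 1, n_draws = 1e5,
                                     n_burn = 5000, thin = 5) {
  csr <- countycar:::graph_csr(graph)
  countycar:::icar_gibbs_moments(csr$adj, csr$adj_start, csr$nnbr, sigma2,
                                 as.integer(n_draws + n_burn),
                                 as.integer(n_burn), as.integer(thin))
}

# Independent split-chain potential scale reduction factor, written directly
# from the between/within variance definition.
psrf_reference <- function(chains) {
  chains <- as.matrix(chains)
  half <- floor(nrow(chains) / 2)
  parts <- c(lapply(seq_len(ncol(chains)), function(j) chains[1:half, j]),
             lapply(seq_len(ncol(chains)), function(j)
               chains[(nrow(chains) - half + 1):nrow(chains), j]))
  nn <- half
  mm <- length(parts)
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, var, numeric(1))
  W <- sum(vars) / mm
  B <- nn * sum((means - mean(means))^2) / (mm - 1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# dense weight matrix for ape::Moran.I
moran_weights <- function(graph) {
  n <- n_nodes(graph)
  W <- matrix(0, n, n)
  idx <- setNames(seq_len(n), graph$node_ids)
  for (i in graph$node_ids) W[idx[i], idx[graph$neighbours[[i]]]] <- 1
  W
}
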