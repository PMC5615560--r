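#' County adjacency graphs
#'
#' A `county_graph` is a symmetric, self-loop-free neighbour structure over
#' counties: for every county it records the set of adjacent counties and the
#' neighbour count `L` that scales the conditional variance of the intrinsic
#' CAR prior (`sigma2_s / L_i`).
#'
#' @param node_ids character vector of county identifiers (unique).
#' @param neighbours list, one character vector of neighbouring ids per node.
#' @returns A `county_graph` object: list with `node_ids`, `neighbours`
#'   (named list of character vectors) and `L` (named integer vector).
#' @examples
#' county_graph(c("a", "b"), list(a = "b", b = "a"))
#' @export
county_graph <- function(node_ids, neighbours) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node identifiers")
  if (length(neighbours) != length(node_ids))
    stop("neighbours must have one entry per node")
  names(neighbours) <- node_ids
  neighbours <- lapply(neighbours, function(x) sort(unique(as.character(x))))
  g <- structure(
    list(node_ids = node_ids,
         neighbours = neighbours,
         L = vapply(neighbours, length, integer(1))),
    class = "county_graph")
  validate_county_graph(g)
}

validate_county_graph <- function(g) {
  ids <- g$node_ids
  for (i in ids) {
    nb <- g$neighbours[[i]]
    if (i %in% nb) stop("self-loop at node '", i, "'")
    unknown <- setdiff(nb, ids)
    if (length(unknown))
      stop("edge references unknown node '", unknown[1], "'")
    for (j in nb) {
      if (!(i %in% g$neighbours[[j]]))
        stop("asymmetric adjacency between '", i, "' and '", j, "'")
    }
  }
  stopifnot(identical(unname(g$L), unname(vapply(g$neighbours, length, integer(1)))))
  g
}

#' @export
print.county_graph <- function(x, ...) {
  cat("<county_graph> ", length(x$node_ids), " nodes, ",
      sum(x$L) / 2, " edges, ", sum(x$L == 0), " island(s)\n", sep = "")
  invisible(x)
}

#' @export
format.county_graph <- function(x, ...) {
  paste0("<county_graph: ", length(x$node_ids), " nodes>")
}

#' Number of nodes in a county graph
#' @param g a `county_graph`.
#' @returns integer count of nodes.
#' @export
n_nodes <- function(g) length(g$node_ids)

#' Edge list of a county graph
#' @param g a `county_graph`.
#' @returns tibble with columns `from`, `to`, one row per unordered edge.
#' @export
graph_edges <- function(g) {
  rows <- purrr::map(g$node_ids, function(i) {
    nb <- g$neighbours[[i]]
    nb <- nb[nb > i]  # each unordered pair once, lexicographic
    if (length(nb)) tibble::tibble(from = i, to = nb) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble::tibble(from = character(), to = character()) else out
}

#' Lattice contiguity graph
#'
#' Builds a rook (shared edges) or queen (shared edges or corners) contiguity
#' graph on a `rows` x `cols` lattice — the synthetic stand-in for US county
#' contiguity. Node ids are `"r<row>c<col>"`.
#'
#' @param rows,cols positive integers, lattice dimensions with `rows*cols >= 2`.
#' @param scheme `"rook"` (default) or `"queen"`.
#' @returns A connected `county_graph` with attributes `grid_rows`,
#'   `grid_cols`, `grid_scheme` recorded for fast spectral simulation.
#' @examples
#' g <- grid_graph(3, 3)
#' g$L[["r2c2"]]  # centre cell has 4 rook neighbours
#' @export
grid_graph <- function(rows, cols, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  if (length(rows) != 1 || length(cols) != 1 ||
      !is.finite(rows) || !is.finite(cols) ||
      rows < 1 || cols < 1 || rows != floor(rows) || cols != floor(cols))
    stop("rows and cols must be positive integers")
  if (rows * cols < 2) stop("lattice must have at least 2 cells")
  id <- function(r, c) paste0("r", r, "c", c)
  steps <- list(c(0, 1), c(1, 0))
  if (scheme == "queen") steps <- c(steps, list(c(1, 1), c(1, -1)))
  nbrs <- vector("list", rows * cols)
  names(nbrs) <- as.vector(vapply(seq_len(cols), function(cc)
    vapply(seq_len(rows), function(rr) id(rr, cc), character(1)),
    character(rows)))
  add_edge <- function(a, b) {
    nbrs[[a]] <<- c(nbrs[[a]], b)
    nbrs[[b]] <<- c(nbrs[[b]], a)
  }
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (st in steps) {
      r2 <- r + st[1]; c2 <- c + st[2]
      if (r2 >= 1 && r2 <= rows && c2 >= 1 && c2 <= cols)
        add_edge(id(r, c), id(r2, c2))
    }
  }
  # order nodes row-major
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols), id)))
  g <- county_graph(ids, nbrs[ids])
  attr(g, "grid_rows") <- rows
  attr(g, "grid_cols") <- cols
  attr(g, "grid_scheme") <- scheme
  g
}

#' Read a county adjacency file
#'
#' Supports the GAL spatial-weights dialect (header line with the node count,
#' then alternating `id count` / neighbour-list records) and plain
#' whitespace-delimited edge lists (`from to` per line). Asymmetric input is
#' symmetrised with a warning; self-loops are rejected.
#'
#' @param path file path.
#' @param format `"gal"` or `"edges"`.
#' @returns A `county_graph`.
#' @seealso [write_graph_file()]
#' @export
read_graph_file <- function(path, format = c("gal", "edges")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty adjacency file: ", path)
  if (format == "gal") {
    # token stream: header line (node count, optionally preceded by 0), then
    # repeated records of id, neighbour count, and that many neighbour ids
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n_declared <- if (length(header) >= 2 && header[1] == "0")
      suppressWarnings(as.integer(header[2]))
    else suppressWarnings(as.integer(header[1]))
    toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"), use.names = FALSE)
    toks <- toks[nzchar(toks)]
    ids <- character(0); nbrs <- list()
    k <- 1L
    while (k <= length(toks)) {
      if (k + 1L > length(toks))
        stop("malformed GAL file: truncated record at token ", k)
      node <- toks[k]
      cnt <- suppressWarnings(as.integer(toks[k + 1L]))
      if (is.na(cnt) || cnt < 0)
        stop("malformed GAL record for node '", node, "'")
      if (k + 1L + cnt > length(toks))
        stop("GAL record for node '", node, "' declares ", cnt,
             " neighbours but the file ends early")
      nb <- if (cnt > 0) toks[(k + 2L):(k + 1L + cnt)] else character(0)
      ids <- c(ids, node)
      nbrs[[node]] <- nb
      k <- k + 2L + cnt
    }
    if (!is.na(n_declared) && n_declared != length(ids))
      warning("GAL header declares ", n_declared, " nodes; file lists ",
              length(ids))
    edges <- dplyr::bind_rows(purrr::imap(nbrs, function(nb, i) {
      if (length(nb)) tibble::tibble(from = i, to = nb) else NULL
    }))
    if (!nrow(edges)) edges <- tibble::tibble(from = character(), to = character())
  } else {
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad)) stop("edge-list line ", bad[1], " does not have 2 fields")
    edges <- tibble::tibble(from = vapply(parts, `[`, character(1), 1),
                            to = vapply(parts, `[`, character(1), 2))
    ids <- sort(unique(c(edges$from, edges$to)))
    nbrs <- NULL
  }
  if (any(edges$from == edges$to))
    stop("self-loop on node '", edges$from[edges$from == edges$to][1], "'")
  if (format == "gal") {
    unknown <- setdiff(unique(c(edges$from, edges$to)), ids)
    if (length(unknown))
      stop("edge references unknown node '", unknown[1], "'")
  }
  # symmetrise; GAL records list both directions, edge lists each pair once
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (format == "gal" && nrow(edges)) {
    fwd <- paste(edges$from, edges$to)
    rev <- paste(edges$to, edges$from)
    if (!all(rev %in% fwd))
      warning("asymmetric adjacency input symmetrised")
  }
  und <- unique(key(edges$from, edges$to))
  pairs <- do.call(rbind, strsplit(und, " "))
  nb_out <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) nb_out[[i]] <- character(0)
  if (!is.null(nrow(pairs))) for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    nb_out[[a]] <- c(nb_out[[a]], b)
    nb_out[[b]] <- c(nb_out[[b]], a)
  }
  county_graph(ids, nb_out)
}

#' Write a county adjacency file
#'
#' @param g a `county_graph`.
#' @param path destination file path.
#' @param format `"gal"` or `"edges"`. The GAL dialect writes a node-count
#'   header then `id count` / neighbour-list record pairs; `"edges"` writes
#'   one `from to` line per unordered edge (islands are not representable).
#' @returns `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("gal", "edges")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "county_graph"))
  if (format == "gal") {
    out <- as.character(length(g$node_ids))
    for (i in g$node_ids) {
      nb <- g$neighbours[[i]]
      out <- c(out, paste(i, length(nb)),
               if (length(nb)) paste(nb, collapse = " ") else "")
    }
    writeLines(out, path)
  } else {
    e <- graph_edges(g)
    if (any(g$L == 0))
      warning("island nodes dropped by edge-list format")
    writeLines(paste(e$from, e$to), path)
  }
  invisible(path)
}

#' Is the graph connected (over non-island nodes)?
#' @param g a `county_graph`.
#' @param ignore_islands drop zero-neighbour nodes before checking.
#' @returns logical.
#' @export
graph_connected <- function(g, ignore_islands = FALSE) {
  ids <- g$node_ids
  if (ignore_islands) ids <- ids[g$L[ids] > 0]
  if (length(ids) <= 1) return(TRUE)
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  queue <- ids[1]
  seen[ids[1]] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (j in g$neighbours[[cur]]) {
      if (j %in% ids && !seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}

#' Graph Laplacian matrix
#' @param g a `county_graph`.
#' @returns dense numeric matrix `diag(L) - A` in node order.
#' @export
graph_laplacian <- function(g) {
  n <- n_nodes(g)
  idx <- stats::setNames(seq_len(n), g$node_ids)
  M <- matrix(0, n, n, dimnames = list(g$node_ids, g$node_ids))
  for (i in g$node_ids) {
    M[i, g$neighbours[[i]]] <- -1
  }
  diag(M) <- g$L
  M
}

# CSR (0-based) encoding consumed by the C++ samplers
graph_csr <- function(g) {
  idx <- stats::setNames(seq_along(g$node_ids) - 1L, g$node_ids)
  nb <- lapply(g$node_ids, function(i) unname(idx[g$neighbours[[i]]]))
  list(adj = as.integer(unlist(nb, use.names = FALSE)),
       adj_start = as.integer(c(0L, cumsum(lengths(nb)))[seq_along(nb)]),
       nnbr = as.integer(lengths(nb)))
}
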