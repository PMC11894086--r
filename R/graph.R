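#' Graph container for evolutionary dynamics
#'
#' An `evo_graph` holds a symmetric 0/1 adjacency matrix with zero diagonal
#' over `N >= 2` nodes. Every individual occupies one node; links define the
#' replacement neighbourhood of the Moran process. Nodes are indexed 1..N in
#' R; on-disk edge lists use 0-based indices (see [read_graph()]).
#'
#' @param adjacency square numeric matrix with entries in \{0, 1\}, symmetric,
#'   zero diagonal.
#' @param name optional label carried along in outputs.
#' @return an object of class `evo_graph` with fields `adjacency`, `N`, `name`.
#' @examples
#' g <- evo_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' g$N
#' @export
evo_graph <- function(adjacency, name = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop_validation("adjacency must be a square matrix")
  A <- unname(adjacency * 1)
  N <- nrow(A)
  if (N < 2) stop_validation("a graph needs at least 2 nodes")
  if (anyNA(A) || !all(A %in% c(0, 1)))
    stop_validation("adjacency entries must be 0 or 1 (unweighted graph)")
  if (any(diag(A) != 0)) stop_validation("self-loops are not allowed")
  if (!isTRUE(all.equal(A, t(A))))
    stop_validation("adjacency must be symmetric (undirected graph)")
  structure(list(adjacency = A, N = N, name = name), class = "evo_graph")
}

#' @export
print.evo_graph <- function(x, ...) {
  cat(sprintf("<evo_graph%s: N = %d, edges = %d>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$N, sum(x$adjacency) / 2))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Construct a named graph
#'
#' Canonical structures used throughout: the star (node 1 is the centre, all
#' other nodes are leaves), the cycle, the complete graph, and the 2-D grid
#' (periodic by default, giving a 4-regular torus).
#'
#' @param kind one of `"star"`, `"cycle"`, `"complete"`, `"grid2d"`.
#' @param N number of nodes (star: >= 3, cycle: >= 3, complete: >= 2). For
#'   `grid2d` give `rows` and `cols` instead.
#' @param rows,cols grid dimensions (each >= 3 when `periodic`).
#' @param periodic wrap the grid into a torus (default `TRUE`).
#' @return an [evo_graph()].
#' @examples
#' make_named_graph("star", 8)
#' make_named_graph("grid2d", rows = 3, cols = 3)
#' @export
make_named_graph <- function(kind = c("star", "cycle", "complete", "grid2d"),
                             N = NULL, rows = NULL, cols = NULL,
                             periodic = TRUE) {
  kind <- match.arg(kind)
  if (kind == "grid2d") {
    if (is.null(rows) || is.null(cols)) {
      if (is.null(N)) stop_invalid("grid2d needs rows and cols")
      side <- sqrt(N)
      if (side != round(side)) stop_invalid("grid2d from N needs a square N")
      rows <- cols <- as.integer(side)
    }
    minside <- if (periodic) 3L else 2L
    if (rows < minside || cols < minside)
      stop_invalid("grid2d needs rows, cols >= ", minside)
    ig <- igraph::make_lattice(dimvector = c(rows, cols), periodic = periodic)
    A <- as.matrix(igraph::as_adjacency_matrix(ig))
    A[A > 1] <- 1  # 2x2 periodic lattices produce multi-edges; collapsed
    return(evo_graph(A, name = sprintf("grid2d:%dx%d%s", rows, cols,
                                       if (periodic) "" else ":flat")))
  }
  if (is.null(N)) stop_invalid(kind, " needs N")
  N <- as.integer(N)
  minN <- switch(kind, star = 3L, cycle = 3L, complete = 2L)
  if (is.na(N) || N < minN)
    stop_invalid(kind, " needs N >= ", minN)
  A <- matrix(0, N, N)
  if (kind == "star") {
    A[1, 2:N] <- 1
    A[2:N, 1] <- 1
  } else if (kind == "cycle") {
    idx <- cbind(1:N, c(2:N, 1))
    A[idx] <- 1
    A[idx[, 2:1]] <- 1
  } else {
    A[] <- 1
    diag(A) <- 0
  }
  evo_graph(A, name = paste0(kind, ":", N))
}

#' Sample a connected Erdős–Rényi graph
#'
#' Draws G(N, p) graphs and rejects disconnected ones, so the result follows
#' the G(N, p) distribution conditioned on connectivity. Deterministic given
#' `seed`; with `seed = NULL` the current RNG stream is used (this is how
#' [census()] draws its sequence of graphs).
#'
#' @param N number of nodes.
#' @param p edge probability in (0, 1].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param max_tries rejection budget before giving up.
#' @return a connected [evo_graph()].
#' @export
sample_er_connected <- function(N, p, seed = NULL, max_tries = 1e5) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stop_invalid("edge probability p must be in (0, 1]")
  if (N < 2) stop_invalid("N must be >= 2")
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      ig <- igraph::sample_gnp(N, p)
      if (igraph::is_connected(ig)) {
        A <- as.matrix(igraph::as_adjacency_matrix(ig))
        return(evo_graph(A, name = sprintf("er:%d:%g", N, p)))
      }
    }
    stop_sampling(sprintf(
      "no connected G(%d, %g) sample in %g draws; increase p or the budget",
      N, p, max_tries))
  })
}

#' Node temperatures
#'
#' The in-temperature of node i is \eqn{\sum_j a_{ji} / \sum_k a_{jk}}: the
#' total replacement pressure the node receives when each neighbour spreads
#' one unit of reproduction uniformly over its own links. High-degree nodes of
#' heterogeneous graphs are "hot": they turn over often, and under
#' temperature initialisation they are the likely home of the first mutant.
#' For undirected graphs in- and out-temperatures coincide; both sum to N.
#'
#' @param g an [evo_graph()].
#' @param direction `"in"` or `"out"`.
#' @return numeric vector of length `N`.
#' @examples
#' temperature(make_named_graph("star", 4)) # centre 3, leaves 1/3
#' @export
temperature <- function(g, direction = c("in", "out")) {
  direction <- match.arg(direction)
  stopifnot(inherits(g, "evo_graph"))
  A <- g$adjacency
  outdeg <- rowSums(A)
  indeg <- colSums(A)
  if (direction == "in") {
    if (any(outdeg == 0))
      stop_invalid("in-temperature undefined: graph has isolated nodes")
    colSums(A / outdeg)
  } else {
    if (any(indeg == 0))
      stop_invalid("out-temperature undefined: graph has isolated nodes")
    rowSums(t(t(A) / indeg))
  }
}

#' Connectivity and regularity checks
#'
#' @param g an [evo_graph()].
#' @return logical scalar.
#' @export
is_connected_graph <- function(g) {
  igraph::is_connected(as_igraph(g))
}

#' @rdname is_connected_graph
#' @export
is_regular_graph <- function(g) {
  deg <- rowSums(g$adjacency)
  length(unique(deg)) == 1L
}

check_connected <- function(g) {
  if (!is_connected_graph(g))
    stop_invalid("fixation probability is defined only if the graph is connected")
  invisible(TRUE)
}
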