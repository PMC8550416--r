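#' Directed acyclic graphs and partially directed graphs
#'
#' `dag()` constructs a directed acyclic graph over a fixed node set;
#' `pdag()` constructs a partially directed graph (directed arcs plus
#' undirected edges), the output type of constraint-based learning and of
#' [to_cpdag()].  Both are stored as adjacency matrices: `amat[i, j] == 1`
#' encodes the arc `i -> j`; in a `pdag`, `amat[i, j] == amat[j, i] == 1`
#' encodes the undirected edge `i - j`.
#'
#' Acyclicity, unknown endpoints, self-arcs and duplicate arcs are checked
#' on construction and after every mutation.
#'
#' @param nodes character vector of unique variable names.
#' @param arcs `NULL`, or a two-column matrix / data frame of `(from, to)`
#'   directed arcs.
#' @param undirected `NULL`, or a two-column matrix / data frame of
#'   unordered node pairs.
#' @return An object of class `smm_dag` (resp. `smm_pdag`).
#' @examples
#' g <- dag(c("A", "B", "C"), arcs = rbind(c("A", "B"), c("B", "C")))
#' arcs(g)
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_contract("duplicate node names")
  if (length(nodes) == 0L) stop_contract("a dag needs at least one node")
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "smm_dag")
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs))) g <- add_arc(g, arcs[i, 1L], arcs[i, 2L])
  }
  g
}

#' @rdname dag
#' @export
pdag <- function(nodes, arcs = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_contract("duplicate node names")
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat), class = "smm_pdag")
  chk <- function(a, b) {
    if (!(a %in% nodes) || !(b %in% nodes))
      stop_identifier("unknown node in edge %s-%s", a, b)
    if (a == b) stop_contract("self-edge at node %s", a)
  }
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    for (i in seq_len(nrow(arcs))) {
      chk(arcs[i, 1L], arcs[i, 2L])
      g$amat[arcs[i, 1L], arcs[i, 2L]] <- 1L
    }
  }
  if (!is.null(undirected) && NROW(undirected) > 0L) {
    undirected <- as.matrix(undirected)
    for (i in seq_len(nrow(undirected))) {
      chk(undirected[i, 1L], undirected[i, 2L])
      if (g$amat[undirected[i, 1L], undirected[i, 2L]] == 1L &&
          g$amat[undirected[i, 2L], undirected[i, 1L]] == 0L)
        stop_contract("edge %s-%s is both directed and undirected",
                      undirected[i, 1L], undirected[i, 2L])
      g$amat[undirected[i, 1L], undirected[i, 2L]] <- 1L
      g$amat[undirected[i, 2L], undirected[i, 1L]] <- 1L
    }
  }
  g
}

is_dag_object <- function(x) inherits(x, "smm_dag")
is_pdag_object <- function(x) inherits(x, "smm_pdag")

check_node <- function(g, x) {
  if (!all(x %in% g$nodes))
    stop_identifier("unknown node(s): %s",
                    paste(setdiff(x, g$nodes), collapse = ", "))
  invisible(x)
}

## Acyclicity test on an adjacency matrix of directed arcs (Kahn peeling).
amat_is_acyclic <- function(amat) {
  p <- nrow(amat)
  indeg <- colSums(amat)
  alive <- rep(TRUE, p)
  repeat {
    free <- which(alive & indeg == 0)
    if (length(free) == 0L) break
    alive[free] <- FALSE
    for (v in free) {
      ch <- which(amat[v, ] == 1L)
      indeg[ch] <- indeg[ch] - 1L
    }
  }
  !any(alive)
}

#' Add, drop or reverse an arc of a DAG
#'
#' Mutators return a new graph; acyclicity is re-checked on every addition
#' and reversal.
#'
#' @param g an `smm_dag`.
#' @param from,to arc endpoints (node names).
#' @return The modified `smm_dag`.
#' @export
add_arc <- function(g, from, to) {
  check_node(g, c(from, to))
  if (from == to) stop_contract("self-arc at node %s", from)
  if (g$amat[from, to] == 1L) stop_contract("arc %s->%s already present", from, to)
  g$amat[from, to] <- 1L
  if (!amat_is_acyclic(g$amat))
    stop_contract("arc %s->%s would create a directed cycle", from, to)
  g
}

#' @rdname add_arc
#' @export
drop_arc <- function(g, from, to) {
  check_node(g, c(from, to))
  g$amat[from, to] <- 0L
  g
}

#' @rdname add_arc
#' @export
reverse_arc <- function(g, from, to) {
  check_node(g, c(from, to))
  if (g$amat[from, to] != 1L) stop_contract("no arc %s->%s to reverse", from, to)
  g$amat[from, to] <- 0L
  g$amat[to, from] <- 1L
  if (!amat_is_acyclic(g$amat))
    stop_contract("reversing %s->%s would create a directed cycle", from, to)
  g
}

#' Graph accessors
#'
#' `arcs()` returns the directed arcs of a graph as a two-column data frame
#' (for a `pdag`, each undirected edge is reported once by
#' `undirected_edges()` instead).  `parents()`, `children()` and
#' `node_names()` are self-describing.
#'
#' @param g an `smm_dag` or `smm_pdag`.
#' @param x a node name.
#' @return `arcs()`/`undirected_edges()`: data frame with columns `from`,
#'   `to`; `parents()`/`children()`: character vector.
#' @export
arcs <- function(g) {
  a <- g$amat
  if (is_pdag_object(g)) a[a == 1L & t(a) == 1L] <- 0L
  idx <- which(a == 1L, arr.ind = TRUE)
  data.frame(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' @rdname arcs
#' @export
undirected_edges <- function(g) {
  if (!is_pdag_object(g)) return(data.frame(from = character(), to = character()))
  a <- g$amat == 1L & t(g$amat) == 1L
  a[lower.tri(a, diag = TRUE)] <- FALSE
  idx <- which(a, arr.ind = TRUE)
  data.frame(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' @rdname arcs
#' @export
parents <- function(g, x) {
  check_node(g, x)
  a <- g$amat
  if (is_pdag_object(g)) {
    und <- a == 1L & t(a) == 1L
    a[und] <- 0L
  }
  g$nodes[a[, x] == 1L]
}

#' @rdname arcs
#' @export
children <- function(g, x) {
  check_node(g, x)
  a <- g$amat
  if (is_pdag_object(g)) {
    und <- a == 1L & t(a) == 1L
    a[und] <- 0L
  }
  g$nodes[a[x, ] == 1L]
}

#' @rdname arcs
#' @export
node_names <- function(g) g$nodes

#' Deterministic topological order
#'
#' Kahn's algorithm with lexicographic tie-breaking on node names, so that
#' sampling orders (and therefore seeded draws) are identical across
#' platforms and across node orderings of the input.
#'
#' @param g an `smm_dag`.
#' @return Character vector: the nodes in topological order.
#' @export
topological_order <- function(g) {
  amat <- g$amat
  indeg <- colSums(amat)
  alive <- rep(TRUE, length(g$nodes))
  out <- character(0)
  repeat {
    free <- g$nodes[alive & indeg == 0]
    if (length(free) == 0L) break
    v <- sort(free)[1L]
    out <- c(out, v)
    alive[match(v, g$nodes)] <- FALSE
    ch <- which(amat[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
  }
  if (any(alive)) stop_contract("graph contains a directed cycle")
  out
}

## Ancestors (resp. descendants) of a node set, excluding the set itself
## unless reachable.
node_reach <- function(amat, nodes, start, up = TRUE) {
  p <- length(nodes)
  seen <- rep(FALSE, p)
  queue <- match(start, nodes)
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- if (up) which(amat[, v] == 1L) else which(amat[v, ] == 1L)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  nodes[seen]
}

ancestors_of <- function(g, x) setdiff(node_reach(g$amat, g$nodes, x, up = TRUE), x)
descendants_of <- function(g, x) setdiff(node_reach(g$amat, g$nodes, x, up = FALSE), x)

#' Skeleton and structural Hamming distance
#'
#' `skeleton_pairs()` lists the unordered adjacent pairs of a graph;
#' `shd()` is the number of unordered pairs on which two skeletons
#' disagree (direction is ignored), the structure-recovery metric used in
#' the stochastic tests.
#'
#' @param g,g1,g2 graphs (`smm_dag` or `smm_pdag`).
#' @return `skeleton_pairs()`: data frame `from`/`to` with `from < to`;
#'   `shd()`: non-negative integer.
#' @export
skeleton_pairs <- function(g) {
  a <- (g$amat + t(g$amat)) > 0
  a[lower.tri(a, diag = TRUE)] <- FALSE
  idx <- which(a, arr.ind = TRUE)
  pairs <- data.frame(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]],
                      stringsAsFactors = FALSE)
  swap <- pairs$from > pairs$to
  tmp <- pairs$from[swap]; pairs$from[swap] <- pairs$to[swap]; pairs$to[swap] <- tmp
  pairs[order(pairs$from, pairs$to), , drop = FALSE]
}

#' @rdname skeleton_pairs
#' @export
shd <- function(g1, g2) {
  k1 <- paste(skeleton_pairs(g1)$from, skeleton_pairs(g1)$to)
  k2 <- paste(skeleton_pairs(g2)$from, skeleton_pairs(g2)$to)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' @export
print.smm_dag <- function(x, ...) {
  a <- arcs(x)
  cat(sprintf("<dag> %d nodes, %d arcs\n", length(x$nodes), nrow(a)))
  if (nrow(a)) cat(paste0("  ", a$from, " -> ", a$to, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.smm_pdag <- function(x, ...) {
  a <- arcs(x); u <- undirected_edges(x)
  cat(sprintf("<pdag> %d nodes, %d directed arcs, %d undirected edges\n",
              length(x$nodes), nrow(a), nrow(u)))
  if (nrow(a)) cat(paste0("  ", a$from, " -> ", a$to, collapse = "\n"), "\n")
  if (nrow(u)) cat(paste0("  ", u$from, " -- ", u$to, collapse = "\n"), "\n")
  invisible(x)
}
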