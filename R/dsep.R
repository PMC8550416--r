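#' d-separation
#'
#' Tests whether `x` and `y` are d-separated given the conditioning set `z`
#' under the standard criterion: every path is blocked either by a
#' non-collider that lies in `z`, or by a collider whose
#' descendants-or-self avoid `z`.  Implemented via the
#' moralized-ancestral-graph reduction: restrict to the ancestral closure
#' of `{x, y} + z`, moralize (marry co-parents, drop directions), delete
#' `z`, and test graph separation.
#'
#' @param g an `smm_dag`.
#' @param x,y distinct node names, not contained in `z`.
#' @param z character vector (possibly empty) of conditioning nodes.
#' @return `TRUE` iff `x` and `y` are d-separated given `z`.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
#' d_separated(g, "A", "B", character(0))  # collider: TRUE
#' d_separated(g, "A", "B", "C")           # conditioning activates: FALSE
#' @export
d_separated <- function(g, x, y, z = character(0)) {
  z <- as.character(z)
  check_node(g, c(x, y, z))
  if (x == y) stop_contract("x and y must be distinct")
  if (x %in% z || y %in% z) stop_contract("x and y must not be in z")

  keep <- union(node_reach(g$amat, g$nodes, c(x, y, z), up = TRUE), c(x, y, z))
  idx <- match(keep, g$nodes)
  sub <- g$amat[idx, idx, drop = FALSE]
  # moralize: connect parents sharing a child, then drop directions
  und <- sub | t(sub)
  for (j in seq_along(keep)) {
    pa <- which(sub[, j] == 1L)
    if (length(pa) > 1L) und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  drop <- match(z, keep)
  if (length(drop)) { und[drop, ] <- FALSE; und[, drop] <- FALSE }
  # BFS from x to y in the moral graph
  src <- match(x, keep); dst <- match(y, keep)
  seen <- rep(FALSE, length(keep)); seen[src] <- TRUE
  queue <- src
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(und[v, ])
    nb <- nb[!seen[nb]]
    if (dst %in% nb) return(FALSE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  TRUE
}

#' Markov blanket of a node
#'
#' Parents, children and co-parents (other parents of the node's children),
#' excluding the node itself.  Conditioning on the blanket renders the node
#' independent of every other variable.
#'
#' @param g an `smm_dag`.
#' @param x a node name.
#' @return Character vector of blanket members, sorted.
#' @export
markov_blanket <- function(g, x) {
  check_node(g, x)
  ch <- children(g, x)
  co <- unlist(lapply(ch, function(c) parents(g, c)))
  sort(setdiff(union(parents(g, x), union(ch, co)), x))
}

## v-structures of a DAG: rows (a, c, b) with a -> c <- b, a and b
## non-adjacent, a < b lexicographically.
v_structures <- function(g) {
  out <- list()
  adj <- (g$amat + t(g$amat)) > 0
  for (c in g$nodes) {
    pa <- parents(g, c)
    if (length(pa) < 2L) next
    cmb <- utils::combn(sort(pa), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      if (!adj[a, b]) out[[length(out) + 1L]] <- c(a, c, b)
    }
  }
  if (!length(out)) return(matrix(character(0), 0, 3))
  do.call(rbind, out)
}

## Meek rules R1-R4 iterated to fixpoint on a mixed graph given as an
## adjacency matrix (one-way 1 = directed, two-way 1 = undirected).
meek_closure <- function(amat) {
  nodes <- rownames(amat)
  p <- length(nodes)
  repeat {
    changed <- FALSE
    dir <- amat == 1L & t(amat) == 0L
    und <- amat == 1L & t(amat) == 1L
    adj <- (amat + t(amat)) > 0
    orient <- function(i, j) { amat[j, i] <<- 0L; changed <<- TRUE }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!und[i, j] || i == j) next
      # R1: a -> i, i - j, a and j non-adjacent  =>  i -> j
      a <- which(dir[, i])
      if (any(!adj[a, j])) { orient(i, j); break }
      # R2: i -> c -> j with i - j  =>  i -> j
      if (any(dir[i, ] & dir[, j])) { orient(i, j); break }
      # R3: i - j, i - c, i - d, c -> j, d -> j, c and d non-adjacent => i -> j
      cand <- which(und[i, ] & dir[, j])
      if (length(cand) > 1L) {
        ok <- FALSE
        for (c1 in cand) { for (d1 in cand) {
          if (c1 < d1 && !adj[c1, d1]) { ok <- TRUE; break } }
          if (ok) break }
        if (ok) { orient(i, j); break }
      }
      # R4: i - j, i - d, d -> c, c -> j, j and d non-adjacent  =>  i -> j
      cand <- which(und[i, ] & !adj[, j])
      ok <- FALSE
      for (d1 in cand) {
        if (any(dir[d1, ] & dir[, j])) { ok <- TRUE; break }
      }
      if (ok) { orient(i, j); break }
    }
    if (!changed) break
  }
  amat
}

#' CPDAG of a DAG
#'
#' Returns the completed partially directed graph representing the Markov
#' equivalence class of `g`: the skeleton, the v-structure arcs, and every
#' further orientation compelled by Meek rules R1-R4 iterated to a
#' fixpoint; all remaining edges are undirected.
#'
#' @param g an `smm_dag`.
#' @return An `smm_pdag`.
#' @export
to_cpdag <- function(g) {
  amat <- matrix(0L, length(g$nodes), length(g$nodes),
                 dimnames = list(g$nodes, g$nodes))
  sk <- (g$amat + t(g$amat)) > 0
  amat[sk] <- 1L                       # everything undirected
  vs <- v_structures(g)
  if (nrow(vs)) for (k in seq_len(nrow(vs))) {
    amat[vs[k, 2L], vs[k, 1L]] <- 0L   # a -> c
    amat[vs[k, 2L], vs[k, 3L]] <- 0L   # b -> c
  }
  amat <- meek_closure(amat)
  out <- pdag(g$nodes)
  out$amat <- amat
  out
}

#' Consistent extension of a PDAG to a DAG
#'
#' Orients the undirected edges of a partially directed graph into a DAG
#' that preserves all directed arcs and creates no new v-structure
#' (Dor-Tarsi procedure).  Node choices are lexicographic, so the
#' extension is deterministic.  Used wherever a downstream consumer (CPT
#' fitting, sampling) needs a full DAG from a constraint-learning output.
#'
#' @param g an `smm_pdag` (an `smm_dag` is returned unchanged).
#' @return An `smm_dag`.
#' @export
consistent_extension <- function(g) {
  if (is_dag_object(g)) return(g)
  amat <- g$amat
  nodes <- g$nodes
  res <- amat                  # final orientation, filled as nodes retire
  alive <- rep(TRUE, length(nodes)); names(alive) <- nodes
  repeat {
    if (!any(alive)) break
    live <- nodes[alive]
    picked <- NULL
    for (x in sort(live)) {
      dir_out <- any(amat[x, live] == 1L & amat[live, x] == 0L)
      if (dir_out) next
      nb_und <- live[amat[x, live] == 1L & amat[live, x] == 1L]
      nb_all <- live[(amat[x, live] + amat[live, x]) > 0]
      ok <- TRUE
      for (y in nb_und) {
        others <- setdiff(nb_all, y)
        if (length(others) &&
            !all((amat[y, others] + amat[others, y]) > 0)) { ok <- FALSE; break }
      }
      if (ok) { picked <- x; break }
    }
    if (is.null(picked))
      stop_contract("pdag admits no consistent extension")
    x <- picked
    nb_und <- live[amat[x, live] == 1L & amat[live, x] == 1L]
    for (y in nb_und) { res[y, x] <- 1L; res[x, y] <- 0L }
    amat[x, ] <- 0L; amat[, x] <- 0L
    alive[x] <- FALSE
  }
  out <- dag(nodes)
  out$amat <- res
  if (!amat_is_acyclic(res)) stop_contract("extension produced a cycle")
  out
}
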