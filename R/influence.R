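#' Unblocked simple paths between two nodes
#'
#' Enumerates the simple paths between `x` and `y` in the skeleton of the
#' DAG that are d-connecting given the empty conditioning set, i.e. that
#' contain no collider (an interior node whose two path edges both point
#' into it).  With `directed_only = TRUE` only paths that follow arc
#' directions from `x` to `y` are returned.  Paths are ordered shortest
#' first, then lexicographically by node sequence.
#'
#' @param g an `smm_dag`.
#' @param x,y distinct node names.
#' @param directed_only logical (default `FALSE`).
#' @return List of character vectors (node sequences from `x` to `y`).
#' @export
unblocked_paths <- function(g, x, y, directed_only = FALSE) {
  check_node(g, c(x, y))
  if (x == y) stop_contract("x and y must be distinct")
  nodes <- g$nodes
  amat <- g$amat
  sk <- (amat + t(amat)) > 0
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    nb <- nodes[if (directed_only) amat[v, ] == 1L else sk[v, ]]
    for (w in sort(nb)) {
      if (w %in% path) next
      if (!directed_only && length(path) >= 2L) {
        u <- path[length(path) - 1L]
        if (amat[u, v] == 1L && amat[w, v] == 1L) next  # collider at v
      }
      if (w == y) paths[[length(paths) + 1L]] <<- c(path, w)
      else walk(c(path, w))
    }
  }
  walk(x)
  if (!length(paths)) return(list())
  key <- vapply(paths, function(p)
    sprintf("%04d %s", length(p), paste(p, collapse = " ")), "")
  paths[order(key)]
}

#' Distance Weighted Influence
#'
#' `dwi()` scores the influence of `x` on `y` as the sum over unblocked
#' simple paths of `w ^ length(path)` with a constant `w` in `[0, 1]`
#' (at `w = 1` this is the unblocked path count).  `dwi_weighted()`
#' replaces the constant per-path weight with the product of the bootstrap
#' strengths of the arcs along the path; an arc traversed against its
#' direction uses the stored strength of the arc unchanged (strengths are
#' properties of edges in the averaged model).
#'
#' @param g an `smm_dag`.
#' @param x,y distinct node names.
#' @param w constant weight in `[0, 1]`.
#' @param strengths an `arc_strength_table` (see
#'   [bootstrap_arc_strength()]) covering every arc on every unblocked
#'   path.
#' @param directed_only restrict to directed paths.
#' @return A non-negative score (0 when no unblocked path exists).
#' @export
dwi <- function(g, x, y, w, directed_only = FALSE) {
  if (!is_scalar_number(w) || w < 0 || w > 1)
    stop_contract("w must lie in [0, 1]")
  paths <- unblocked_paths(g, x, y, directed_only)
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) w ^ (length(p) - 1L), 0))
}

#' @rdname dwi
#' @export
dwi_weighted <- function(g, strengths, x, y, directed_only = FALSE) {
  paths <- unblocked_paths(g, x, y, directed_only)
  if (!length(paths)) return(0)
  amat <- g$amat
  path_weight <- function(p) {
    wgt <- 1
    for (k in seq_len(length(p) - 1L)) {
      a <- p[k]; b <- p[k + 1L]
      from <- if (amat[a, b] == 1L) a else b
      to <- if (amat[a, b] == 1L) b else a
      hit <- strengths$from == from & strengths$to == to
      if (!any(hit))
        stop_config("no strength recorded for arc %s->%s", from, to)
      wgt <- wgt * strengths$strength[which(hit)[1L]]
    }
    wgt
  }
  sum(vapply(paths, path_weight, 0))
}

#' Strength-weighted influence ranking towards a target
#'
#' Removes any excluded arcs (implausible links vetoed by prior
#' knowledge), computes [dwi_weighted()] from every other node to
#' `target`, and returns the scores sorted descending with lexicographic
#' tie-breaking.  Nodes whose only connections run through colliders
#' score 0.
#'
#' @param g an `smm_dag`.
#' @param strengths an `arc_strength_table`.
#' @param target target node name.
#' @param exclusions `NULL` or a data frame / matrix of arcs to delete
#'   before scoring.
#' @param w optional constant weight; when supplied the constant-w [dwi()]
#'   is used instead of arc strengths.
#' @param directed_only restrict to directed paths.
#' @return A `dwi_result`: data frame `node`, `score` plus attributes
#'   `target` and `mode`.
#' @export
rank_influence <- function(g, strengths = NULL, target, exclusions = NULL,
                           w = NULL, directed_only = FALSE) {
  check_node(g, target)
  if (!is.null(exclusions) && NROW(exclusions)) {
    ex <- as.matrix(exclusions)
    for (k in seq_len(nrow(ex))) g <- drop_arc(g, ex[k, 1L], ex[k, 2L])
  }
  mode <- if (is.null(w)) "strength-weighted" else "constant-w"
  if (mode == "strength-weighted" && is.null(strengths))
    stop_config("strength-weighted ranking needs an arc strength table")
  score <- vapply(setdiff(g$nodes, target), function(v) {
    if (mode == "constant-w") dwi(g, v, target, w, directed_only)
    else dwi_weighted(g, strengths, v, target, directed_only)
  }, 0)
  nodes <- setdiff(g$nodes, target)
  ord <- order(-score, nodes)
  structure(data.frame(node = nodes[ord], score = unname(score[ord]),
                       stringsAsFactors = FALSE),
            target = target, mode = mode, w = w,
            class = c("dwi_result", "data.frame"))
}
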