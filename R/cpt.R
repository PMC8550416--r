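#' Conditional probability table sets
#'
#' A `cpt_set` carries, for every node of a DAG, a probability matrix with
#' one column per parent configuration (first parent varying fastest,
#' matching R's array convention) and one row per level of the node.
#' Every column is validated to be non-negative and to sum to 1 within
#' `1e-9`.
#'
#' @param g an `smm_dag`.
#' @param levels named list of character level vectors, one per node.
#' @param tables named list; each element is either an `r x q` matrix or a
#'   list with elements `parents` (character) and `prob` (matrix).  When
#'   `parents` is omitted it defaults to the node's parents in `g`, ordered
#'   as in `node_names(g)`.
#' @return An object of class `cpt_set`.
#' @export
cpt_set <- function(g, levels, tables) {
  if (!all(g$nodes %in% names(levels)))
    stop_contract("levels must cover every node")
  out <- list(nodes = g$nodes, levels = levels[g$nodes], tables = list())
  for (v in g$nodes) {
    tb <- tables[[v]]
    if (is.null(tb)) stop_contract("missing CPT for node %s", v)
    if (is.matrix(tb) || is.numeric(tb)) tb <- list(prob = tb)
    pa <- tb$parents %||% intersect(g$nodes, parents(g, v))
    prob <- tb$prob
    if (!is.matrix(prob)) prob <- matrix(prob, nrow = length(levels[[v]]))
    r <- length(levels[[v]])
    q <- prod(vapply(levels[pa], length, 1L))
    if (nrow(prob) != r || ncol(prob) != q)
      stop_contract("CPT for %s must be %d x %d, got %d x %d",
                    v, r, q, nrow(prob), ncol(prob))
    if (any(prob < -1e-12))
      stop_contract("negative probability in CPT for %s", v)
    if (any(abs(colSums(prob) - 1) > 1e-9))
      stop_contract("CPT columns for %s must sum to 1", v)
    out$tables[[v]] <- list(parents = pa, prob = prob)
  }
  structure(out, class = "cpt_set")
}

#' @export
print.cpt_set <- function(x, ...) {
  cat(sprintf("<cpt_set> %d nodes\n", length(x$nodes)))
  invisible(x)
}

#' Fit conditional probability tables by frequency counts
#'
#' Maximum-likelihood (optionally smoothed) parameter fitting on complete
#' discrete data: each entry is `(N_ijk + s) / (N_ij + s * r_i)` where `s`
#' is the smoothing pseudo-count.  With `smoothing = 0`, parent
#' configurations never observed in the data receive the uniform
#' distribution over the node's levels, so downstream prediction never
#' meets a zero-probability stratum.
#'
#' @param g an `smm_dag` whose nodes all appear in `data`.
#' @param data a [discrete_dataset()].
#' @param smoothing non-negative pseudo-count (default 0, plain frequency
#'   counts).
#' @return A [cpt_set()].
#' @export
fit_cpts <- function(g, data, smoothing = 0) {
  if (!all(g$nodes %in% dataset_vars(data)))
    stop_contract("dag nodes must be a subset of the data variables")
  if (!is_scalar_number(smoothing) || smoothing < 0)
    stop_contract("smoothing must be a non-negative number")
  nl <- dataset_nlev(data)
  tables <- list()
  for (v in g$nodes) {
    pa <- intersect(g$nodes, parents(g, v))
    r <- nl[[v]]
    radix <- nl[pa]
    q <- as.integer(prod(radix))
    cfg <- config_index(data$x[, pa, drop = FALSE], radix)
    cnt <- tabulate(data$x[, v] + r * (cfg - 1L), nbins = r * q)
    cnt <- matrix(cnt, nrow = r, ncol = q)
    tot <- colSums(cnt)
    prob <- sweep(cnt + smoothing, 2L, tot + smoothing * r, "/")
    empty <- tot + smoothing * r == 0
    if (any(empty)) prob[, empty] <- 1 / r
    tables[[v]] <- list(parents = pa, prob = prob)
  }
  cpt_set(g, data$levels[g$nodes], tables)
}

## Resolve a named assignment of level labels (or indices) to indices.
resolve_levels <- function(cpts, assignment) {
  vars <- names(assignment)
  if (is.null(vars) || !all(vars %in% cpts$nodes))
    stop_identifier("unknown variable(s) in assignment: %s",
                    paste(setdiff(vars, cpts$nodes), collapse = ", "))
  idx <- integer(length(vars)); names(idx) <- vars
  for (v in vars) {
    val <- assignment[[v]]
    if (is.numeric(val)) {
      i <- as.integer(val)
    } else {
      i <- match(as.character(val), cpts$levels[[v]])
    }
    if (is.na(i) || i < 1L || i > length(cpts$levels[[v]]))
      stop_identifier("value %s is not a level of %s", as.character(val), v)
    idx[[v]] <- i
  }
  idx
}

#' Joint probability of a full assignment
#'
#' The chain-rule product over nodes of `P(x_i | pa(x_i))`: the network's
#' factorization of the joint distribution.
#'
#' @param g an `smm_dag`.
#' @param cpts a [cpt_set()] for `g`.
#' @param assignment named vector/list covering every node (level labels or
#'   1-based level indices).
#' @return A probability.
#' @export
joint_probability <- function(g, cpts, assignment) {
  if (!setequal(names(assignment), g$nodes))
    stop_contract("assignment must cover every node exactly")
  idx <- resolve_levels(cpts, assignment)
  p <- 1
  for (v in g$nodes) {
    tb <- cpts$tables[[v]]
    radix <- vapply(cpts$levels[tb$parents], length, 1L)
    cfg <- config_index(matrix(idx[tb$parents], nrow = 1L), radix)
    p <- p * tb$prob[idx[[v]], cfg]
  }
  unname(p)
}

## Enumerate the joint distribution over `vars` (a topologically closed,
## ancestrally closed set).  Returns list(vars, radix, prob) where prob is
## a vector over the mixed-radix cells (first var fastest).
enumerate_joint <- function(cpts, vars) {
  radix <- vapply(cpts$levels[vars], length, 1L)
  M <- prod(radix)
  if (log2(M) > 25)
    stop_contract("network too large to enumerate (%.1f binary-equivalent nodes)", log2(M))
  M <- as.integer(M)
  cells <- 0:(M - 1L)
  idx <- list(); stride <- 1
  for (v in vars) {
    idx[[v]] <- (cells %/% stride) %% radix[[v]] + 1L
    stride <- stride * radix[[v]]
  }
  prob <- rep(1, M)
  for (v in vars) {
    tb <- cpts$tables[[v]]
    if (!all(tb$parents %in% vars))
      stop_contract("enumeration set is not ancestrally closed at %s", v)
    pr <- vapply(cpts$levels[tb$parents], length, 1L)
    if (length(tb$parents)) {
      cfg <- idx[[tb$parents[1L]]] - 1L
      stridep <- pr[1L]
      if (length(tb$parents) > 1L) for (j in 2L:length(tb$parents)) {
        cfg <- cfg + (idx[[tb$parents[j]]] - 1L) * stridep
        stridep <- stridep * pr[j]
      }
      cfg <- cfg + 1L
    } else cfg <- rep.int(1L, M)
    prob <- prob * tb$prob[cbind(idx[[v]], cfg)]
  }
  list(vars = vars, radix = radix, idx = idx, prob = prob)
}

#' Exact conditional probability by enumeration
#'
#' Ground-truth oracle for the Monte-Carlo machinery: computes
#' `P(event | evidence)` by exhaustive summation of the chain-rule joint,
#' after pruning to the ancestral closure of the mentioned variables
#' (barren nodes integrate to 1).  Guarded at 25 binary-equivalent nodes.
#'
#' @param g an `smm_dag`.
#' @param cpts a [cpt_set()].
#' @param event,evidence named vectors of level labels (disjoint variable
#'   sets); `evidence` may be empty.
#' @return A probability.
#' @export
exact_query <- function(g, cpts, event, evidence = NULL) {
  ev_vars <- names(evidence)
  # an event variable that is also instantiated as evidence is trivially
  # determined: probability 1 when the levels agree, 0 otherwise
  overlap <- intersect(names(event), ev_vars)
  for (v in overlap) {
    if (!identical(as.character(event[[v]]), as.character(evidence[[v]])))
      return(0)
  }
  event <- event[setdiff(names(event), overlap)]
  if (!length(event)) return(1)
  target <- union(names(event), ev_vars)
  check_node(g, target)
  keep <- union(node_reach(g$amat, g$nodes, target, up = TRUE), target)
  keep <- intersect(topological_order(g), keep)
  sub_cpts <- cpts
  joint <- enumerate_joint(sub_cpts, keep)
  ev_idx <- if (length(evidence)) resolve_levels(cpts, evidence) else integer(0)
  e_idx <- resolve_levels(cpts, event)
  mask_ev <- rep(TRUE, length(joint$prob))
  for (v in names(ev_idx)) mask_ev <- mask_ev & joint$idx[[v]] == ev_idx[[v]]
  p_ev <- sum(joint$prob[mask_ev])
  if (p_ev <= 0)
    stop_degenerate("evidence has probability zero; conditional undefined")
  mask_e <- mask_ev
  for (v in names(e_idx)) mask_e <- mask_e & joint$idx[[v]] == e_idx[[v]]
  sum(joint$prob[mask_e]) / p_ev
}

#' Ancestral (forward) sampling
#'
#' Draws complete records root-to-leaf along the deterministic topological
#' order of [topological_order()]; identical `(seed, n)` reproduce
#' identical datasets on any platform.
#'
#' @param g an `smm_dag`.
#' @param cpts a [cpt_set()].
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @param layers optional named layer tags for the resulting dataset.
#' @return A [discrete_dataset()].
#' @export
ancestral_sample <- function(g, cpts, n, seed = 1L, layers = NULL) {
  if (!is_scalar_number(n) || n < 1) stop_contract("n must be >= 1")
  n <- as.integer(n)
  ord <- topological_order(g)
  x <- matrix(0L, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  with_seed(seed, {
    for (v in ord) {
      tb <- cpts$tables[[v]]
      r <- length(cpts$levels[[v]])
      radix <- vapply(cpts$levels[tb$parents], length, 1L)
      cfg <- config_index(x[, tb$parents, drop = FALSE], radix)
      cum <- apply(tb$prob, 2L, cumsum)        # r x q
      u <- stats::runif(n)
      # level = 1 + number of cumulative bins strictly below u
      pc <- t(cum)[cfg, , drop = FALSE]        # n x r
      lev <- 1L + as.integer(rowSums(u > pc[, -r, drop = FALSE]))
      x[, v] <- pmin(lev, r)
    }
  })
  discrete_dataset(x, layers = layers, levels = cpts$levels[g$nodes])
}
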