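# Independent brute-force oracles used to cross-check the package.  These
# deliberately re-derive everything from first principles (explicit
# assignment grids, row-by-row products, naive path recursion) and share
# no code path with the implementation under test.

# Full joint distribution of a small network as a data frame: one row per
# complete assignment (level indices) plus a `prob` column.
oracle_joint <- function(g, cpts) {
  vars <- g$nodes
  lv <- lapply(cpts$levels[vars], seq_along)
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  prob <- rep(1, nrow(grid))
  for (v in vars) {
    tb <- cpts$tables[[v]]
    for (r in seq_len(nrow(grid))) {
      cfg <- 1L
      stride <- 1L
      for (pa in tb$parents) {
        cfg <- cfg + (grid[r, pa] - 1L) * stride
        stride <- stride * length(cpts$levels[[pa]])
      }
      prob[r] <- prob[r] * tb$prob[grid[r, v], cfg]
    }
  }
  grid$prob <- prob
  grid
}

# Conditional independence X _||_ Y | Z under the enumerated joint.
oracle_ci <- function(joint, x, y, z, tol = 1e-9) {
  zg <- if (length(z)) unique(joint[z]) else data.frame(row.names = 1)
  for (r in seq_len(nrow(zg))) {
    sel <- rep(TRUE, nrow(joint))
    for (v in z) sel <- sel & joint[[v]] == zg[r, v]
    pz <- sum(joint$prob[sel])
    if (pz <= tol) next
    for (xi in unique(joint[[x]])) for (yi in unique(joint[[y]])) {
      pxy <- sum(joint$prob[sel & joint[[x]] == xi & joint[[y]] == yi]) / pz
      px <- sum(joint$prob[sel & joint[[x]] == xi]) / pz
      py <- sum(joint$prob[sel & joint[[y]] == yi]) / pz
      if (abs(pxy - px * py) > tol) return(FALSE)
    }
  }
  TRUE
}

# Exact conditional P(event | evidence) from the enumerated joint.
oracle_query <- function(joint, cpts, event, evidence = NULL) {
  sel <- rep(TRUE, nrow(joint))
  for (v in names(evidence))
    sel <- sel & joint[[v]] == match(evidence[[v]], cpts$levels[[v]])
  pe <- sum(joint$prob[sel])
  for (v in names(event))
    sel <- sel & joint[[v]] == match(event[[v]], cpts$levels[[v]])
  sum(joint$prob[sel]) / pe
}

# All collider-free simple paths between x and y (naive recursion over the
# skeleton, with an explicit direction check at every interior node).
oracle_paths <- function(g, x, y) {
  nodes <- g$nodes
  am <- g$amat
  out <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    for (w in nodes) {
      if (w %in% path) next
      if (am[last, w] == 0L && am[w, last] == 0L) next
      if (length(path) >= 2L) {
        prev <- path[length(path) - 1L]
        if (am[prev, last] == 1L && am[w, last] == 1L) next
      }
      if (w == y) out[[length(out) + 1L]] <<- c(path, w) else recurse(c(path, w))
    }
  }
  recurse(x)
  out
}

# All 25 DAGs over three named nodes, as adjacency matrices.
oracle_dags3 <- function(nodes = c("A", "B", "C")) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    am <- matrix(0L, 3L, 3L, dimnames = list(nodes, nodes))
    st <- c(s1, s2, s3)
    for (k in 1:3) {
      if (st[k] == 1L) am[pairs[[k]][1L], pairs[[k]][2L]] <- 1L
      if (st[k] == 2L) am[pairs[[k]][2L], pairs[[k]][1L]] <- 1L
    }
    p2 <- am %*% am
    if (any(diag(p2) > 0) || any(diag(p2 %*% am) > 0)) next
    out[[length(out) + 1L]] <- am
  }
  out
}

# Best BIC score over all 25 three-node DAGs (exhaustive oracle).
oracle_best3_score <- function(data, score = "bic") {
  nodes <- colnames(data$x)
  max(vapply(oracle_dags3(nodes), function(am)
    sum(vapply(nodes, function(v)
      family_score(v, nodes[am[, v] == 1L], data, score), 0)), 0))
}
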