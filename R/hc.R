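#' Score-based structure search
#'
#' `hill_climb()` greedily applies the single best score-improving move
#' among arc additions, deletions and reversals, starting from the empty
#' graph plus any whitelisted arcs, until it reaches a one-move local
#' maximum.  `tabu_search()` continues past local maxima: when no
#' improving move exists it takes the best non-tabu (possibly worsening)
#' move, keeps a fixed-length tabu list of move inverses, allows a bounded
#' number of consecutive non-improving steps, and returns the best-scoring
#' graph encountered.  Both honour blacklists/whitelists, are fully
#' deterministic (ties broken by move type add < delete < reverse, then
#' `from`, then `to`), and never return a constraint-violating graph.
#'
#' @param data a [discrete_dataset()].
#' @param config an [algorithm_config()]; its `score`, `tabu_len`,
#'   `max_noimprove` and `max_parents` fields are used.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param restrict_pairs optional data frame of unordered pairs; when
#'   given, additions are restricted to these pairs (the hybrid
#'   restrict-maximize mechanism).
#' @return An `smm_dag`.
#' @export
hill_climb <- function(data, config = algorithm_config("hc"),
                       constraints = NULL, restrict_pairs = NULL) {
  greedy_engine(data, config, constraints, restrict_pairs, tabu = FALSE)
}

#' @rdname hill_climb
#' @export
tabu_search <- function(data, config = algorithm_config("tabu"),
                        constraints = NULL, restrict_pairs = NULL) {
  greedy_engine(data, config, constraints, restrict_pairs, tabu = TRUE)
}

greedy_engine <- function(data, config, constraints, restrict_pairs, tabu) {
  nodes <- dataset_vars(data)
  p <- length(nodes)
  score <- config$score
  cm <- constraint_matrices(constraints, nodes)
  allow <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(restrict_pairs)) {
    allow[, ] <- FALSE
    if (NROW(restrict_pairs)) {
      rp <- as.matrix(restrict_pairs)
      allow[rp] <- TRUE
      allow[rp[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
  }
  allow[cm$bl] <- FALSE
  allow[cm$wl] <- TRUE
  diag(allow) <- FALSE

  g <- dag(nodes)
  wl_arcs <- which(cm$wl, arr.ind = TRUE)
  if (nrow(wl_arcs)) for (k in seq_len(nrow(wl_arcs)))
    g <- add_arc(g, nodes[wl_arcs[k, 1L]], nodes[wl_arcs[k, 2L]])

  fs <- function(v, pa) family_score(v, pa, data, score)
  pa_of <- function(v) nodes[g$amat[, v] == 1L]
  fam <- vapply(nodes, function(v) fs(v, pa_of(v)), 0)

  # Dadd[i, j]: score delta of giving j the extra parent i (legality is
  # checked at selection time); Ddel[i, j]: delta of removing parent i.
  Dadd <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  Ddel <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  refresh_child <- function(j) {
    pa <- pa_of(j)
    for (i in nodes) {
      if (i == j) next
      if (i %in% pa) {
        Ddel[i, j] <<- fs(j, setdiff(pa, i)) - fam[[j]]
        Dadd[i, j] <<- NA_real_
      } else if (allow[i, j] || allow[j, i]) {
        Dadd[i, j] <<- fs(j, c(pa, i)) - fam[[j]]
        Ddel[i, j] <<- NA_real_
      } else {
        Dadd[i, j] <<- NA_real_
        Ddel[i, j] <<- NA_real_
      }
    }
  }
  for (j in nodes) refresh_child(j)

  creates_cycle_add <- function(i, j)
    i %in% node_reach(g$amat, nodes, j, up = FALSE)
  creates_cycle_rev <- function(i, j) {
    # reversing i -> j adds j -> i: a cycle exists iff some other
    # directed path i ~> j remains
    am <- g$amat; am[i, j] <- 0L
    j %in% node_reach(am, nodes, i, up = FALSE)
  }

  eps <- 1e-9
  tabu_list <- character(0)
  max_parents <- config$max_parents %||% Inf
  best_amat <- g$amat
  cur_score <- sum(fam)
  best_score <- cur_score
  noimprove <- 0L

  repeat {
    npar <- colSums(g$amat)
    cand <- list()
    ok_add <- !is.na(Dadd) & allow & g$amat == 0L & t(g$amat) == 0L
    ok_add[, npar >= max_parents] <- FALSE
    ia <- which(ok_add, arr.ind = TRUE)
    if (nrow(ia)) cand$add <- data.frame(
      type = 0L, from = nodes[ia[, 1L]], to = nodes[ia[, 2L]],
      delta = Dadd[ia], stringsAsFactors = FALSE)
    ok_del <- !is.na(Ddel) & g$amat == 1L & !cm$wl
    id <- which(ok_del, arr.ind = TRUE)
    if (nrow(id)) cand$del <- data.frame(
      type = 1L, from = nodes[id[, 1L]], to = nodes[id[, 2L]],
      delta = Ddel[id], stringsAsFactors = FALSE)
    ok_rev <- g$amat == 1L & !cm$wl & t(allow)
    ok_rev[npar >= max_parents, ] <- FALSE   # reversal adds a parent to `from`
    ir <- which(ok_rev, arr.ind = TRUE)
    if (nrow(ir)) {
      dl <- Ddel[ir]
      da <- Dadd[cbind(ir[, 2L], ir[, 1L])]
      keep <- !is.na(dl) & !is.na(da)
      ir <- ir[keep, , drop = FALSE]
      if (nrow(ir)) cand$rev <- data.frame(
        type = 2L, from = nodes[ir[, 1L]], to = nodes[ir[, 2L]],
        delta = dl[keep] + da[keep], stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || !nrow(cand)) break
    cand <- cand[order(-cand$delta, cand$type, cand$from, cand$to), , drop = FALSE]

    chosen <- NULL
    for (k in seq_len(nrow(cand))) {
      mv <- cand[k, ]
      if (!tabu && mv$delta <= eps) break
      if (tabu && paste(mv$type, mv$from, mv$to) %in% tabu_list) next
      legal <- switch(as.character(mv$type),
        "0" = !creates_cycle_add(mv$from, mv$to),
        "1" = TRUE,
        "2" = !creates_cycle_rev(mv$from, mv$to))
      if (legal) { chosen <- mv; break }
    }
    if (is.null(chosen)) break

    inverse_key <- switch(as.character(chosen$type),
      "0" = paste(1L, chosen$from, chosen$to),
      "1" = paste(0L, chosen$from, chosen$to),
      "2" = paste(2L, chosen$to, chosen$from))
    changed <- if (chosen$type == 2L) c(chosen$from, chosen$to) else chosen$to
    if (chosen$type == 0L) {
      g$amat[chosen$from, chosen$to] <- 1L
    } else if (chosen$type == 1L) {
      g$amat[chosen$from, chosen$to] <- 0L
    } else {
      g$amat[chosen$from, chosen$to] <- 0L
      g$amat[chosen$to, chosen$from] <- 1L
    }
    cur_score <- cur_score + chosen$delta
    for (v in changed) fam[[v]] <- fs(v, pa_of(v))
    for (v in changed) refresh_child(v)
    if (tabu) {
      tabu_list <- c(inverse_key, tabu_list)
      if (length(tabu_list) > config$tabu_len)
        tabu_list <- tabu_list[seq_len(config$tabu_len)]
    }

    if (cur_score > best_score + eps) {
      best_score <- cur_score
      best_amat <- g$amat
      noimprove <- 0L
    } else {
      noimprove <- noimprove + 1L
      if (tabu && noimprove >= config$max_noimprove) break
    }
  }

  out <- dag(nodes)
  out$amat <- best_amat
  if (!amat_is_acyclic(best_amat)) stop_contract("search produced a cycle")
  out
}
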