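## Cached G2 tester: one cache environment per learning run.
make_tester <- function(data, alpha, guard) {
  cache <- new.env(parent = emptyenv())
  function(x, y, z = character(0)) {
    z <- sort(z)
    key <- if (x < y) paste(x, y, paste(z, collapse = ","))
           else paste(y, x, paste(z, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- ci_test_g2(x, y, z, data, alpha = alpha, guard = guard)
    cache[[key]] <- res
    res
  }
}

subsets_up_to <- function(set, k) {
  out <- list(character(0))
  for (s in seq_len(min(k, length(set)))) {
    cmb <- utils::combn(set, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Markov blanket discovery
#'
#' Learns the Markov blanket of `target` from data with one of the
#' classical constraint-based discovery schemes, all driven by the G2
#' test: grow-shrink (`"gs"`: add any variable dependent given the current
#' blanket, then remove any member independent given the rest), `"iamb"`
#' (grow by maximal association, then backward removal), `"fast-iamb"`
#' (speculative ranked batch additions per pass) and `"inter-iamb"`
#' (backward removal interleaved after every addition).
#'
#' @param target variable name.
#' @param data a [discrete_dataset()].
#' @param variant one of `"gs"`, `"iamb"`, `"fast-iamb"`, `"inter-iamb"`.
#' @param alpha test level.
#' @param guard logical, see [ci_test_g2()].
#' @param tester internal: a shared cached tester.
#' @return Character vector (sorted): the estimated blanket; never
#'   contains `target`.
#' @export
learn_markov_blanket <- function(target, data, variant = "iamb",
                                 alpha = 0.05, guard = TRUE, tester = NULL) {
  vars <- dataset_vars(data)
  if (!target %in% vars) stop_identifier("unknown target %s", target)
  variant <- match.arg(variant, c("gs", "iamb", "fast-iamb", "inter-iamb"))
  test <- tester %||% make_tester(data, alpha, guard)
  others <- setdiff(vars, target)
  mb <- character(0)

  backward <- function(mb) {
    repeat {
      removed <- FALSE
      for (y in mb) {
        if (test(target, y, setdiff(mb, y))$independent) {
          mb <- setdiff(mb, y); removed <- TRUE
        }
      }
      if (!removed) break
    }
    mb
  }

  if (variant == "gs") {
    repeat {
      added <- FALSE
      for (y in setdiff(others, mb)) {
        if (!test(target, y, mb)$independent) { mb <- c(mb, y); added <- TRUE }
      }
      if (!added) break
    }
    mb <- backward(mb)
  } else if (variant %in% c("iamb", "inter-iamb")) {
    seen <- character(0)          # blanket states; repetition => oscillation
    repeat {
      state <- paste(sort(mb), collapse = ",")
      if (state %in% seen) break
      seen <- c(seen, state)
      rest <- setdiff(others, mb)
      if (!length(rest)) break
      res <- lapply(rest, function(y) test(target, y, mb))
      dep <- !vapply(res, `[[`, TRUE, "independent")
      if (!any(dep)) break
      pv <- vapply(res, `[[`, 0, "p_value")
      pick <- rest[dep][order(pv[dep], rest[dep])][1L]
      mb <- c(mb, pick)
      if (variant == "inter-iamb") mb <- backward(mb)
    }
    mb <- backward(mb)
  } else { # fast-iamb
    nl <- dataset_nlev(data)
    n <- nrow(data$x)
    seen <- character(0)
    repeat {
      state <- paste(sort(mb), collapse = ",")
      if (state %in% seen) break
      seen <- c(seen, state)
      rest <- setdiff(others, mb)
      if (!length(rest)) break
      res <- lapply(rest, function(y) test(target, y, mb))
      dep <- !vapply(res, `[[`, TRUE, "independent")
      if (!any(dep)) break
      pv <- vapply(res, `[[`, 0, "p_value")
      ranked <- rest[dep][order(pv[dep], rest[dep])]
      # speculative batch: keep adding while the conditioning set stays
      # within the data's resolution (N >= 5 df for the next test)
      batch <- character(0)
      for (y in ranked) {
        df_next <- (nl[[target]] - 1) * (max(nl[ranked]) - 1) *
          prod(nl[c(mb, batch, y)])
        if (length(batch) && n < 5 * df_next) break
        batch <- c(batch, y)
      }
      mb <- c(mb, batch)
      mb <- backward(mb)
    }
    mb <- backward(mb)
  }
  sort(mb)
}

## Sepset search: smallest separating subset (sizes 0..cap) drawn from the
## smaller of the two candidate pools.  Returns list(found, sepset).
find_sepset <- function(x, y, pool_x, pool_y, cap, test) {
  pool <- if (length(pool_x) <= length(pool_y)) pool_x else pool_y
  for (S in subsets_up_to(sort(pool), cap)) {
    if (test(x, y, S)$independent) return(list(found = TRUE, sepset = S))
  }
  list(found = FALSE, sepset = NULL)
}

#' Constraint-based structure learning
#'
#' The classical pipeline: per-node Markov blankets (variant from
#' `config$algorithm`), AND-rule symmetry correction, neighbour resolution
#' within blankets (a pair stays adjacent iff no small conditioning subset
#' separates it), collider orientation of unshielded triples whose middle
#' node is outside the separating set, constraint application
#' (blacklisted directions removed, whitelisted arcs forced) and Meek-rule
#' propagation.  The result may retain undirected edges.
#'
#' @param data a [discrete_dataset()].
#' @param config an [algorithm_config()] with a constraint-based
#'   `algorithm` (`"gs"`, `"iamb"`, `"fast-iamb"`, `"inter-iamb"`).
#' @param constraints a [constraint_set()] or `NULL`.
#' @return An `smm_pdag`.
#' @export
constraint_learn <- function(data, config = algorithm_config("iamb"),
                             constraints = NULL) {
  vars <- dataset_vars(data)
  p <- length(vars)
  cm <- constraint_matrices(constraints, vars)
  test <- make_tester(data, config$alpha, config$guard)
  variant <- if (config$algorithm %in% c("gs", "iamb", "fast-iamb", "inter-iamb"))
    config$algorithm else "iamb"
  cap <- config$max_sx

  mb <- lapply(vars, function(v)
    learn_markov_blanket(v, data, variant, config$alpha, config$guard, test))
  names(mb) <- vars
  # symmetry (AND rule)
  for (v in vars) mb[[v]] <- mb[[v]][vapply(mb[[v]], function(u)
    v %in% mb[[u]], TRUE)]

  adj <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  sepsets <- new.env(parent = emptyenv())
  sep_key <- function(a, b) if (a < b) paste(a, b) else paste(b, a)
  for (x in vars) for (y in mb[[x]]) {
    if (x >= y) next
    if (cm$bl[x, y] && cm$bl[y, x]) next         # pair forbidden outright
    s <- find_sepset(x, y, setdiff(mb[[x]], y), setdiff(mb[[y]], x), cap, test)
    if (s$found) assign(sep_key(x, y), s$sepset, envir = sepsets)
    else adj[x, y] <- adj[y, x] <- TRUE
  }
  wl <- which(cm$wl, arr.ind = TRUE)
  if (nrow(wl)) for (k in seq_len(nrow(wl)))
    adj[wl[k, 1L], wl[k, 2L]] <- adj[wl[k, 2L], wl[k, 1L]] <- TRUE

  amat <- matrix(0L, p, p, dimnames = list(vars, vars))
  amat[adj] <- 1L                                # undirected skeleton
  # collider orientation on unshielded triples
  for (y in vars) {
    nb <- vars[adj[, y]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(sort(nb), 2L)
    for (k in seq_len(ncol(cmb))) {
      x <- cmb[1L, k]; z <- cmb[2L, k]
      if (adj[x, z]) next
      key <- sep_key(x, z)
      if (exists(key, envir = sepsets, inherits = FALSE)) {
        S <- get(key, envir = sepsets)
      } else {
        s <- find_sepset(x, z, setdiff(vars[adj[, x]], z),
                         setdiff(vars[adj[, z]], x), cap, test)
        S <- if (s$found) s$sepset else NULL
        if (s$found) assign(key, S, envir = sepsets)
      }
      if (!is.null(S) && !(y %in% S)) {
        # orient into the collider, but never in a blacklisted direction
        if (!cm$bl[x, y]) amat[y, x] <- 0L        # x -> y
        if (!cm$bl[z, y]) amat[y, z] <- 0L        # z -> y
      }
    }
  }
  # constraints: forced directions, forbidden directions
  if (nrow(wl)) for (k in seq_len(nrow(wl))) {
    amat[wl[k, 1L], wl[k, 2L]] <- 1L
    amat[wl[k, 2L], wl[k, 1L]] <- 0L
  }
  bl <- which(cm$bl, arr.ind = TRUE)
  if (nrow(bl)) for (k in seq_len(nrow(bl))) {
    i <- bl[k, 1L]; j <- bl[k, 2L]
    if (amat[i, j] == 1L && amat[j, i] == 1L) {
      amat[i, j] <- 0L                            # orient the allowed way
    } else if (amat[i, j] == 1L) {
      amat[i, j] <- 0L                            # forbidden direction: the
      amat[j, i] <- 1L                            # layering forces the other
    }
  }
  amat <- meek_closure(amat)
  out <- pdag(vars)
  out$amat <- amat
  out
}

#' MMPC skeleton discovery
#'
#' Per-target candidate parent-children sets built with the max-min
#' heuristic: repeatedly add the candidate whose weakest (minimum over
#' conditioning subsets of the current set) association with the target is
#' strongest, stop when no candidate survives its weakest test, then
#' backward-remove false positives; an edge is kept only when found from
#' both endpoints (AND rule), making the result order-invariant.
#'
#' @inheritParams constraint_learn
#' @return Data frame of unordered skeleton pairs (`from < to`), sorted.
#' @export
mmpc_skeleton <- function(data, config = algorithm_config("mmhc"),
                          constraints = NULL) {
  vars <- dataset_vars(data)
  cm <- constraint_matrices(constraints, vars)
  test <- make_tester(data, config$alpha, config$guard)
  cap <- config$max_sx

  cpc_of <- function(target) {
    cand <- setdiff(vars, target)
    cand <- cand[!(cm$bl[cand, target] & cm$bl[target, cand])]
    cpc <- character(0)
    maxp <- stats::setNames(rep(-Inf, length(cand)), cand)  # worst p so far
    for (y in cand) maxp[y] <- test(target, y, character(0))$p_value
    cand <- cand[maxp[cand] <= config$alpha]                # drop independents
    while (length(cand)) {
      pick <- cand[order(maxp[cand], cand)][1L]
      cpc <- c(cpc, pick)
      cand <- setdiff(cand, pick)
      if (!length(cand)) break
      # update min-association with subsets that contain the new member
      base <- setdiff(cpc, pick)
      subs <- lapply(subsets_up_to(sort(base), cap - 1L),
                     function(S) c(S, pick))
      drop <- character(0)
      for (y in cand) {
        for (S in subs) {
          if (length(S) > cap) next
          pv <- test(target, y, S)$p_value
          if (pv > maxp[y]) maxp[y] <- pv
          if (maxp[y] > config$alpha) { drop <- c(drop, y); break }
        }
      }
      cand <- setdiff(cand, drop)
    }
    # backward: remove members separated by some subset of the rest
    for (y in cpc) {
      for (S in subsets_up_to(sort(setdiff(cpc, y)), cap)) {
        if (test(target, y, S)$independent) { cpc <- setdiff(cpc, y); break }
      }
    }
    cpc
  }

  cpc <- lapply(vars, cpc_of)
  names(cpc) <- vars
  pairs <- list()
  for (x in vars) for (y in cpc[[x]])
    if (x < y && x %in% cpc[[y]]) pairs[[length(pairs) + 1L]] <- c(x, y)
  wl <- which(cm$wl, arr.ind = TRUE)
  if (nrow(wl)) for (k in seq_len(nrow(wl))) {
    a <- vars[wl[k, 1L]]; b <- vars[wl[k, 2L]]
    pairs[[length(pairs) + 1L]] <- c(min(a, b), max(a, b))
  }
  if (!length(pairs))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, pairs))
  out <- data.frame(from = m[, 1L], to = m[, 2L], stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Hybrid restrict-maximize learning
#'
#' Runs a skeleton-producing restrict phase, then a score search whose arc
#' additions are limited to the discovered skeleton.  `restrict = "mmpc"`
#' with `maximize = "hc"` is MMHC; `restrict = "iamb"` derives the
#' skeleton from IAMB blankets via [constraint_learn()].  Every returned
#' arc lies (as an unordered pair) inside the restrict-phase skeleton or
#' the whitelist.
#'
#' @inheritParams constraint_learn
#' @param restrict `"mmpc"` or `"iamb"` (overrides `config$restrict`).
#' @param maximize `"hc"` or `"tabu"` (overrides `config$maximize`).
#' @return An `smm_dag`.
#' @export
restrict_maximize <- function(data, config = algorithm_config("rsmax2"),
                              constraints = NULL, restrict = NULL,
                              maximize = NULL) {
  restrict <- restrict %||% config$restrict
  maximize <- maximize %||% config$maximize
  sk <- if (restrict == "mmpc") {
    mmpc_skeleton(data, config, constraints)
  } else {
    skeleton_pairs(constraint_learn(data, config, constraints))
  }
  if (maximize == "hc") hill_climb(data, config, constraints, restrict_pairs = sk)
  else tabu_search(data, config, constraints, restrict_pairs = sk)
}

#' Run one roster configuration
#'
#' Dispatches an [algorithm_config()] to the matching learner.
#' Score-based and hybrid configurations return an `smm_dag`;
#' constraint-based configurations return an `smm_pdag`.
#'
#' @inheritParams constraint_learn
#' @return An `smm_dag` or `smm_pdag`.
#' @export
learn_structure <- function(data, config, constraints = NULL) {
  switch(config$algorithm,
    hc = hill_climb(data, config, constraints),
    tabu = tabu_search(data, config, constraints),
    gs = , iamb = , `fast-iamb` = , `inter-iamb` =
      constraint_learn(data, config, constraints),
    mmhc = restrict_maximize(data, config, constraints,
                             restrict = "mmpc", maximize = "hc"),
    rsmax2 = restrict_maximize(data, config, constraints))
}
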