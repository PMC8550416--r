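#' Bootstrap replicate structure learning
#'
#' Learns `B` structures, each on an independent bootstrap resample (with
#' replacement, size N) of the data, with one roster configuration.
#' Score-based and hybrid outputs are converted to their equivalence-class
#' PDAG via [to_cpdag()]; constraint-based outputs are PDAGs already.
#' Fully reproducible given `seed`.
#'
#' @param data a [discrete_dataset()].
#' @param config an [algorithm_config()].
#' @param B number of replicates (>= 1).
#' @param seed integer seed.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param resample with `FALSE`, each replicate learns on the original
#'   data (useful for B = 1 consensus runs).
#' @return List of `B` `smm_pdag`s.
#' @export
run_replicates <- function(data, config, B = 100L, seed = 1L,
                           constraints = NULL, resample = TRUE) {
  if (!is_scalar_number(B) || B < 1) stop_contract("B must be >= 1")
  n <- nrow(data$x)
  idx <- with_seed(seed, lapply(seq_len(B), function(b)
    if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)))
  lapply(seq_len(B), function(b) {
    g <- learn_structure(dataset_subset(data, idx[[b]]), config, constraints)
    if (is_dag_object(g)) to_cpdag(g) else g
  })
}

#' Per-algorithm consensus arc scoring
#'
#' Reduces a list of replicate structures to one score per unordered node
#' pair: 1 for the majority direction when a single direction's frequency
#' exceeds `threshold`; 0.5 when the pair is connected (in any form) more
#' than `threshold` of the time but no single direction is; 0 (omitted)
#' otherwise.  Comparisons are strict (`> threshold`), and the result is
#' invariant to the order of the replicate list.
#'
#' @param structures list of `smm_pdag`/`smm_dag` replicates.
#' @param threshold occurrence threshold in (0, 1), default 0.7.
#' @return Data frame `from`, `to`, `score` (scores in {0.5, 1}; zero-score
#'   pairs are omitted).
#' @export
score_algorithm_arcs <- function(structures, threshold = 0.7) {
  if (!length(structures)) stop_contract("structures must be non-empty")
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stop_contract("threshold must be in (0, 1)")
  B <- length(structures)
  nodes <- structures[[1L]]$nodes
  fdir <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  fund <- fdir
  for (s in structures) {
    a <- s$amat[nodes, nodes]
    und <- a == 1L & t(a) == 1L
    fdir <- fdir + (a == 1L & !und)
    fund <- fund + (und & upper.tri(und))
  }
  fdir <- fdir / B; fund <- fund / B
  out <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    a <- nodes[i]; b <- nodes[j]
    f_ab <- fdir[a, b]; f_ba <- fdir[b, a]; f_u <- fund[a, b]
    f_edge <- f_ab + f_ba + f_u
    if (max(f_ab, f_ba) > threshold) {
      dirn <- if (f_ba > f_ab) c(b, a) else c(a, b)
      out[[length(out) + 1L]] <- data.frame(from = dirn[1L], to = dirn[2L],
                                            score = 1, stringsAsFactors = FALSE)
    } else if (f_edge > threshold) {
      dirn <- if (f_ba > f_ab) c(b, a) else c(a, b)
      out[[length(out) + 1L]] <- data.frame(from = dirn[1L], to = dirn[2L],
                                            score = 0.5, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Consensus table across the algorithm roster
#'
#' Assembles per-algorithm arc scores into an arcs-by-algorithms matrix
#' with entries in {0, 0.5, 1}: the row sums are the arc occurrences and
#' the column sums the per-algorithm total arcs.  Rows are sorted by
#' occurrence (descending), then lexicographically.  A row's printed
#' direction is the direction favoured by the majority of the directed
#' entries (ties break lexicographically).
#'
#' @param scores named list of data frames from [score_algorithm_arcs()],
#'   one per algorithm.
#' @param algorithms optional character vector of algorithm ids (defaults
#'   to `names(scores)`); column order is the roster order and is the
#'   selection tie-break.
#' @return A `consensus_table`: list with `arcs` (data frame `from`,
#'   `to`), `entries` (matrix), `occurrence`, `totals`, `algorithms`.
#' @export
build_consensus <- function(scores, algorithms = NULL) {
  algorithms <- algorithms %||% names(scores)
  if (is.null(algorithms) || !length(algorithms))
    stop_contract("at least one algorithm is required")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  keys <- character(0)
  for (s in scores) if (nrow(s)) keys <- union(keys, pair_key(s$from, s$to))
  entries <- matrix(0, length(keys), length(algorithms),
                    dimnames = list(keys, algorithms))
  dirvote <- new.env(parent = emptyenv())
  for (aid in algorithms) {
    s <- scores[[aid]]
    if (is.null(s) || !nrow(s)) next
    for (r in seq_len(nrow(s))) {
      key <- pair_key(s$from[r], s$to[r])
      entries[key, aid] <- s$score[r]
      if (s$score[r] == 1) {
        k2 <- arc_key(s$from[r], s$to[r])
        votes <- dirvote[[key]]
        if (is.null(votes)) votes <- numeric(0)
        votes[k2] <- (if (k2 %in% names(votes)) votes[[k2]] else 0) + 1
        dirvote[[key]] <- votes
      }
    }
  }
  arcs <- do.call(rbind, lapply(keys, function(key) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
    votes <- dirvote[[key]]
    if (!is.null(votes) && length(votes)) {
      best <- sort(names(votes)[votes == max(votes)])[1L]
      ft <- strsplit(best, "->", fixed = TRUE)[[1L]]
      data.frame(from = ft[1L], to = ft[2L], stringsAsFactors = FALSE)
    } else data.frame(from = ab[1L], to = ab[2L], stringsAsFactors = FALSE)
  }))
  occurrence <- rowSums(entries)
  ord <- order(-occurrence, arcs$from, arcs$to)
  structure(list(arcs = arcs[ord, , drop = FALSE],
                 entries = entries[ord, , drop = FALSE],
                 occurrence = occurrence[ord],
                 totals = colSums(entries),
                 algorithms = algorithms),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("<consensus_table> %d arcs x %d algorithms\n",
              nrow(x$entries), length(x$algorithms)))
  df <- as.data.frame.consensus_table(x)
  print(utils::head(df, 20L))
  if (nrow(df) > 20L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.consensus_table <- function(x, ...) {
  df <- cbind(data.frame(arc = paste(x$arcs$from, "->", x$arcs$to),
                         stringsAsFactors = FALSE),
              as.data.frame(x$entries, check.names = FALSE),
              occurrence = unname(x$occurrence))
  rownames(df) <- NULL
  df
}

#' Export a consensus table as CSV
#'
#' Arcs-by-algorithms layout with an `occurrence` column and a final
#' `total_arcs` row of per-algorithm column sums.
#'
#' @param x a `consensus_table`.
#' @param path file path.
#' @export
write_consensus_csv <- function(x, path) {
  df <- as.data.frame(x)
  total <- c(arc = "total_arcs", as.list(unname(x$totals)), occurrence = NA)
  names(total) <- names(df)
  df <- rbind(df, total)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Select the strongest roster algorithms
#'
#' Ranks roster columns by total arcs (descending), breaking ties by
#' roster order, and returns the top `k` algorithm ids.
#'
#' @param table a `consensus_table`.
#' @param k number of algorithms to keep (`k <=` number of columns).
#' @return Character vector of `k` algorithm ids, in rank order.
#' @export
select_algorithms <- function(table, k) {
  if (k > length(table$algorithms))
    stop_contract("k exceeds the number of roster algorithms")
  ord <- order(-table$totals, seq_along(table$totals))
  table$algorithms[ord][seq_len(k)]
}

#' Misclassification rate of a learned structure
#'
#' Fits CPTs on the training set and predicts the target level of each
#' test record as the exact posterior mode given the record's values on
#' the target's Markov blanket, computed from the target's own CPT and
#' its children's CPT factors (no sampling; ties break to the first
#' level).  With `replicates > 1`, CPTs are refitted on bootstrap
#' resamples of the training data and the replicate rates averaged.
#'
#' @param g an `smm_dag` (learned independently of `test`).
#' @param train,test [discrete_dataset()]s containing `target`.
#' @param target target variable name.
#' @param smoothing CPT smoothing pseudo-count.
#' @param replicates Monte-Carlo refits (default 1 = single fit).
#' @param seed seed for the replicate resamples.
#' @return The misclassification fraction (mean over replicates); the
#'   per-replicate rates are attached as `attr(, "replicates")`.
#' @export
misclassification_rate <- function(g, train, test, target, smoothing = 0,
                                   replicates = 1L, seed = 1L) {
  if (!target %in% dataset_vars(train) || !target %in% dataset_vars(test))
    stop_identifier("target %s missing from train or test", target)
  one_rate <- function(tr) {
    cpts <- fit_cpts(g, tr, smoothing)
    pred <- predict_target(g, cpts, test, target)
    mean(pred != test$x[, target])
  }
  rates <- if (replicates <= 1L) one_rate(train) else {
    n <- nrow(train$x)
    idx <- with_seed(seed, lapply(seq_len(replicates), function(b)
      sample.int(n, n, replace = TRUE)))
    vapply(idx, function(i) one_rate(dataset_subset(train, i)), 0)
  }
  structure(mean(rates), replicates = rates)
}

## Exact posterior mode of `target` given each record's Markov-blanket
## values: log P(t | pa) + sum over children log P(child | pa, t).
predict_target <- function(g, cpts, data, target) {
  n <- nrow(data$x)
  r <- length(cpts$levels[[target]])
  ch <- children(g, target)
  logp <- matrix(0, n, r)
  x <- data$x
  for (t in seq_len(r)) {
    xt <- x
    xt[, target] <- t
    tb <- cpts$tables[[target]]
    radix <- vapply(cpts$levels[tb$parents], length, 1L)
    cfg <- config_index(xt[, tb$parents, drop = FALSE], radix)
    logp[, t] <- log(tb$prob[cbind(rep.int(t, n), cfg)])
    for (c in ch) {
      tbc <- cpts$tables[[c]]
      radc <- vapply(cpts$levels[tbc$parents], length, 1L)
      cfgc <- config_index(xt[, tbc$parents, drop = FALSE], radc)
      logp[, t] <- logp[, t] + log(tbc$prob[cbind(x[, c], cfgc)])
    }
  }
  max.col(logp, ties.method = "first")
}

#' Bootstrap arc strength (model averaging)
#'
#' Learns a structure on each of `R` resamples of size `m` (with
#' replacement by default; set `replace = FALSE` for subsampling) and
#' reports, per directed arc, the fraction of replicates containing it;
#' an undirected PDAG edge contributes 0.5 to each direction.
#'
#' @param data a [discrete_dataset()].
#' @param config an [algorithm_config()].
#' @param R number of replicates (>= 1).
#' @param m resample size (>= 1).
#' @param seed integer seed.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param replace resample with replacement (bootstrap) or without
#'   (subsampling; requires `m <= N`).
#' @return An `arc_strength_table`: data frame `from`, `to`, `strength`
#'   with attributes `R` and `m`; only arcs with positive strength are
#'   listed (absent arcs have strength 0).
#' @export
bootstrap_arc_strength <- function(data, config, R = 1000L, m = 1000L,
                                   seed = 1L, constraints = NULL,
                                   replace = TRUE) {
  if (!is_scalar_number(R) || R < 1) stop_contract("R must be >= 1")
  if (!is_scalar_number(m) || m < 1) stop_contract("m must be >= 1")
  n <- nrow(data$x)
  if (!replace && m > n) stop_contract("subsampling needs m <= N")
  idx <- with_seed(seed, lapply(seq_len(R), function(b)
    sample.int(n, m, replace = replace)))
  nodes <- dataset_vars(data)
  acc <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (b in seq_len(R)) {
    g <- learn_structure(dataset_subset(data, idx[[b]]), config, constraints)
    a <- g$amat[nodes, nodes]
    und <- a == 1L & t(a) == 1L
    acc <- acc + (a == 1L & !und) + 0.5 * und
  }
  acc <- acc / R
  ix <- which(acc > 0, arr.ind = TRUE)
  out <- data.frame(from = nodes[ix[, 1L]], to = nodes[ix[, 2L]],
                    strength = acc[ix], stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, R = as.integer(R), m = as.integer(m),
            class = c("arc_strength_table", "data.frame"))
}

## Strength lookup with a configurable default for absent arcs.
strength_of <- function(strengths, from, to, default = 0) {
  hit <- strengths$from == from & strengths$to == to
  if (any(hit)) strengths$strength[which(hit)[1L]] else default
}
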