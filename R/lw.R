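#' Likelihood-weighting conditional probability queries
#'
#' Importance-sampling inference for `P(event | evidence)`: evidence nodes
#' are clamped to their observed levels, non-evidence nodes are drawn
#' ancestrally, and each sample is weighted by the product of the evidence
#' CPT entries.  The network is never mutated.  With `replicates > 1` the
#' query is repeated on independent sample batches and a 2.5/97.5
#' percentile interval over replicate estimates is attached.
#'
#' @param g an `smm_dag`.
#' @param cpts a [cpt_set()].
#' @param event,evidence named vectors of level labels; disjoint variable
#'   sets.
#' @param n_samples weighted samples per replicate (default `1e5`).
#' @param seed integer seed (all randomness is derived from it).
#' @param replicates number of independent replicate estimates.
#' @return An object of class `query_result`: fields `estimate`,
#'   `replicates` (vector of per-replicate estimates), `interval`,
#'   `n_samples`, `event`, `evidence`.
#' @export
lw_query <- function(g, cpts, event, evidence = NULL, n_samples = 1e5,
                     seed = 1L, replicates = 1L) {
  overlap <- intersect(names(event), names(evidence))
  for (v in overlap) {
    # clamped evidence determines the event coordinate outright
    if (!identical(as.character(event[[v]]), as.character(evidence[[v]])))
      return(structure(list(event = event, evidence = evidence, estimate = 0,
                            replicates = rep(0, replicates),
                            interval = c(0, 0),
                            n_samples = as.integer(n_samples)),
                       class = "query_result"))
  }
  event <- event[setdiff(names(event), overlap)]
  if (!length(event))
    return(structure(list(event = event, evidence = evidence, estimate = 1,
                          replicates = rep(1, replicates),
                          interval = c(1, 1),
                          n_samples = as.integer(n_samples)),
                     class = "query_result"))
  if (!is_scalar_number(n_samples) || n_samples < 1)
    stop_contract("n_samples must be >= 1")
  check_node(g, union(names(event), names(evidence)))
  e_idx <- resolve_levels(cpts, event)
  ev_idx <- if (length(evidence)) resolve_levels(cpts, evidence) else integer(0)
  est <- vapply(seq_len(replicates), function(b) {
    lw_one(g, cpts, e_idx, ev_idx, as.integer(n_samples),
           derive_seed(seed, b))
  }, 0)
  interval <- if (replicates >= 2L)
    unname(stats::quantile(est, c(0.025, 0.975), type = 7)) else range(est)
  structure(list(event = event, evidence = evidence,
                 estimate = mean(est), replicates = est,
                 interval = interval, n_samples = as.integer(n_samples)),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("P(event | evidence) = %.6f  [%d x %d weighted samples]\n",
              x$estimate, length(x$replicates), x$n_samples))
  if (length(x$replicates) >= 2L)
    cat(sprintf("  replicate 95%% interval: [%.6f, %.6f]\n",
                x$interval[1L], x$interval[2L]))
  invisible(x)
}

lw_one <- function(g, cpts, e_idx, ev_idx, n, seed) {
  ord <- topological_order(g)
  x <- matrix(0L, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  logw <- rep(0, n)
  with_seed(seed, {
    for (v in ord) {
      tb <- cpts$tables[[v]]
      r <- length(cpts$levels[[v]])
      radix <- vapply(cpts$levels[tb$parents], length, 1L)
      cfg <- config_index(x[, tb$parents, drop = FALSE], radix)
      if (v %in% names(ev_idx)) {
        x[, v] <- ev_idx[[v]]
        logw <- logw + log(tb$prob[cbind(rep.int(ev_idx[[v]], n), cfg)])
      } else {
        cum <- apply(tb$prob, 2L, cumsum)
        u <- stats::runif(n)
        pc <- t(cum)[cfg, , drop = FALSE]
        lev <- 1L + as.integer(rowSums(u > pc[, -r, drop = FALSE]))
        x[, v] <- pmin(lev, r)
      }
    }
  })
  w <- exp(logw)
  tw <- sum(w)
  if (!is.finite(tw) || tw <= 0)
    stop_degenerate("all likelihood weights are zero; conditional undefined")
  ind <- rep(TRUE, n)
  for (v in names(e_idx)) ind <- ind & x[, v] == e_idx[[v]]
  sum(w[ind]) / tw
}

#' Odds ratio between two evidence levels of a grouping variable
#'
#' Computes `p1 = P(event | group = level)` and
#' `p0 = P(event | group = ref_level)` by likelihood weighting and reports
#' `OR = (p1/(1-p1)) / (p0/(1-p0))` with a percentile interval over
#' independent replicate OR estimates, mirroring disparity tables of the
#' form Event / Evidence / OR / CI.
#'
#' @inheritParams lw_query
#' @param group_var grouping variable name.
#' @param level,ref_level compared level and reference level (distinct).
#' @return A list with `odds_ratio`, `interval`, `p1`, `p0`, and the two
#'   underlying `query_result`s.
#' @export
odds_ratio <- function(g, cpts, event, group_var, level, ref_level,
                       n_samples = 1e5, replicates = 30L, seed = 1L) {
  if (identical(level, ref_level)) stop_contract("level must differ from ref_level")
  q1 <- lw_query(g, cpts, event, stats::setNames(list(level), group_var),
                 n_samples, derive_seed(seed, 1001), replicates)
  q0 <- lw_query(g, cpts, event, stats::setNames(list(ref_level), group_var),
                 n_samples, derive_seed(seed, 2002), replicates)
  p1 <- q1$estimate; p0 <- q0$estimate
  if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1)
    stop_degenerate("degenerate odds (conditional probability at 0 or 1)")
  ors <- (q1$replicates / (1 - q1$replicates)) /
         (q0$replicates / (1 - q0$replicates))
  interval <- if (replicates >= 2L)
    unname(stats::quantile(ors, c(0.025, 0.975), type = 7)) else range(ors)
  list(odds_ratio = (p1 / (1 - p1)) / (p0 / (1 - p0)),
       interval = interval, p1 = p1, p0 = p0,
       query = q1, reference_query = q0)
}
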