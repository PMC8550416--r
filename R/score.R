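#' Decomposable network scores
#'
#' `family_score()` scores one node given a candidate parent set on
#' complete discrete data; the total network score is the sum of family
#' scores (decomposability), computed by `network_score()`.  Larger is
#' better.  The log-likelihood term is `sum_jk N_ijk * ln(N_ijk / N_ij)`
#' with `0 ln 0 = 0`; BIC subtracts `(ln N / 2) * (r - 1) * q` and AIC
#' subtracts `(r - 1) * q`, where `r` is the node's level count and `q`
#' the number of parent configurations.
#'
#' @param node node name.
#' @param parents character vector of parent names (excluding `node`).
#' @param data a [discrete_dataset()].
#' @param score `"bic"`, `"aic"` or `"loglik"`.
#' @return A scalar score.
#' @export
family_score <- function(node, parents, data, score = "bic") {
  if (node %in% parents) stop_contract("parents must exclude the node")
  nl <- dataset_nlev(data)
  r <- nl[[node]]
  radix <- nl[parents]
  q <- prod(radix)
  n <- nrow(data$x)
  cfg <- config_index(data$x[, parents, drop = FALSE], radix)
  cnt <- tabulate(data$x[, node] + r * (cfg - 1L), nbins = r * as.integer(q))
  cnt <- matrix(cnt, nrow = r)
  tot <- colSums(cnt)
  nz <- cnt > 0
  ll <- sum(cnt[nz] * log(cnt[nz] / rep(tot, each = r)[nz]))
  pen <- switch(match.arg(score, c("bic", "aic", "loglik")),
                bic = log(n) / 2 * (r - 1) * q,
                aic = (r - 1) * q,
                loglik = 0)
  ll - pen
}

#' @rdname family_score
#' @param g an `smm_dag`.
#' @export
network_score <- function(g, data, score = "bic") {
  sum(vapply(g$nodes, function(v)
    family_score(v, intersect(g$nodes, parents(g, v)), data, score), 0))
}

#' G-squared conditional independence test
#'
#' Log-likelihood-ratio test of `x` independent of `y` given the variable
#' set `z`:
#' `G2 = 2 * sum N_xyz * ln(N_xyz * N_z / (N_xz * N_yz))`, with degrees of
#' freedom `(r_x - 1)(r_y - 1) * prod(r_z)` and a chi-square upper-tail
#' p-value.  Empty strata contribute zero.  When `guard` is on (default)
#' and `N < 5 * df`, the test is considered unreliable and reports
#' independence, preventing degenerate high-dimensional tests from
#' flooding learned skeletons.
#'
#' @param x,y distinct variable names.
#' @param z character vector of conditioning variables (possibly empty).
#' @param data a [discrete_dataset()].
#' @param alpha significance level in (0, 1).
#' @param guard logical; apply the `N >= 5 * df` reliability heuristic.
#' @return List with `statistic`, `df`, `p_value`, `independent`,
#'   `guarded`.
#' @export
ci_test_g2 <- function(x, y, z = character(0), data, alpha = 0.05, guard = TRUE) {
  if (x == y || x %in% z || y %in% z)
    stop_contract("x, y and z must be distinct")
  nl <- dataset_nlev(data)
  rx <- nl[[x]]; ry <- nl[[y]]
  radz <- nl[z]
  qz <- as.integer(prod(radz))
  n <- nrow(data$x)
  zi <- config_index(data$x[, z, drop = FALSE], radz)
  xi <- data$x[, x]; yi <- data$x[, y]
  cell <- xi + rx * (yi - 1L) + rx * ry * (zi - 1L)
  nxyz <- tabulate(cell, nbins = rx * ry * qz)
  dim(nxyz) <- c(rx, ry, qz)
  nxz <- apply(nxyz, c(1L, 3L), sum)
  nyz <- apply(nxyz, c(2L, 3L), sum)
  nz <- apply(nxyz, 3L, sum)
  expv <- array(0, dim(nxyz))
  for (k in seq_len(qz)) if (nz[k] > 0)
    expv[, , k] <- outer(nxz[, k], nyz[, k]) / nz[k]
  pos <- nxyz > 0 & expv > 0
  g2 <- 2 * sum(nxyz[pos] * log(nxyz[pos] / expv[pos]))
  df <- (rx - 1) * (ry - 1) * qz
  p <- stats::pchisq(g2, df, lower.tail = FALSE)
  guarded <- guard && n < 5 * df
  list(statistic = g2, df = df, p_value = p,
       independent = if (guarded) TRUE else p > alpha,
       guarded = guarded)
}
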