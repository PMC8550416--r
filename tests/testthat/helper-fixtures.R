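# Shared builders for the suite: random graphs and parameterizations are
# always drawn under explicit seeds.

rand_dag <- function(p, arc_prob = 0.4, seed = 1L, prefix = "V") {
  nodes <- paste0(prefix, seq_len(p))
  set.seed(seed)
  am <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
    if (stats::runif(1) < arc_prob) am[i, j] <- 1L   # upper-triangular: acyclic
  g <- dag(nodes)
  g$amat <- am
  g
}

rand_cpts <- function(g, seed = 1L, r = 2L, conc = 1) {
  set.seed(seed)
  lv <- stats::setNames(rep(list(as.character(seq_len(r) - 1L)),
                            length(g$nodes)), g$nodes)
  tabs <- list()
  for (v in g$nodes) {
    pa <- parents(g, v)
    q <- r ^ length(pa)
    pr <- vapply(seq_len(q), function(j) {
      w <- stats::rgamma(r, conc)
      w / sum(w)
    }, numeric(r))
    tabs[[v]] <- list(parents = pa, prob = matrix(pr, nrow = r))
  }
  cpt_set(g, lv, tabs)
}

# Binary dataset of p mutually independent uniform variables.
indep_data <- function(n, p, seed = 1L, prefix = "V") {
  set.seed(seed)
  x <- matrix(sample(1:2, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, paste0(prefix, seq_len(p))))
  lv <- stats::setNames(rep(list(c("0", "1")), p), colnames(x))
  discrete_dataset(x, levels = lv)
}

small_cohort <- function(n = 20000L, seed = 3L) {
  generate_cohort(cohort_config(n = n, seed = seed))
}
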