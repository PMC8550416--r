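test_that("family scores match their closed forms and decompose", {
  d <- indep_data(100, 1, seed = 1, prefix = "X")
  # force an exactly uniform binary column
  d$x[, 1L] <- rep(1:2, 50L)
  expect_equal(family_score("X1", character(0), d, "loglik"), 100 * log(0.5))
  expect_equal(family_score("X1", character(0), d, "bic"),
               100 * log(0.5) - log(100) / 2)
  expect_equal(family_score("X1", character(0), d, "aic"), 100 * log(0.5) - 1)
  # total network score is the sum of family scores
  co <- small_cohort(n = 2000)
  gt <- default_ground_truth(cohort_config())
  tot <- network_score(gt$dag, co, "bic")
  fam <- sum(vapply(gt$dag$nodes, function(v)
    family_score(v, parents(gt$dag, v), co, "bic"), 0))
  expect_equal(tot, fam, tolerance = 1e-9)
})

test_that("one-arc score deltas equal full network-score recomputation", {
  co <- small_cohort(n = 3000)
  g0 <- dag(dataset_vars(co))
  for (arc in list(c("race", "anemia"), c("hdp", "smm"), c("age", "parity"))) {
    delta_fam <- family_score(arc[2L], arc[1L], co, "bic") -
      family_score(arc[2L], character(0), co, "bic")
    delta_net <- network_score(add_arc(g0, arc[1L], arc[2L]), co, "bic") -
      network_score(g0, co, "bic")
    expect_equal(delta_fam, delta_net, tolerance = 1e-9)
  }
})

test_that("the G2 test matches its closed forms", {
  # perfectly balanced 2x2 -> statistic 0, independent at any alpha
  d0 <- discrete_dataset(cbind(X = rep(1:2, 10L), Y = rep(c(1L, 1L, 2L, 2L), 5L)),
                         levels = list(X = c("0", "1"), Y = c("0", "1")))
  t0 <- ci_test_g2("X", "Y", character(0), d0, guard = FALSE)
  expect_equal(t0$statistic, 0)
  expect_true(t0$independent)
  # diagonal 2x2 -> G2 = 40 ln 2, df 1, p < 1e-6
  d1 <- discrete_dataset(cbind(X = rep(1:2, each = 10L), Y = rep(1:2, each = 10L)),
                         levels = list(X = c("0", "1"), Y = c("0", "1")))
  t1 <- ci_test_g2("X", "Y", character(0), d1, guard = FALSE)
  expect_equal(t1$statistic, 40 * log(2), tolerance = 1e-9)
  expect_equal(t1$df, 1)
  expect_lt(t1$p_value, 1e-6)
  expect_false(t1$independent)
  # reliability guard declares high-df tests independent
  dg <- indep_data(30, 5, seed = 2)    # df = 8, N = 30 < 5 * df
  tg <- ci_test_g2("V1", "V2", c("V3", "V4", "V5"), dg, guard = TRUE)
  expect_true(tg$guarded && tg$independent)
})

test_that("G2 type-I error sits near alpha on independent data", {
  set.seed(77)
  rejections <- 0L
  for (r in 1:2000) {
    x <- sample(1:2, 150, replace = TRUE)
    y <- sample(1:2, 150, replace = TRUE)
    d <- discrete_dataset(cbind(X = x, Y = y),
                          levels = list(X = c("0", "1"), Y = c("0", "1")))
    if (!ci_test_g2("X", "Y", character(0), d, alpha = 0.05,
                    guard = FALSE)$independent)
      rejections <- rejections + 1L
  }
  # binomial(2000, ~0.05): 4 SE band around the nominal level
  expect_gt(rejections / 2000, 0.05 - 4 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(rejections / 2000, 0.05 + 4 * sqrt(0.05 * 0.95 / 2000))
})

test_that("hill climbing honours its contracts", {
  # independent variables: BIC penalty keeps the graph empty
  d <- indep_data(5000, 2, seed = 3)
  expect_equal(nrow(arcs(hill_climb(d))), 0L)
  # strong pairwise dependence: exactly one arc (either direction)
  set.seed(4)
  a <- sample(1:2, 5000, replace = TRUE)
  b <- ifelse(runif(5000) < 0.95, a, sample(1:2, 5000, replace = TRUE))
  d2 <- discrete_dataset(cbind(A = a, B = b),
                         levels = list(A = c("0", "1"), B = c("0", "1")))
  g2 <- hill_climb(d2)
  expect_equal(nrow(skeleton_pairs(g2)), 1L)
  # termination certificate: no single legal move improves the score
  co <- small_cohort(n = 4000)
  bal <- undersample(train_test_split(co, 0.7, 1)$train, "smm", 2)
  cs <- layer_blacklist(co$layers)
  gh <- hill_climb(bal, algorithm_config("hc", score = "bic"), cs)
  sc <- network_score(gh, bal, "bic")
  bl <- cs$blacklist
  for (i in gh$nodes) for (j in gh$nodes) {
    if (i == j) next
    if (gh$amat[i, j] == 0L && gh$amat[j, i] == 0L &&
        !any(bl$from == i & bl$to == j)) {
      cand <- try(add_arc(gh, i, j), silent = TRUE)
      if (!inherits(cand, "try-error"))
        expect_lte(network_score(cand, bal, "bic"), sc + 1e-9)
    }
    if (gh$amat[i, j] == 1L) {
      expect_lte(network_score(drop_arc(gh, i, j), bal, "bic"), sc + 1e-9)
      if (!any(bl$from == j & bl$to == i)) {
        cand <- try(reverse_arc(gh, i, j), silent = TRUE)
        if (!inherits(cand, "try-error"))
          expect_lte(network_score(cand, bal, "bic"), sc + 1e-9)
      }
    }
  }
})

test_that("tabu search never returns less than its greedy phase", {
  for (seed in 41:44) {
    g <- rand_dag(3, arc_prob = 0.6, seed = seed)
    cp <- rand_cpts(g, seed = seed + 7)
    d <- ancestral_sample(g, cp, 3000, seed = seed + 13)
    sc_hc <- network_score(hill_climb(d), d, "bic")
    t1 <- tabu_search(d)
    t2 <- tabu_search(d)
    expect_identical(t1$amat, t2$amat)          # deterministic
    expect_gte(network_score(t1, d, "bic"), sc_hc - 1e-9)
    # on 3 nodes tabu reaches the exhaustive-oracle optimum
    expect_gte(network_score(t1, d, "bic"), oracle_best3_score(d) - 1e-9)
  }
})

test_that("every learner honours blacklists and whitelists", {
  co <- small_cohort(n = 3000)
  sub <- dataset_select(
    co, c("race", "age", "anemia", "hdp", "preexist_htn", "smm"))
  cs <- constraint_set(
    blacklist = rbind(c("smm", "hdp"), c("smm", "anemia"), c("anemia", "race"),
                      c("hdp", "race"), c("smm", "race"), c("smm", "age"),
                      c("preexist_htn", "race"), c("preexist_htn", "age"),
                      c("smm", "preexist_htn")),
    whitelist = rbind(c("race", "anemia")))
  for (cfg in list(algorithm_config("hc"), algorithm_config("tabu"),
                   algorithm_config("gs"), algorithm_config("iamb"),
                   algorithm_config("mmhc"), algorithm_config("rsmax2"))) {
    g <- learn_structure(sub, cfg, cs)
    a <- arcs(g)
    keys <- paste(a$from, a$to)
    for (k in seq_len(nrow(cs$blacklist)))
      expect_false(paste(cs$blacklist$from[k], cs$blacklist$to[k]) %in% keys,
                   label = sprintf("%s blacklisted arc", cfg$id))
    expect_true("race anemia" %in% keys,
                label = sprintf("%s whitelisted arc", cfg$id))
  }
})

test_that("markov blanket discovery recovers chain neighbourhoods", {
  fx <- fixture_network("chain3")
  d <- ancestral_sample(fx$dag, fx$cpts, 10000, seed = 5)
  for (v in c("gs", "iamb", "fast-iamb", "inter-iamb")) {
    mb <- learn_markov_blanket("B", d, v)
    expect_identical(mb, c("A", "C"), label = v)
    expect_false("B" %in% mb)
  }
})

test_that("blankets of independent targets are usually empty", {
  # MB(T) = {} with probability about (1 - alpha)^(p-1)
  hits <- 0L
  for (r in 1:60) {
    d <- indep_data(400, 5, seed = 600 + r)
    if (length(learn_markov_blanket("V1", d, "iamb", alpha = 0.05)) == 0L)
      hits <- hits + 1L
  }
  expect_gt(hits / 60, (1 - 0.05)^4 - 4 * sqrt(0.2 * 0.8 / 60))
})

test_that("constraint learning orients v-structures and leaves chains free", {
  fc <- fixture_network("collider3")
  dc <- ancestral_sample(fc$dag, fc$cpts, 10000, seed = 6)
  pd <- constraint_learn(dc, algorithm_config("iamb"))
  expect_setequal(paste(skeleton_pairs(pd)$from, skeleton_pairs(pd)$to),
                  c("A C", "B C"))
  expect_setequal(paste(arcs(pd)$from, arcs(pd)$to), c("A C", "B C"))
  # a lone dependence is left undirected
  g2 <- dag(c("A", "B"), rbind(c("A", "B")))
  cp2 <- cpt_set(g2, list(A = c("0", "1"), B = c("0", "1")),
                 list(A = matrix(c(0.5, 0.5), ncol = 1L),
                      B = list(parents = "A",
                               prob = rbind(c(0.85, 0.2), c(0.15, 0.8)))))
  d2 <- ancestral_sample(g2, cp2, 8000, seed = 7)
  pd2 <- constraint_learn(d2, algorithm_config("gs"))
  expect_equal(nrow(undirected_edges(pd2)), 1L)
  expect_equal(nrow(arcs(pd2)), 0L)
})

test_that("mmpc recovers chain skeletons and is order-invariant", {
  fx <- fixture_network("chain3")
  d <- ancestral_sample(fx$dag, fx$cpts, 10000, seed = 8)
  sk <- mmpc_skeleton(d, algorithm_config("mmhc"))
  expect_setequal(paste(sk$from, sk$to), c("A B", "B C"))
  # permuting the variable order leaves the skeleton unchanged
  d_perm <- dataset_select(d, c("C", "A", "B"))
  sk2 <- mmpc_skeleton(d_perm, algorithm_config("mmhc"))
  expect_setequal(paste(sk$from, sk$to), paste(sk2$from, sk2$to))
  # independent variables give an (almost surely) empty skeleton
  di <- indep_data(2000, 4, seed = 9)
  expect_lte(nrow(mmpc_skeleton(di, algorithm_config("mmhc"))), 1L)
})

test_that("restrict-maximize honours its skeleton", {
  fx <- fixture_network("chain3")
  d <- ancestral_sample(fx$dag, fx$cpts, 10000, seed = 10)
  # vacuous restriction reproduces plain hill climbing
  full <- expand.grid(from = c("A", "B", "C"), to = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  full <- full[full$from < full$to, ]
  g_full <- hill_climb(d, algorithm_config("hc"), restrict_pairs = full)
  expect_identical(g_full$amat, hill_climb(d, algorithm_config("hc"))$amat)
  # empty skeleton forces the empty graph
  g_empty <- hill_climb(d, algorithm_config("hc"),
                        restrict_pairs = full[0, ])
  expect_equal(nrow(arcs(g_empty)), 0L)
  # recovered arcs are contained in the mmpc skeleton
  sk <- mmpc_skeleton(d, algorithm_config("mmhc"))
  g <- restrict_maximize(d, algorithm_config("rsmax2"), restrict = "mmpc",
                         maximize = "hc")
  a <- arcs(g)
  pair <- paste(pmin(a$from, a$to), pmax(a$from, a$to))
  expect_true(all(pair %in% paste(sk$from, sk$to)))
})
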