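test_that("dag construction enforces its invariants", {
  expect_s3_class(dag(c("A", "B"), rbind(c("A", "B"))), "smm_dag")
  expect_error(dag(c("A", "A")), class = "smmbn_contract_error")
  expect_error(dag(c("A", "B"), rbind(c("A", "C"))),
               class = "smmbn_identifier_error")
  expect_error(dag(c("A", "B"), rbind(c("A", "A"))),
               class = "smmbn_contract_error")
  expect_error(dag(c("A", "B", "C"),
                   rbind(c("A", "B"), c("B", "C"), c("C", "A"))),
               class = "smmbn_contract_error")
  # mutation re-checks acyclicity
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_error(add_arc(g, "C", "A"), class = "smmbn_contract_error")
  tri <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C"), c("C", "B")))
  expect_error(reverse_arc(tri, "A", "B"), class = "smmbn_contract_error")
  g2 <- reverse_arc(drop_arc(g, "B", "C"), "A", "B")
  expect_equal(arcs(g2), data.frame(from = "B", to = "A"))
  # pdag: directed and undirected sets disjoint over unordered projections
  expect_error(pdag(c("A", "B"), arcs = rbind(c("A", "B")),
                    undirected = rbind(c("A", "B"))),
               class = "smmbn_contract_error")
})

test_that("topological order is deterministic with lexicographic ties", {
  g <- dag(c("Z", "A", "M"), rbind(c("Z", "M"), c("A", "M")))
  expect_identical(topological_order(g), c("A", "Z", "M"))
})

test_that("d-separation matches its textbook cases", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  coll <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_true(d_separated(coll, "A", "B"))
  expect_false(d_separated(coll, "A", "B", "C"))
  # conditioning on a collider's descendant also activates the path
  coll2 <- dag(c("A", "B", "C", "D"),
               rbind(c("A", "C"), c("B", "C"), c("C", "D")))
  expect_false(d_separated(coll2, "A", "B", "D"))
  expect_error(d_separated(chain, "A", "Q"), class = "smmbn_identifier_error")
  expect_error(d_separated(chain, "A", "A"), class = "smmbn_contract_error")
})

test_that("d-separation agrees with the exhaustive joint CI oracle", {
  for (seed in 1:4) {
    g <- rand_dag(5, arc_prob = 0.5, seed = seed)
    cpts <- rand_cpts(g, seed = seed + 100)
    joint <- oracle_joint(g, cpts)
    nodes <- g$nodes
    for (i in 1:4) for (j in (i + 1):5) {
      others <- setdiff(nodes, nodes[c(i, j)])
      for (k in 0:(2^length(others) - 1)) {
        z <- others[bitwAnd(k, 2^(seq_along(others) - 1)) > 0]
        # d-separation implies CI for every parameterization; the converse
        # can fail only on measure-zero parameter sets, so with random
        # CPTs the two must agree
        expect_identical(d_separated(g, nodes[i], nodes[j], z),
                         oracle_ci(joint, nodes[i], nodes[j], z, tol = 1e-9),
                         label = sprintf("seed %d: %s _||_ %s | {%s}", seed,
                                         nodes[i], nodes[j],
                                         paste(z, collapse = ",")))
      }
    }
  }
})

test_that("markov blankets collect parents, children and co-parents", {
  chain <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_identical(markov_blanket(chain, "B"), c("A", "C"))
  coll <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_identical(markov_blanket(coll, "A"), c("B", "C"))
  # outcome with parents only: blanket is exactly the parent set
  g <- dag(c("anemia", "hdp", "prior_csec", "smm"),
           rbind(c("anemia", "smm"), c("hdp", "smm"), c("prior_csec", "smm")))
  expect_identical(markov_blanket(g, "smm"), c("anemia", "hdp", "prior_csec"))
  # conditioning on the blanket d-separates the node from everything else
  for (seed in 5:7) {
    gg <- rand_dag(6, arc_prob = 0.4, seed = seed)
    for (v in gg$nodes) {
      mb <- markov_blanket(gg, v)
      for (u in setdiff(gg$nodes, c(v, mb)))
        expect_true(d_separated(gg, v, u, mb))
    }
  }
})

test_that("fit_cpts reproduces frequency counts and smoothing arithmetic", {
  x <- matrix(c(rep(1L, 7L), rep(2L, 3L)), ncol = 1L,
              dimnames = list(NULL, "X"))
  d <- discrete_dataset(x, levels = list(X = c("0", "1")))
  cp <- fit_cpts(dag("X"), d, smoothing = 0)
  expect_equal(cp$tables$X$prob[2L, 1L], 0.3)
  # binary Y | X with 8 of 10 at level 1 in the X=1 stratum
  xy <- cbind(X = rep(c(1L, 2L), each = 10L),
              Y = c(rep(1L, 10L), rep(2L, 8L), 1L, 1L))
  d2 <- discrete_dataset(xy, levels = list(X = c("0", "1"), Y = c("0", "1")))
  g2 <- dag(c("X", "Y"), rbind(c("X", "Y")))
  cp2 <- fit_cpts(g2, d2, smoothing = 0)
  expect_equal(cp2$tables$Y$prob[2L, 2L], 0.8)
  # counts (0, 4) with smoothing 1 -> (1/6, 5/6)
  d3 <- discrete_dataset(matrix(rep(2L, 4L), ncol = 1L,
                                dimnames = list(NULL, "Z")),
                         levels = list(Z = c("0", "1")))
  cp3 <- fit_cpts(dag("Z"), d3, smoothing = 1)
  expect_equal(cp3$tables$Z$prob[, 1L], c(no = 1 / 6, yes = 5 / 6),
               ignore_attr = TRUE)
  # unseen parent configuration at smoothing 0 -> uniform
  d4 <- discrete_dataset(cbind(X = c(1L, 1L), Y = c(1L, 2L)),
                         levels = list(X = c("0", "1"), Y = c("0", "1")))
  cp4 <- fit_cpts(g2, d4, smoothing = 0)
  expect_equal(cp4$tables$Y$prob[, 2L], c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("fitted CPTs maximize the log-likelihood (perturbation check)", {
  fx <- fixture_network("diamond4")
  d <- ancestral_sample(fx$dag, fx$cpts, 2000, seed = 11)
  cp <- fit_cpts(fx$dag, d, smoothing = 0)
  ll <- function(cpts) sum(log(vapply(seq_len(nrow(d$x)), function(r)
    joint_probability(fx$dag, cpts,
                      stats::setNames(as.list(d$x[r, ]), colnames(d$x))), 0)))
  base <- ll(cp)
  for (v in c("X", "Y")) for (dlt in c(-0.05, 0.05)) {
    pert <- cp
    col <- pert$tables[[v]]$prob[, 1L]
    col <- pmin(pmax(col + c(dlt, -dlt), 1e-6), 1 - 1e-6)
    pert$tables[[v]]$prob[, 1L] <- col / sum(col)
    expect_lt(ll(pert), base + 1e-9)
  }
})

test_that("joint_probability multiplies the chain-rule factors", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  cp <- cpt_set(g, list(A = c("0", "1"), B = c("0", "1")),
                list(A = matrix(c(0.5, 0.5), ncol = 1L),
                     B = list(parents = "A",
                              prob = rbind(c(0.9, 0.2), c(0.1, 0.8)))))
  expect_equal(joint_probability(g, cp, c(A = "1", B = "1")), 0.4)
  expect_error(joint_probability(g, cp, c(A = "1")),
               class = "smmbn_contract_error")
  # normalization over all full assignments, on a random fixture
  g5 <- rand_dag(5, seed = 21)
  cp5 <- rand_cpts(g5, seed = 22)
  joint <- oracle_joint(g5, cp5)
  expect_equal(sum(joint$prob), 1, tolerance = 1e-9)
  tot <- sum(vapply(seq_len(nrow(joint)), function(r)
    joint_probability(g5, cp5, stats::setNames(as.list(
      as.integer(joint[r, g5$nodes])), g5$nodes)), 0))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("exact_query agrees with hand arithmetic and the joint oracle", {
  fx <- fixture_network("chain3")
  hand <- 0.7 * 0.8 + 0.1 * 0.2       # P(C=1|A=1) through B
  expect_equal(exact_query(fx$dag, fx$cpts, c(C = "1"), c(A = "1")), hand,
               tolerance = 1e-12)
  expect_equal(exact_query(fx$dag, fx$cpts, c(A = "1"), c(A = "1")), 1)
  # empty evidence reduces to the marginal
  fm <- fixture_network("mixed7")
  joint <- oracle_joint(fm$dag, fm$cpts)
  expect_equal(exact_query(fm$dag, fm$cpts, c(Y = "1")),
               oracle_query(joint, fm$cpts, c(Y = "1")), tolerance = 1e-12)
  expect_equal(exact_query(fm$dag, fm$cpts, c(Y = "1"), c(Z = "0", W = "1")),
               oracle_query(joint, fm$cpts, c(Y = "1"), c(Z = "0", W = "1")),
               tolerance = 1e-12)
  # zero-probability evidence is an undefined conditional
  g0 <- dag(c("A", "B"), rbind(c("A", "B")))
  cp0 <- cpt_set(g0, list(A = c("0", "1"), B = c("0", "1")),
                 list(A = matrix(c(1, 0), ncol = 1L),
                      B = list(parents = "A",
                               prob = rbind(c(0.5, 0.5), c(0.5, 0.5)))))
  expect_error(exact_query(g0, cp0, c(B = "1"), c(A = "1")),
               class = "smmbn_degenerate_error")
})

test_that("ancestral sampling is seeded, complete and consistent", {
  fx <- fixture_network("collider3")
  expect_error(ancestral_sample(fx$dag, fx$cpts, 0),
               class = "smmbn_contract_error")
  one <- ancestral_sample(fx$dag, fx$cpts, 1, seed = 5)
  expect_identical(dim(one$x), c(1L, 3L))
  a <- ancestral_sample(fx$dag, fx$cpts, 500, seed = 9)
  b <- ancestral_sample(fx$dag, fx$cpts, 500, seed = 9)
  expect_identical(a$x, b$x)
  # marginals within 4 binomial SE of the exact values at n = 1e5
  n <- 1e5
  s <- ancestral_sample(fx$dag, fx$cpts, n, seed = 10)
  for (v in c("A", "B", "C")) {
    p <- exact_query(fx$dag, fx$cpts, stats::setNames("1", v))
    expect_lt(abs(mean(s$x[, v] == 2L) - p), 4 * sqrt(p * (1 - p) / n))
  }
  # empirical full-assignment frequencies track the joint
  fd <- fixture_network("diamond4")
  sd4 <- ancestral_sample(fd$dag, fd$cpts, n, seed = 12)
  joint <- oracle_joint(fd$dag, fd$cpts)
  cell <- (sd4$x[, "X"] - 1L) + 2L * (sd4$x[, "A"] - 1L) +
    4L * (sd4$x[, "B"] - 1L) + 8L * (sd4$x[, "Y"] - 1L)
  emp <- tabulate(cell + 1L, nbins = 16L) / n
  key <- (joint$X - 1L) + 2L * (joint$A - 1L) + 4L * (joint$B - 1L) +
    8L * (joint$Y - 1L)
  for (r in seq_len(nrow(joint))) {
    p <- joint$prob[r]
    expect_lt(abs(emp[key[r] + 1L] - p), 4 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("to_cpdag keeps compelled arcs and drops reversible ones", {
  single <- to_cpdag(dag(c("A", "B"), rbind(c("A", "B"))))
  expect_equal(nrow(arcs(single)), 0L)
  expect_equal(nrow(undirected_edges(single)), 1L)
  vs <- to_cpdag(dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C"))))
  expect_setequal(paste(arcs(vs)$from, arcs(vs)$to), c("A C", "B C"))
  # Meek R1: A -> B - C with A, C non-adjacent compels B -> C
  g <- dag(c("A", "B", "C", "D"),
           rbind(c("A", "B"), c("D", "B"), c("B", "C")))
  cp <- to_cpdag(g)
  expect_true("C" %in% children(cp, "B"))
  # random DAGs: consistent extensions of the CPDAG are Markov equivalent
  for (seed in 31:35) {
    gg <- rand_dag(6, arc_prob = 0.4, seed = seed)
    cpd <- to_cpdag(gg)
    ext <- consistent_extension(cpd)
    # same skeleton and same v-structures => identical d-separations
    expect_identical(skeleton_pairs(ext), skeleton_pairs(gg))
    vs_of <- function(g) {
      m <- smmbn:::v_structures(g)
      if (!nrow(m)) character(0) else sort(apply(m, 1L, paste, collapse = ">"))
    }
    expect_identical(vs_of(ext), vs_of(gg))
    nodes <- gg$nodes
    set.seed(seed)
    for (k in 1:25) {
      xy <- sample(nodes, 2L)
      z <- sample(setdiff(nodes, xy), sample(0:3, 1L))
      expect_identical(d_separated(gg, xy[1L], xy[2L], z),
                       d_separated(ext, xy[1L], xy[2L], z))
    }
  }
})

test_that("structure interchange round-trips", {
  fx <- fixture_network("mixed7")
  ms <- model_string(fx$dag)
  expect_identical(model_string(parse_model_string(ms)), ms)
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(fx$dag, tf)
  expect_identical(arcs(read_graphml(tf)), arcs(fx$dag))
  # pdag round-trip keeps undirected edges undirected
  cp <- to_cpdag(dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))))
  tf2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(cp, tf2)
  back <- read_graphml(tf2)
  expect_identical(undirected_edges(back), undirected_edges(cp))
  td <- withr::local_tempfile(fileext = ".dot")
  write_dot(fx$dag, td)
  expect_setequal(paste(arcs(read_dot(td))$from, arcs(read_dot(td))$to),
                  paste(arcs(fx$dag)$from, arcs(fx$dag)$to))
})
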