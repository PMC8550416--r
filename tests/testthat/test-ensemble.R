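test_that("run_replicates is seeded and finds planted arcs", {
  set.seed(1)
  a <- sample(1:2, 1500, replace = TRUE)
  d <- discrete_dataset(cbind(A = a, B = a),   # deterministic dependence
                        levels = list(A = c("0", "1"), B = c("0", "1")))
  cfg <- algorithm_config("hc")
  r1 <- run_replicates(d, cfg, B = 5, seed = 9)
  r2 <- run_replicates(d, cfg, B = 5, seed = 9)
  expect_identical(lapply(r1, `[[`, "amat"), lapply(r2, `[[`, "amat"))
  # B = 1 without resampling equals learning on the data directly
  r0 <- run_replicates(d, cfg, B = 1, seed = 9, resample = FALSE)
  expect_identical(r0[[1L]]$amat, to_cpdag(hill_climb(d, cfg))$amat)
  # the planted edge appears in every bootstrap replicate
  reps <- run_replicates(d, cfg, B = 50, seed = 10)
  pairs <- vapply(reps, function(g) nrow(skeleton_pairs(g)) == 1L &&
                    all(skeleton_pairs(g) == c("A", "B")), TRUE)
  expect_true(all(pairs))
})

test_that("score_algorithm_arcs implements the 1 / 0.5 / 0 rule", {
  mk_dir <- function() dag(c("A", "B"), rbind(c("A", "B")))
  mk_und <- function() to_cpdag(mk_dir())
  mk_none <- function() dag(c("A", "B"))
  # all replicates contain A -> B as a directed arc
  s <- score_algorithm_arcs(replicate(100, mk_dir(), simplify = FALSE), 0.7)
  expect_equal(s, data.frame(from = "A", to = "B", score = 1))
  # direction split 40/40 with 20% absent: edge 0.8 > 0.7, no direction
  rev1 <- dag(c("A", "B"), rbind(c("B", "A")))
  reps <- c(replicate(4, mk_dir(), simplify = FALSE),
            replicate(4, rev1, simplify = FALSE),
            replicate(2, mk_none(), simplify = FALSE))
  s2 <- score_algorithm_arcs(reps, 0.7)
  expect_equal(s2$score, 0.5)
  # a 60% direction does not clear the strict threshold
  reps3 <- c(replicate(6, mk_dir(), simplify = FALSE),
             replicate(4, mk_none(), simplify = FALSE))
  expect_equal(nrow(score_algorithm_arcs(reps3, 0.7)), 0L)
  # exactly at the threshold is still out (strict >)
  reps4 <- c(replicate(7, mk_dir(), simplify = FALSE),
             replicate(3, mk_none(), simplify = FALSE))
  expect_equal(nrow(score_algorithm_arcs(reps4, 0.7)), 0L)
  # undirected edges count toward the edge frequency only
  reps5 <- c(replicate(8, mk_und(), simplify = FALSE),
             replicate(2, mk_none(), simplify = FALSE))
  expect_equal(score_algorithm_arcs(reps5, 0.7)$score, 0.5)
  # invariance to replicate order
  expect_equal(score_algorithm_arcs(rev(reps), 0.7), s2)
})

test_that("consensus tables assemble, sum and sort correctly", {
  one <- data.frame(from = "A", to = "B", score = 1)
  ct1 <- build_consensus(list(alg = one), "alg")
  expect_equal(unname(ct1$occurrence), 1)
  expect_equal(unname(ct1$totals), 1)
  # eleven algorithms all scoring one arc 1 -> occurrence 11
  scores <- stats::setNames(replicate(11, one, simplify = FALSE),
                            paste0("a", 1:11))
  ct11 <- build_consensus(scores)
  expect_equal(unname(ct11$occurrence), 11)
  # mixed entries 1, 1, 0.5 sum to 2.5
  ctm <- build_consensus(list(x = one, y = one,
                              z = data.frame(from = "A", to = "B", score = 0.5)))
  expect_equal(unname(ctm$occurrence), 2.5)
  # row and column sums recompute exactly from the entries matrix
  s_multi <- list(
    p = data.frame(from = c("A", "C"), to = c("B", "B"), score = c(1, 0.5)),
    q = data.frame(from = "A", to = "B", score = 1))
  ct <- build_consensus(s_multi)
  expect_equal(unname(ct$occurrence), unname(rowSums(ct$entries)))
  expect_equal(unname(ct$totals), unname(colSums(ct$entries)))
  # rows sorted by occurrence descending
  expect_true(all(diff(ct$occurrence) <= 0))
  # CSV export carries the total row
  tf <- withr::local_tempfile(fileext = ".csv")
  write_consensus_csv(ct, tf)
  out <- utils::read.csv(tf, check.names = FALSE)
  expect_equal(out$arc[nrow(out)], "total_arcs")
})

test_that("algorithm selection ranks totals with roster-order ties", {
  ids <- c("hc-bic", "hc-aic", "tabu-bic", "tabu-aic", "gs", "iamb",
           "fast-iamb", "inter-iamb", "mmhc", "h2pc", "rsmax2")
  totals <- c(29, 29, 28, 29, 8, 20, 16.5, 20, 28, 28, 26)
  mk <- function(tot) {
    k <- floor(tot)
    data.frame(from = paste0("n", seq_len(k + (tot > k))), to = "t",
               score = c(rep(1, k), if (tot > k) 0.5),
               stringsAsFactors = FALSE)
  }
  scores <- stats::setNames(lapply(totals, mk), ids)
  ct <- build_consensus(scores, ids)
  expect_equal(unname(ct$totals), totals)
  expect_identical(select_algorithms(ct, 3),
                   c("hc-bic", "hc-aic", "tabu-aic"))
  expect_identical(select_algorithms(ct, 11)[1:4],
                   c("hc-bic", "hc-aic", "tabu-aic", "tabu-bic"))
  expect_error(select_algorithms(ct, 12), class = "smmbn_contract_error")
  # all-equal totals fall back to roster order
  eq <- stats::setNames(replicate(3, mk(2), simplify = FALSE), c("x", "y", "z"))
  expect_identical(select_algorithms(build_consensus(eq), 2), c("x", "y"))
})

test_that("misclassification behaves on degenerate relationships", {
  # target independent of the lone predictor, prior perturbed to 0.6/0.4:
  # the majority level is always predicted
  set.seed(31)
  n <- 4000
  t_lv <- ifelse(runif(n) < 0.4, 2L, 1L)
  x_lv <- sample(1:2, n, replace = TRUE)
  d <- discrete_dataset(cbind(X = x_lv, T = t_lv),
                        levels = list(X = c("0", "1"), T = c("0", "1")))
  sp <- train_test_split(d, 0.7, seed = 5)
  g <- dag(c("X", "T"))
  r <- misclassification_rate(g, sp$train, sp$test, "T")
  expect_equal(as.numeric(r), mean(sp$test$x[, "T"] == 2L))
  # deterministic parent -> zero error
  d2 <- discrete_dataset(cbind(X = x_lv, T = x_lv),
                         levels = list(X = c("0", "1"), T = c("0", "1")))
  sp2 <- train_test_split(d2, 0.7, seed = 6)
  g2 <- dag(c("X", "T"), rbind(c("X", "T")))
  expect_equal(as.numeric(
    misclassification_rate(g2, sp2$train, sp2$test, "T")), 0)
  # replicate-averaged mode returns the per-replicate rates
  r3 <- misclassification_rate(g2, sp2$train, sp2$test, "T", replicates = 5)
  expect_length(attr(r3, "replicates"), 5L)
})

test_that("balanced training beats the uninformative baseline on the cohort", {
  co <- small_cohort(n = 30000, seed = 13)
  sp <- train_test_split(co, 0.7, seed = 14)
  bal <- undersample(sp$train, "smm", seed = 15)
  cs <- layer_blacklist(co$layers)
  g <- hill_climb(bal, algorithm_config("hc", score = "bic"), cs)
  rate <- as.numeric(misclassification_rate(g, bal, sp$test, "smm",
                                            smoothing = 1))
  # a balanced-trained classifier with no signal errs ~50% of the time
  expect_lt(rate, 0.5)
})

test_that("bootstrap arc strengths are frequencies of learned arcs", {
  set.seed(41)
  a <- sample(1:2, 1200, replace = TRUE)
  d <- discrete_dataset(cbind(A = a, B = a),
                        levels = list(A = c("0", "1"), B = c("0", "1")))
  cs <- constraint_set(whitelist = rbind(c("A", "B")))
  st <- bootstrap_arc_strength(d, algorithm_config("hc"), R = 20, m = 400,
                               seed = 42, constraints = cs)
  expect_equal(strength_of(st, "A", "B"), 1)
  expect_equal(attr(st, "R"), 20L)
  # independent variables: all strengths low
  di <- indep_data(3000, 3, seed = 43)
  sti <- bootstrap_arc_strength(di, algorithm_config("hc"), R = 50, m = 1000,
                                seed = 44)
  if (nrow(sti)) expect_true(all(sti$strength < 0.3))
  # strengths lie in [0, 1] and R * strength is (half-)integral
  co <- small_cohort(n = 6000)
  bal <- undersample(train_test_split(co, 0.7, 1)$train, "smm", 2)
  stc <- bootstrap_arc_strength(bal, algorithm_config("hc"), R = 10,
                                m = nrow(bal$x), seed = 45,
                                constraints = layer_blacklist(co$layers))
  expect_true(all(stc$strength >= 0 & stc$strength <= 1))
  expect_true(all(abs(stc$strength * 10 * 2 -
                        round(stc$strength * 10 * 2)) < 1e-9))
})
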