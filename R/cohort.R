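#' Synthetic birth-cohort configuration
#'
#' Collects the knobs of the calibrated ground-truth network behind the
#' synthetic cohort: cohort size and seed, the target outcome prevalence
#' (~2%, the rare-outcome imbalance the pipeline must cope with), the
#' race distribution, per-race conditional probabilities for anemia and
#' hypertensive disorder of pregnancy (HDP), the remaining comorbidity
#' parameters, the outcome's per-parent log-odds effects, and the spread
#' of the ordinal county-quartile variables.  Defaults are the package's
#' stated world; see the methods vignette for the rationale of each
#' value.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param prevalence target outcome marginal, in (0, 1).
#' @param race_dist probabilities over races white/black/hispanic/other,
#'   summing to 1.
#' @param p_anemia,p_hdp per-race conditional probabilities (named as
#'   `race_dist`).
#' @param outcome_effects log-odds increments of the outcome's parents
#'   (`hdp`, `anemia`, `prior_csec`); all-zero makes the outcome
#'   independent of its parents.
#' @param county_noise standard deviation of the latent ordinal scale
#'   generating the county quartile variables (default 0.9 quartile
#'   units; larger = noisier county structure).
#' @param htn_age,htn_race_or,p_csec_parity,p_obesity_pov,diab_age,
#'   diab_obesity_or,p_mental_ins remaining comorbidity parameters (see
#'   defaults).
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n = 50000L, seed = 1L, prevalence = 0.02,
                          race_dist = c(white = 0.70, black = 0.18,
                                        hispanic = 0.08, other = 0.04),
                          p_anemia = c(white = 0.07, black = 0.14,
                                       hispanic = 0.11, other = 0.12),
                          p_hdp = c(white = 0.11, black = 0.13,
                                    hispanic = 0.09, other = 0.09),
                          outcome_effects = c(hdp = log(6), anemia = log(3.5),
                                              prior_csec = log(2.5)),
                          county_noise = 0.9,
                          htn_age = c(0.015, 0.025, 0.05, 0.08),
                          htn_race_or = c(white = 1, black = 2,
                                          hispanic = 1.2, other = 1.2),
                          p_csec_parity = c(0.01, 0.30, 0.45),
                          p_obesity_pov = c(0.18, 0.22, 0.27, 0.32),
                          diab_age = c(0.01, 0.03, 0.06, 0.09),
                          diab_obesity_or = 2.5,
                          p_mental_ins = c(0.10, 0.17, 0.12)) {
  probs <- c(prevalence, race_dist, p_anemia, p_hdp, htn_age,
             p_csec_parity, p_obesity_pov, diab_age, p_mental_ins)
  if (any(probs <= 0 | probs >= 1))
    stop_config("all probabilities must lie strictly in (0, 1)")
  if (abs(sum(race_dist) - 1) > 1e-8)
    stop_config("race distribution must sum to 1")
  if (!is_scalar_number(county_noise) || county_noise <= 0)
    stop_config("county_noise must be positive")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalence = prevalence, race_dist = race_dist,
                 p_anemia = p_anemia, p_hdp = p_hdp,
                 outcome_effects = outcome_effects,
                 county_noise = county_noise, htn_age = htn_age,
                 htn_race_or = htn_race_or, p_csec_parity = p_csec_parity,
                 p_obesity_pov = p_obesity_pov, diab_age = diab_age,
                 diab_obesity_or = diab_obesity_or,
                 p_mental_ins = p_mental_ins),
            class = "cohort_config")
}

binary_levels <- c("no", "yes")
quartile_levels <- c("Q1", "Q2", "Q3", "Q4")

## One binary CPT column per parent config from P(yes).
bin_cpt <- function(p_yes) rbind(no = 1 - p_yes, yes = p_yes)

## Discretized latent ordinal distribution over the four quartile labels.
ordinal_row <- function(mu, sd) {
  d <- stats::dnorm(1:4, mean = mu, sd = sd)
  d / sum(d)
}

#' Calibrated ground-truth network
#'
#' Builds the three-layer, 19-node DAG and CPTs that generate the
#' synthetic cohort.  Layer 0 holds demographics and the ordinal county
#' quartile variables; layer 1 the comorbidity flags with race- and
#' age-dependent tables; layer 2 the binary outcome with parents
#' `{hdp, anemia, prior_csec}`.  The per-race anemia and HDP
#' probabilities are exact CPT entries; the outcome's base rate is solved
#' numerically so that the exact marginal prevalence equals the
#' configured target.  County variables reach the outcome only through
#' comorbidities (they carry no influence on the outcome themselves).
#'
#' @param config a [cohort_config()].
#' @return List with elements `dag`, `cpts`, `layers` and the solved
#'   `base_rate`.
#' @export
default_ground_truth <- function(config = cohort_config()) {
  races <- names(config$race_dist)
  nodes <- c("race", "age", "education", "marital", "insurance", "parity",
             "pct_black_q", "pct_poverty_q", "pct_urban_q", "pct_owner_q",
             "obgyn_q",
             "anemia", "hdp", "preexist_htn", "prior_csec", "diabetes",
             "obesity", "mental_health", "smm")
  layers <- stats::setNames(c(rep(0L, 11L), rep(1L, 7L), 2L), nodes)
  levels <- list(
    race = races,
    age = c("15-19", "20-34", "35-39", "40+"),
    education = c("less-hs", "hs", "college"),
    marital = c("married", "not-married"),
    insurance = c("private", "medicaid", "other"),
    parity = c("0", "1", "2+"),
    pct_black_q = quartile_levels, pct_poverty_q = quartile_levels,
    pct_urban_q = quartile_levels, pct_owner_q = quartile_levels,
    obgyn_q = quartile_levels,
    anemia = binary_levels, hdp = binary_levels,
    preexist_htn = binary_levels, prior_csec = binary_levels,
    diabetes = binary_levels, obesity = binary_levels,
    mental_health = binary_levels, smm = binary_levels)

  arcs <- rbind(
    c("race", "pct_black_q"),
    c("pct_black_q", "pct_urban_q"), c("pct_poverty_q", "pct_urban_q"),
    c("pct_black_q", "pct_owner_q"), c("pct_urban_q", "obgyn_q"),
    c("race", "marital"), c("education", "insurance"),
    c("race", "anemia"), c("race", "hdp"),
    c("race", "preexist_htn"), c("age", "preexist_htn"),
    c("parity", "prior_csec"),
    c("pct_poverty_q", "obesity"),
    c("age", "diabetes"), c("obesity", "diabetes"),
    c("insurance", "mental_health"),
    c("hdp", "smm"), c("anemia", "smm"), c("prior_csec", "smm"))
  g <- dag(nodes, arcs)

  noise <- config$county_noise
  age_dist <- c(0.08, 0.77, 0.12, 0.03)
  parity_dist <- c(0.40, 0.32, 0.28)
  tables <- list(
    race = matrix(unname(config$race_dist), ncol = 1L),
    age = matrix(age_dist, ncol = 1L),
    education = matrix(c(0.14, 0.38, 0.48), ncol = 1L),
    parity = matrix(parity_dist, ncol = 1L),
    pct_poverty_q = matrix(rep(0.25, 4L), ncol = 1L),
    marital = list(parents = "race",
                   prob = rbind(c(0.65, 0.35, 0.55, 0.60),
                                1 - c(0.65, 0.35, 0.55, 0.60))),
    insurance = list(parents = "education",
                     prob = cbind(c(0.15, 0.80, 0.05),
                                  c(0.40, 0.55, 0.05),
                                  c(0.70, 0.25, 0.05))),
    pct_black_q = list(parents = "race",
                       prob = cbind(c(0.35, 0.30, 0.20, 0.15),
                                    c(0.10, 0.20, 0.30, 0.40),
                                    rep(0.25, 4L), rep(0.25, 4L))),
    anemia = list(parents = "race", prob = bin_cpt(unname(config$p_anemia))),
    hdp = list(parents = "race", prob = bin_cpt(unname(config$p_hdp))),
    prior_csec = list(parents = "parity",
                      prob = bin_cpt(config$p_csec_parity)),
    obesity = list(parents = "pct_poverty_q",
                   prob = bin_cpt(config$p_obesity_pov)),
    mental_health = list(parents = "insurance",
                         prob = bin_cpt(config$p_mental_ins)))
  # county ordinal tables: latent scale mean mixes the parents' quartiles
  urb <- sapply(seq_len(16L), function(k) {
    b <- (k - 1L) %% 4L + 1L            # pct_black_q varies fastest
    p <- (k - 1L) %/% 4L + 1L
    ordinal_row(0.7 * b + 0.3 * (5 - p), noise)
  })
  tables$pct_urban_q <- list(parents = c("pct_black_q", "pct_poverty_q"),
                             prob = urb)
  tables$pct_owner_q <- list(parents = "pct_black_q",
                             prob = sapply(1:4, function(b)
                               ordinal_row(5 - b, noise)))
  tables$obgyn_q <- list(parents = "pct_urban_q",
                         prob = sapply(1:4, function(u) ordinal_row(u, noise)))
  # preexisting hypertension: age base rates with race odds multipliers
  htn <- sapply(seq_len(16L), function(k) {
    r <- (k - 1L) %% 4L + 1L            # race varies fastest
    a <- (k - 1L) %/% 4L + 1L
    stats::plogis(stats::qlogis(config$htn_age[a]) +
                    log(unname(config$htn_race_or)[r]))
  })
  tables$preexist_htn <- list(parents = c("race", "age"), prob = bin_cpt(htn))
  diab <- sapply(seq_len(8L), function(k) {
    a <- (k - 1L) %% 4L + 1L            # age varies fastest
    o <- (k - 1L) %/% 4L + 1L
    stats::plogis(stats::qlogis(config$diab_age[a]) +
                    (o == 2L) * log(config$diab_obesity_or))
  })
  tables$diabetes <- list(parents = c("age", "obesity"), prob = bin_cpt(diab))

  # outcome: solve the base rate so the exact marginal hits the target.
  # P(anemia, hdp) mixes over race; prior_csec mixes over parity.
  p_joint_ah <- function(a, h) sum(config$race_dist *
    (a * config$p_anemia + (1 - a) * (1 - config$p_anemia)) *
    (h * config$p_hdp + (1 - h) * (1 - config$p_hdp)))
  p_cs <- sum(parity_dist * config$p_csec_parity)
  beta <- config$outcome_effects
  marginal <- function(logit_base) {
    tot <- 0
    for (h in 0:1) for (a in 0:1) for (cs in 0:1) {
      p_cfg <- p_joint_ah(a, h) * (cs * p_cs + (1 - cs) * (1 - p_cs))
      tot <- tot + p_cfg * stats::plogis(logit_base + h * beta[["hdp"]] +
        a * beta[["anemia"]] + cs * beta[["prior_csec"]])
    }
    tot
  }
  f <- function(lb) marginal(lb) - config$prevalence
  if (f(-30) > 0 || f(10) < 0)
    stop_config("prevalence target %.4f is infeasible under the configured effects",
                config$prevalence)
  logit_base <- stats::uniroot(f, c(-30, 10), tol = 1e-12)$root
  smm <- sapply(seq_len(8L), function(k) {
    h <- (k - 1L) %% 2L                  # hdp varies fastest
    a <- ((k - 1L) %/% 2L) %% 2L
    cs <- (k - 1L) %/% 4L
    stats::plogis(logit_base + h * beta[["hdp"]] + a * beta[["anemia"]] +
                    cs * beta[["prior_csec"]])
  })
  tables$smm <- list(parents = c("hdp", "anemia", "prior_csec"),
                     prob = bin_cpt(smm))

  list(dag = g, cpts = cpt_set(g, levels, tables), layers = layers,
       base_rate = stats::plogis(logit_base))
}

#' Generate a synthetic cohort
#'
#' Ancestral-samples `config$n` records from the calibrated ground truth;
#' identical configurations (including seed) reproduce identical
#' datasets, and [write_dataset_csv()] output is byte-identical across
#' runs.
#'
#' @param config a [cohort_config()].
#' @return A [discrete_dataset()] with layer tags attached.
#' @export
generate_cohort <- function(config = cohort_config()) {
  gt <- default_ground_truth(config)
  ancestral_sample(gt$dag, gt$cpts, config$n, config$seed, layers = gt$layers)
}

#' Small fixture networks with hand-specified CPTs
#'
#' A catalogue of tiny networks whose exact query answers are documented
#' and recomputed by hand across the test suite: `chain3` (A -> B -> C),
#' `collider3` (A -> C <- B), `diamond4` (X -> A -> Y, X -> B -> Y) and
#' `mixed7` (a seven-node graph mixing forks, chains and one collider,
#' used by the path-enumeration oracle).
#'
#' @param id one of `"chain3"`, `"collider3"`, `"diamond4"`, `"mixed7"`.
#' @return List with elements `dag` and `cpts`.
#' @export
fixture_network <- function(id) {
  b <- c("0", "1")
  if (identical(id, "chain3")) {
    g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
    cpts <- cpt_set(g, list(A = b, B = b, C = b), list(
      A = matrix(c(0.7, 0.3), ncol = 1L),
      B = list(parents = "A", prob = rbind(c(0.8, 0.2), c(0.2, 0.8))),
      C = list(parents = "B", prob = rbind(c(0.9, 0.3), c(0.1, 0.7)))))
  } else if (identical(id, "collider3")) {
    g <- dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
    cpts <- cpt_set(g, list(A = b, B = b, C = b), list(
      A = matrix(c(0.6, 0.4), ncol = 1L),
      B = matrix(c(0.4, 0.6), ncol = 1L),
      C = list(parents = c("A", "B"),
               prob = bin_cpt(c(0.1, 0.7, 0.5, 0.9)))))
  } else if (identical(id, "diamond4")) {
    g <- dag(c("X", "A", "B", "Y"),
             rbind(c("X", "A"), c("X", "B"), c("A", "Y"), c("B", "Y")))
    cpts <- cpt_set(g, list(X = b, A = b, B = b, Y = b), list(
      X = matrix(c(0.5, 0.5), ncol = 1L),
      A = list(parents = "X", prob = bin_cpt(c(0.2, 0.7))),
      B = list(parents = "X", prob = bin_cpt(c(0.3, 0.6))),
      Y = list(parents = c("A", "B"),
               prob = bin_cpt(c(0.05, 0.5, 0.4, 0.9)))))
  } else if (identical(id, "mixed7")) {
    g <- dag(c("Z", "X", "M1", "M2", "Y", "C", "W"),
             rbind(c("Z", "X"), c("Z", "Y"),
                   c("X", "M1"), c("M1", "Y"),
                   c("X", "M2"), c("M2", "Y"),
                   c("X", "C"), c("Y", "C"),
                   c("W", "M1")))
    lv <- stats::setNames(rep(list(b), 7L),
                          c("Z", "X", "M1", "M2", "Y", "C", "W"))
    cpts <- cpt_set(g, lv, list(
      Z = matrix(c(0.5, 0.5), ncol = 1L),
      W = matrix(c(0.7, 0.3), ncol = 1L),
      X = list(parents = "Z", prob = bin_cpt(c(0.3, 0.7))),
      M1 = list(parents = c("X", "W"),
                prob = bin_cpt(c(0.2, 0.6, 0.4, 0.8))),
      M2 = list(parents = "X", prob = bin_cpt(c(0.25, 0.65))),
      Y = list(parents = c("Z", "M1", "M2"),
               prob = bin_cpt(c(0.05, 0.3, 0.35, 0.6, 0.25, 0.5, 0.55, 0.85))),
      C = list(parents = c("X", "Y"),
               prob = bin_cpt(c(0.1, 0.5, 0.6, 0.9)))))
  } else {
    stop_identifier("unknown fixture id %s", as.character(id))
  }
  list(dag = g, cpts = cpts)
}
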