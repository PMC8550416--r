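#' Quartile discretization
#'
#' Cuts a numeric vector at its empirical 25/50/75 percentiles
#' (linear-interpolation definition, `stats::quantile` type 7) into the
#' ordinal labels `Q1..Q4`.  Intervals are left-open/right-closed except
#' the lowest, so a value equal to a cut point falls in the lower
#' interval.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @return Character vector of labels `Q1..Q4`, same length as `values`.
#' @export
quartile_discretize <- function(values) {
  if (!is.numeric(values)) stop_contract("values must be numeric")
  if (length(unique(values)) < 2L)
    stop_degenerate("constant input cannot be discretized into quartiles")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(duplicated(qs)))
    stop_degenerate("quartile cut points are not distinct")
  breaks <- c(-Inf, qs, Inf)
  as.character(cut(values, breaks, labels = paste0("Q", 1:4), right = TRUE))
}

#' Maternal age binning
#'
#' Discretizes a numeric age column into the four standard maternal age
#' categories: 15-19 (everything under 20), 20-34, 35-39 and 40+.
#'
#' @param values numeric ages.
#' @return Character vector of labels `15-19`, `20-34`, `35-39`, `40+`.
#' @export
age_discretize <- function(values) {
  if (!is.numeric(values)) stop_contract("values must be numeric")
  as.character(cut(values, c(-Inf, 19, 34, 39, Inf),
                   labels = c("15-19", "20-34", "35-39", "40+"),
                   right = TRUE))
}

#' Random train/test split
#'
#' Disjoint partition covering every record with
#' `round(fraction * N)` training rows; the stratified mode draws
#' `round(fraction * n_level)` rows within each target level, preserving
#' class proportions within rounding.
#'
#' @param data a [discrete_dataset()].
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify logical; stratify on `target`.
#' @param target target variable (required when `stratify = TRUE`).
#' @return List with `train` and `test` datasets.
#' @export
train_test_split <- function(data, fraction = 0.7, seed = 1L,
                             stratify = FALSE, target = NULL) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    stop_contract("fraction must be in (0, 1)")
  n <- nrow(data$x)
  idx <- with_seed(seed, {
    if (stratify) {
      if (is.null(target)) stop_contract("stratified split needs a target")
      lev <- data$x[, target]
      unlist(lapply(sort(unique(lev)), function(l) {
        rows <- which(lev == l)
        sample(rows, round(fraction * length(rows)))
      }))
    } else sample.int(n, round(fraction * n))
  })
  idx <- sort(idx)
  list(train = dataset_subset(data, idx),
       test = dataset_subset(data, setdiff(seq_len(n), idx)))
}

#' Random under-sampling of the majority class
#'
#' Keeps every minority-class record and a uniform
#' without-replacement subset of majority records of equal size,
#' producing a balanced dataset; record order is the original row order
#' (deterministic given the seed).
#'
#' @param data a [discrete_dataset()].
#' @param target binary target variable.
#' @param seed integer seed.
#' @return A balanced [discrete_dataset()].
#' @export
undersample <- function(data, target, seed = 1L) {
  if (!target %in% dataset_vars(data)) stop_identifier("unknown target %s", target)
  lev <- data$x[, target]
  counts <- tabulate(lev, nbins = length(data$levels[[target]]))
  present <- which(counts > 0L)
  if (length(present) < 2L)
    stop_degenerate("under-sampling needs both target classes present")
  if (length(counts) != 2L)
    stop_contract("target must be binary")
  minority <- which.min(counts)
  majority <- 3L - minority
  keep_min <- which(lev == minority)
  maj_rows <- which(lev == majority)
  keep_maj <- with_seed(seed, sample(maj_rows, counts[minority]))
  dataset_subset(data, sort(c(keep_min, keep_maj)))
}

#' Pipeline configuration
#'
#' Bundles every choice of the end-to-end procedure: the input (a CSV
#' path with declared layers, or a [cohort_config()] for synthetic
#' data), the target, split/under-sampling/replicate/bootstrap/query
#' seeds, the algorithm roster, the consensus threshold and selection
#' size, bootstrap parameters, the influence-ranking mode and the query
#' roster.
#'
#' @param input `NULL` (synthetic) or path to a CSV file.
#' @param cohort a [cohort_config()] used when `input` is `NULL`.
#' @param layers named layer tags for CSV input.
#' @param target target variable name.
#' @param split_fraction training fraction.
#' @param stratify stratified split on the target.
#' @param seeds named list/vector with entries `split`, `undersample`,
#'   `replicates`, `bootstrap`, `queries`.
#' @param roster list of [algorithm_config()]s (default
#'   [default_roster()]).
#' @param threshold consensus occurrence threshold (strict, default 0.7).
#' @param k number of algorithms selected.
#' @param replicates_B replicate runs per algorithm feeding the consensus.
#' @param bootstrap_R,bootstrap_m arc-strength bootstrap replicates and
#'   resample size.
#' @param strength_data `"balanced"` (default) or `"original"`: which
#'   training data feeds [bootstrap_arc_strength()].
#' @param smoothing CPT smoothing for prediction and queries.
#' @param mc_replicates Monte-Carlo refits for the misclassification
#'   report.
#' @param dwi_exclusions arcs removed before influence ranking.
#' @param dwi_w optional constant DWI weight (otherwise
#'   strength-weighted).
#' @param query_group grouping variable for disparity queries.
#' @param query_event named event vector, e.g. `c(smm = "yes")`.
#' @param query_levels compared levels (first entry of the group
#'   variable's levels is the reference when `NULL`).
#' @param query_n,query_replicates likelihood-weighting effort.
#' @param out_dir artifact directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, cohort = cohort_config(),
                            layers = NULL, target = "smm",
                            split_fraction = 0.7, stratify = FALSE,
                            seeds = list(split = 11L, undersample = 22L,
                                         replicates = 33L, bootstrap = 44L,
                                         queries = 55L),
                            roster = default_roster(), threshold = 0.7,
                            k = 3L, replicates_B = 100L,
                            bootstrap_R = 1000L, bootstrap_m = 1000L,
                            strength_data = c("balanced", "original"),
                            smoothing = 1, mc_replicates = 1L,
                            dwi_exclusions = NULL, dwi_w = NULL,
                            query_group = "race",
                            query_event = c(smm = "yes"),
                            query_levels = NULL, query_n = 10000L,
                            query_replicates = 30L, out_dir = "smmbn-run") {
  if (!is_scalar_number(split_fraction) || split_fraction <= 0 ||
      split_fraction >= 1) stop_config("split fraction must be in (0, 1)")
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stop_config("threshold must be in (0, 1)")
  if (k > length(roster)) stop_config("k exceeds the roster size")
  structure(list(input = input, cohort = cohort, layers = layers,
                 target = target, split_fraction = split_fraction,
                 stratify = stratify, seeds = as.list(seeds),
                 roster = roster, threshold = threshold, k = as.integer(k),
                 replicates_B = as.integer(replicates_B),
                 bootstrap_R = as.integer(bootstrap_R),
                 bootstrap_m = as.integer(bootstrap_m),
                 strength_data = match.arg(strength_data),
                 smoothing = smoothing,
                 mc_replicates = as.integer(mc_replicates),
                 dwi_exclusions = dwi_exclusions, dwi_w = dwi_w,
                 query_group = query_group, query_event = query_event,
                 query_levels = query_levels,
                 query_n = as.integer(query_n),
                 query_replicates = as.integer(query_replicates),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s | %s", stage, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the end-to-end pipeline
#'
#' Executes, in order: load/generate -> split -> under-sample the
#' training set -> replicate structure learning for every roster
#' algorithm -> consensus table -> top-k selection -> misclassification
#' on the untouched original test set -> bootstrap arc strength with the
#' lowest-misclassification algorithm -> strength-weighted influence
#' ranking towards the target -> disparity odds-ratio queries.  Writes
#' `consensus.csv`, `selection.json`, `misclassification.csv`,
#' `arc_strength.csv`, `network.graphml`, `dwi.csv`, `odds_ratios.csv`
#' and a `manifest.json` from which the run is exactly reproducible.
#'
#' @param config a [pipeline_config()] (or path to a manifest JSON).
#' @param stages subset of
#'   `c("prepare", "learn", "strength", "influence", "query")`; later
#'   stages imply earlier ones.
#' @return Invisibly, a list bundle with all intermediate objects and
#'   artifact paths.
#' @export
run_pipeline <- function(config, stages = c("prepare", "learn", "strength",
                                            "influence", "query")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  all_stages <- c("prepare", "learn", "strength", "influence", "query")
  upto <- max(match(stages, all_stages))
  stages <- all_stages[seq_len(upto)]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(out, f)
  bundle <- list(config = config, artifacts = character(0))

  # --- prepare ---------------------------------------------------------
  data <- if (is.null(config$input)) {
    stage_log("prepare", "generating synthetic cohort n=%d seed=%d",
              config$cohort$n, config$cohort$seed)
    generate_cohort(config$cohort)
  } else {
    stage_log("prepare", "reading %s", config$input)
    read_dataset_csv(config$input, layers = config$layers)
  }
  split <- train_test_split(data, config$split_fraction,
                            config$seeds$split, config$stratify,
                            config$target)
  balanced <- undersample(split$train, config$target, config$seeds$undersample)
  stage_log("prepare", "train=%d test=%d balanced=%d", nrow(split$train$x),
            nrow(split$test$x), nrow(balanced$x))
  constraints <- layer_blacklist(data$layers)
  bundle$data <- data; bundle$train <- split$train; bundle$test <- split$test
  bundle$balanced <- balanced; bundle$constraints <- constraints
  for (nm in c("train", "test", "balanced")) {
    write_dataset_csv(bundle[[nm]], art(paste0(nm, ".csv")))
    bundle$artifacts <- c(bundle$artifacts, art(paste0(nm, ".csv")))
  }
  write_pipeline_config(config, art("manifest.json"))
  bundle$artifacts <- c(bundle$artifacts, art("manifest.json"))
  if (upto < 2L) return(invisible(bundle))

  # --- learn: replicates, consensus, selection, misclassification ------
  ids <- vapply(config$roster, `[[`, "", "id")
  scores <- list()
  for (i in seq_along(config$roster)) {
    cfg <- config$roster[[i]]
    stage_log("learn", "algorithm %s (B=%d)", cfg$id, config$replicates_B)
    reps <- run_replicates(balanced, cfg, config$replicates_B,
                           derive_seed(config$seeds$replicates, i),
                           constraints,
                           resample = config$replicates_B > 1L)
    scores[[cfg$id]] <- score_algorithm_arcs(reps, config$threshold)
  }
  consensus <- build_consensus(scores, ids)
  write_consensus_csv(consensus, art("consensus.csv"))
  selected <- select_algorithms(consensus, config$k)
  stage_log("learn", "selected: %s", paste(selected, collapse = ", "))

  sel_cfg <- config$roster[match(selected, ids)]
  sel_dags <- lapply(sel_cfg, function(cfg) {
    g <- learn_structure(balanced, cfg, constraints)
    if (is_pdag_object(g)) consistent_extension(g) else g
  })
  rates <- vapply(seq_along(sel_cfg), function(j)
    as.numeric(misclassification_rate(sel_dags[[j]], balanced, split$test,
                                      config$target, config$smoothing,
                                      config$mc_replicates,
                                      derive_seed(config$seeds$replicates,
                                                  1000 + j))), 0)
  mis <- data.frame(algorithm = selected, misclassification = rates,
                    stringsAsFactors = FALSE)
  utils::write.csv(mis, art("misclassification.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(selected = selected,
                            totals = as.list(consensus$totals),
                            best = selected[which.min(rates)]),
                       art("selection.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  best_i <- which.min(rates)           # ties resolve to roster order
  best_cfg <- sel_cfg[[best_i]]
  best_dag <- sel_dags[[best_i]]
  stage_log("learn", "best algorithm: %s (rate %.3f)", best_cfg$id,
            rates[best_i])
  bundle$consensus <- consensus; bundle$selected <- selected
  bundle$misclassification <- mis; bundle$best <- best_cfg$id
  bundle$best_dag <- best_dag
  bundle$artifacts <- c(bundle$artifacts, art("consensus.csv"),
                        art("misclassification.csv"), art("selection.json"))
  if (upto < 3L) return(invisible(bundle))

  # --- strength --------------------------------------------------------
  sdata <- if (config$strength_data == "balanced") balanced else split$train
  m <- min(config$bootstrap_m, nrow(sdata$x))
  stage_log("strength", "bootstrapping %s: R=%d m=%d on %s data",
            best_cfg$id, config$bootstrap_R, m, config$strength_data)
  strengths <- bootstrap_arc_strength(sdata, best_cfg, config$bootstrap_R, m,
                                      config$seeds$bootstrap, constraints)
  utils::write.csv(as.data.frame(strengths), art("arc_strength.csv"),
                   row.names = FALSE, quote = FALSE)
  write_graphml(best_dag, art("network.graphml"), strengths = strengths)
  bundle$strengths <- strengths
  bundle$artifacts <- c(bundle$artifacts, art("arc_strength.csv"),
                        art("network.graphml"))
  if (upto < 4L) return(invisible(bundle))

  # --- influence -------------------------------------------------------
  # arcs of the learned graph that never surfaced in the bootstrap get
  # strength 0 so the ranking is total
  ga <- arcs(best_dag)
  missing <- !(arc_key(ga$from, ga$to) %in%
                 arc_key(strengths$from, strengths$to))
  if (any(missing)) {
    pad <- data.frame(from = ga$from[missing], to = ga$to[missing],
                      strength = 0, stringsAsFactors = FALSE)
    strengths <- structure(rbind(as.data.frame(strengths), pad),
                           R = attr(strengths, "R"), m = attr(strengths, "m"),
                           class = c("arc_strength_table", "data.frame"))
  }
  dwi_tab <- rank_influence(best_dag, strengths, config$target,
                            exclusions = config$dwi_exclusions,
                            w = config$dwi_w)
  utils::write.csv(as.data.frame(dwi_tab), art("dwi.csv"), row.names = FALSE,
                   quote = FALSE)
  bundle$dwi <- dwi_tab
  bundle$artifacts <- c(bundle$artifacts, art("dwi.csv"))
  stage_log("influence", "top nodes: %s",
            paste(utils::head(dwi_tab$node, 3L), collapse = ", "))
  if (upto < 5L) return(invisible(bundle))

  # --- query -----------------------------------------------------------
  # queries run against the original-distribution training data so that
  # conditional probabilities reflect the cohort, not the balanced set
  qcpts <- fit_cpts(best_dag, split$train, config$smoothing)
  glevels <- data$levels[[config$query_group]]
  qlev <- config$query_levels %||% glevels[-1L]
  ref <- setdiff(glevels, qlev)[1L]
  rows <- list(data.frame(event = paste(names(config$query_event),
                                        config$query_event, sep = "="),
                          evidence = paste0(config$query_group, "=", ref),
                          odds_ratio = 1, lower = NA_real_, upper = NA_real_,
                          stringsAsFactors = FALSE))
  for (lv in qlev) {
    or <- odds_ratio(best_dag, qcpts, config$query_event, config$query_group,
                     lv, ref, config$query_n, config$query_replicates,
                     derive_seed(config$seeds$queries, match(lv, glevels)))
    rows[[length(rows) + 1L]] <- data.frame(
      event = paste(names(config$query_event), config$query_event, sep = "="),
      evidence = paste0(config$query_group, "=", lv),
      odds_ratio = or$odds_ratio, lower = or$interval[1L],
      upper = or$interval[2L], stringsAsFactors = FALSE)
  }
  ors <- do.call(rbind, rows)
  utils::write.csv(ors, art("odds_ratios.csv"), row.names = FALSE,
                   quote = FALSE)
  bundle$odds_ratios <- ors
  bundle$artifacts <- c(bundle$artifacts, art("odds_ratios.csv"))
  stage_log("query", "done; %d artifacts under %s",
            length(bundle$artifacts), out)
  invisible(bundle)
}

#' Serialize / restore a pipeline configuration (run manifest)
#'
#' The manifest JSON echoes the full configuration (seeds included) plus
#' the package version; re-running [run_pipeline()] on a manifest path
#' reproduces every artifact byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  listify <- function(x) if (!is.null(names(x)) && !is.list(x)) as.list(x) else x
  payload <- unclass(config)
  payload$cohort <- lapply(unclass(payload$cohort), listify)
  payload$roster <- lapply(payload$roster, unclass)
  payload$layers <- listify(payload$layers)
  payload$query_event <- listify(payload$query_event)
  payload$package_version <- as.character(utils::packageVersion("smmbn"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  roster <- lapply(seq_len(nrow(p$roster)), function(i) {
    x <- as.list(p$roster[i, ])
    x$max_parents <- if (is.null(x$max_parents) || !is.finite(x$max_parents))
      Inf else x$max_parents
    do.call(algorithm_config,
            x[intersect(names(x), names(formals(algorithm_config)))])
  })
  delist <- function(x) if (is.list(x)) unlist(x) else x
  cohort_args <- lapply(p$cohort[intersect(names(p$cohort),
                                           names(formals(cohort_config)))],
                        delist)
  cohort <- do.call(cohort_config, cohort_args)
  pipeline_config(
    input = p$input, cohort = cohort, layers = unlist(p$layers),
    target = p$target, split_fraction = p$split_fraction,
    stratify = isTRUE(p$stratify), seeds = p$seeds, roster = roster,
    threshold = p$threshold, k = p$k, replicates_B = p$replicates_B,
    bootstrap_R = p$bootstrap_R, bootstrap_m = p$bootstrap_m,
    strength_data = p$strength_data, smoothing = p$smoothing,
    mc_replicates = p$mc_replicates, dwi_exclusions = p$dwi_exclusions,
    dwi_w = p$dwi_w, query_group = p$query_group,
    query_event = unlist(p$query_event), query_levels = p$query_levels,
    query_n = p$query_n, query_replicates = p$query_replicates,
    out_dir = p$out_dir)
}

#' Command-line entry point
#'
#' Subcommand interface mirroring [run_pipeline()]:
#' `prepare | learn | strength | influence | query | all`, with flags
#' `--config path.json` (a manifest written by [write_pipeline_config()]),
#' `--out dir`, `--n N`, `--seed S` (synthetic-cohort overrides).
#' Designed for `Rscript -e 'smmbn::pipeline_cli()'` or the installed
#' `inst/cli/smmbn` script.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return Invisibly, the pipeline bundle.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop_config("usage: smmbn <prepare|learn|strength|influence|query|all> [--config c.json] [--out dir] [--n N] [--seed S]")
  cmd <- args[[1L]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop_config("missing value for --%s", key)
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
            else pipeline_config()
  if (!is.null(opts$out)) config$out_dir <- opts$out
  if (!is.null(opts$n)) config$cohort$n <- as.integer(opts$n)
  if (!is.null(opts$seed)) config$cohort$seed <- as.integer(opts$seed)
  stages <- switch(cmd,
    prepare = "prepare", learn = "learn", strength = "strength",
    influence = "influence", query = , all = "query",
    stop_config("unknown subcommand %s", cmd))
  run_pipeline(config, stages = stages)
}
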