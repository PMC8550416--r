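#' Arc constraints and layering blacklists
#'
#' A `constraint_set` holds forbidden (blacklisted) and required
#' (whitelisted) directed arcs.  Every learner honours it: no blacklisted
#' arc ever appears in an output and every whitelisted arc is present.
#' `layer_blacklist()` converts layer tags into the blacklist encoding the
#' layering strategy: a node may not have parents from a higher
#' (more downstream) layer, i.e. every arc `a -> b` with
#' `layer(a) > layer(b)` is forbidden.
#'
#' @param blacklist,whitelist `NULL` or two-column data frames / matrices
#'   of directed arcs `(from, to)`.
#' @return A `constraint_set`.
#' @export
constraint_set <- function(blacklist = NULL, whitelist = NULL) {
  norm <- function(m) {
    if (is.null(m) || NROW(m) == 0L)
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    m <- as.data.frame(as.matrix(m), stringsAsFactors = FALSE)
    names(m) <- c("from", "to")
    unique(m)
  }
  bl <- norm(blacklist); wl <- norm(whitelist)
  if (nrow(merge(bl, wl)) > 0L)
    stop_config("whitelist and blacklist overlap")
  if (nrow(wl)) {
    nodes <- unique(c(wl$from, wl$to))
    g <- try(dag(nodes, as.matrix(wl)), silent = TRUE)
    if (inherits(g, "try-error"))
      stop_config("whitelisted arcs must be mutually acyclic")
  }
  structure(list(blacklist = bl, whitelist = wl), class = "constraint_set")
}

#' @rdname constraint_set
#' @param layers named non-negative integer vector of layer tags
#'   (0 = most upstream).
#' @export
layer_blacklist <- function(layers) {
  vars <- names(layers)
  grid <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to &
                 layers[grid$from] > layers[grid$to], , drop = FALSE]
  rownames(grid) <- NULL
  constraint_set(blacklist = grid)
}

## Fast lookup matrices for a constraint set over a node vector.
constraint_matrices <- function(constraints, nodes) {
  p <- length(nodes)
  bl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  cs <- constraints %||% constraint_set()
  b <- cs$blacklist[cs$blacklist$from %in% nodes & cs$blacklist$to %in% nodes, ]
  w <- cs$whitelist
  if (nrow(w) && !all(w$from %in% nodes & w$to %in% nodes))
    stop_config("whitelisted arc endpoints missing from the data")
  if (nrow(b)) bl[cbind(b$from, b$to)] <- TRUE
  if (nrow(w)) wl[cbind(w$from, w$to)] <- TRUE
  if (any(bl & wl)) stop_config("whitelist and blacklist overlap")
  list(bl = bl, wl = wl)
}

#' Structure-learning algorithm configurations
#'
#' Bundles the knobs of one learning run: the algorithm id, the score
#' (score-based and hybrid maximization), the conditional-independence
#' test level, tabu parameters, the conditioning-set cap and the seed.
#' `default_roster()` returns the eleven-configuration ensemble used by
#' the consensus procedure: HC and tabu under BIC and AIC, the four
#' Markov-blanket constraint algorithms, MMHC, and two generic
#' restrict-maximize hybrids.
#'
#' @param algorithm one of `"hc"`, `"tabu"`, `"gs"`, `"iamb"`,
#'   `"fast-iamb"`, `"inter-iamb"`, `"mmhc"`, `"rsmax2"`.
#' @param score `"bic"`, `"aic"` or `"loglik"` (score-based / hybrid).
#' @param test currently `"g2"`.
#' @param alpha test level in (0, 1).
#' @param tabu_len tabu-list length (tabu search).
#' @param max_noimprove bound on consecutive non-improving tabu steps.
#' @param max_sx maximum conditioning-set size for subset searches.
#' @param max_parents cap on parent-set size in score search.
#' @param restrict skeleton producer for `rsmax2`: `"mmpc"` or `"iamb"`.
#' @param maximize `"hc"` or `"tabu"` for hybrid maximization.
#' @param guard logical, the `N >= 5 df` test-reliability heuristic.
#' @param id optional label; defaults to a descriptive one.
#' @param seed integer seed recorded with the configuration.
#' @return An `algorithm_config`.
#' @export
algorithm_config <- function(algorithm, score = "bic", test = "g2",
                             alpha = 0.05, tabu_len = 10L,
                             max_noimprove = 20L, max_sx = 3L,
                             max_parents = Inf, restrict = "mmpc",
                             maximize = "hc", guard = TRUE, id = NULL,
                             seed = 1L) {
  algorithm <- match.arg(algorithm,
    c("hc", "tabu", "gs", "iamb", "fast-iamb", "inter-iamb", "mmhc", "rsmax2"))
  score <- match.arg(score, c("bic", "aic", "loglik"))
  test <- match.arg(test, "g2")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must be in (0, 1)")
  family <- switch(algorithm,
    hc = , tabu = "score-based",
    gs = , iamb = , `fast-iamb` = , `inter-iamb` = "constraint-based",
    "hybrid")
  if (is.null(id)) {
    id <- switch(family,
      "score-based" = paste(algorithm, score, sep = "-"),
      "constraint-based" = algorithm,
      if (algorithm == "mmhc") "mmhc" else paste("rsmax2", restrict, sep = "-"))
  }
  structure(list(algorithm = algorithm, family = family, score = score,
                 test = test, alpha = alpha, tabu_len = as.integer(tabu_len),
                 max_noimprove = as.integer(max_noimprove),
                 max_sx = as.integer(max_sx), max_parents = max_parents,
                 restrict = match.arg(restrict, c("mmpc", "iamb")),
                 maximize = match.arg(maximize, c("hc", "tabu")),
                 guard = isTRUE(guard), id = id, seed = as.integer(seed)),
            class = "algorithm_config")
}

#' @rdname algorithm_config
#' @param alpha_roster alpha applied to every roster member.
#' @export
default_roster <- function(alpha_roster = 0.05) {
  list(
    algorithm_config("hc",   score = "bic", id = "hc-bic"),
    algorithm_config("hc",   score = "aic", id = "hc-aic"),
    algorithm_config("tabu", score = "bic", id = "tabu-bic"),
    algorithm_config("tabu", score = "aic", id = "tabu-aic"),
    algorithm_config("gs", alpha = alpha_roster),
    algorithm_config("iamb", alpha = alpha_roster),
    algorithm_config("fast-iamb", alpha = alpha_roster),
    algorithm_config("inter-iamb", alpha = alpha_roster),
    algorithm_config("mmhc", score = "bic", alpha = alpha_roster),
    algorithm_config("rsmax2", restrict = "iamb", maximize = "hc",
                     score = "bic", alpha = alpha_roster, id = "rsmax2-iamb"),
    algorithm_config("rsmax2", restrict = "mmpc", maximize = "tabu",
                     score = "bic", alpha = alpha_roster, id = "rsmax2-mmpc")
  )
}

#' Serialize / restore an algorithm configuration as JSON
#'
#' @param config an `algorithm_config` (or list of them).
#' @param path file path.
#' @return `read_algorithm_config()` returns the restored object(s).
#' @export
write_algorithm_config <- function(config, path) {
  payload <- if (inherits(config, "algorithm_config")) unclass(config)
             else lapply(config, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_algorithm_config
#' @export
read_algorithm_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore <- function(x) {
    x$max_parents <- if (is.null(x$max_parents) ||
                         !is.finite(suppressWarnings(as.numeric(x$max_parents))))
      Inf else as.numeric(x$max_parents)
    do.call(algorithm_config,
            x[intersect(names(x), names(formals(algorithm_config)))])
  }
  if (is.data.frame(payload)) {
    lapply(seq_len(nrow(payload)), function(i) restore(as.list(payload[i, ])))
  } else if (!is.null(payload$algorithm)) restore(payload)
  else lapply(payload, restore)
}
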