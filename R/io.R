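#' Compact model-string representation
#'
#' `model_string()` renders a DAG as `[A][B|A][C|A:B]` (each node followed
#' by its colon-separated parents), listing nodes in the deterministic
#' topological order; `parse_model_string()` inverts it.  The format
#' round-trips structures as plain text.
#'
#' @param g an `smm_dag`.
#' @param s a model string.
#' @return `model_string()`: character scalar; `parse_model_string()`:
#'   an `smm_dag`.
#' @export
model_string <- function(g) {
  ord <- topological_order(g)
  paste(vapply(ord, function(v) {
    pa <- sort(parents(g, v))
    if (length(pa)) sprintf("[%s|%s]", v, paste(pa, collapse = ":"))
    else sprintf("[%s]", v)
  }, ""), collapse = "")
}

#' @rdname model_string
#' @export
parse_model_string <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    stop_contract("model string must be a single character value")
  toks <- regmatches(s, gregexpr("\\[[^]]+\\]", s))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(gsub("\\s", "", s)))
    stop_contract("malformed model string: %s", s)
  nodes <- character(0); arcs <- list()
  for (tk in toks) {
    body <- substr(tk, 2L, nchar(tk) - 1L)
    parts <- strsplit(body, "|", fixed = TRUE)[[1L]]
    v <- parts[1L]
    nodes <- c(nodes, v)
    if (length(parts) > 1L) {
      for (pa in strsplit(parts[2L], ":", fixed = TRUE)[[1L]])
        arcs[[length(arcs) + 1L]] <- c(pa, v)
    }
  }
  dag(nodes, if (length(arcs)) do.call(rbind, arcs) else NULL)
}

#' GraphML export / import
#'
#' Writes a DAG or PDAG as GraphML (undirected PDAG edges carry
#' `directed="false"`), optionally attaching an arc-strength table as a
#' `weight` edge attribute; `read_graphml()` restores structures written
#' by this package.
#'
#' @param g an `smm_dag` or `smm_pdag`.
#' @param path file path.
#' @param strengths optional `arc_strength_table` attached as edge
#'   weights.
#' @return `read_graphml()`: an `smm_dag` (or `smm_pdag` when undirected
#'   edges are present).
#' @export
write_graphml <- function(g, path, strengths = NULL) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  if (!is.null(strengths)) {
    key <- xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                               attr.name = "weight", attr.type = "double")
    invisible(key)
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (v in g$nodes) xml2::xml_add_child(graph, "node", id = v)
  a <- arcs(g)
  add_edge <- function(from, to, directed) {
    e <- xml2::xml_add_child(graph, "edge", source = from, target = to)
    if (!directed) xml2::xml_set_attr(e, "directed", "false")
    if (!is.null(strengths)) {
      d <- xml2::xml_add_child(e, "data", key = "weight")
      xml2::xml_set_text(d, format(strength_of(strengths, from, to),
                                   digits = 15))
    }
  }
  if (nrow(a)) for (k in seq_len(nrow(a))) add_edge(a$from[k], a$to[k], TRUE)
  u <- undirected_edges(g)
  if (nrow(u)) for (k in seq_len(nrow(u))) add_edge(u$from[k], u$to[k], FALSE)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//node"), "id")
  edges <- xml2::xml_find_all(doc, ".//edge")
  from <- xml2::xml_attr(edges, "source")
  to <- xml2::xml_attr(edges, "target")
  und <- !is.na(xml2::xml_attr(edges, "directed")) &
    xml2::xml_attr(edges, "directed") == "false"
  if (any(und)) {
    pdag(nodes, arcs = cbind(from[!und], to[!und]),
         undirected = cbind(from[und], to[und]))
  } else {
    dag(nodes, arcs = if (length(from)) cbind(from, to) else NULL)
  }
}

#' DOT export / import
#'
#' Writes Graphviz DOT text (`a -> b;` for arcs, `a -- b [dir=none];` for
#' undirected PDAG edges); `read_dot()` parses files written by this
#' package.
#'
#' @inheritParams write_graphml
#' @export
write_dot <- function(g, path) {
  a <- arcs(g); u <- undirected_edges(g)
  lines <- c("digraph G {",
             sprintf("  \"%s\";", g$nodes),
             if (nrow(a)) sprintf("  \"%s\" -> \"%s\";", a$from, a$to),
             if (nrow(u)) sprintf("  \"%s\" -> \"%s\" [dir=none];", u$from, u$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dot
#' @export
read_dot <- function(path) {
  lines <- readLines(path)
  nodes <- character(0); arcs <- list(); und <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    m <- regmatches(ln, regexec('^"([^"]+)" -> "([^"]+)"( \\[dir=none\\])?;$', ln))[[1L]]
    if (length(m)) {
      if (nchar(m[4L])) und[[length(und) + 1L]] <- m[2:3]
      else arcs[[length(arcs) + 1L]] <- m[2:3]
      nodes <- union(nodes, m[2:3])
      next
    }
    m <- regmatches(ln, regexec('^"([^"]+)";$', ln))[[1L]]
    if (length(m)) nodes <- union(nodes, m[2L])
  }
  if (length(und))
    pdag(nodes, arcs = if (length(arcs)) do.call(rbind, arcs) else NULL,
         undirected = do.call(rbind, und))
  else dag(nodes, arcs = if (length(arcs)) do.call(rbind, arcs) else NULL)
}
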