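#' Bundle a graph or tree with its annotations for export
#'
#' @param x a [rooted_digraph()] or [dominator_tree()].
#' @param annotations annotation map from [annotate_nodes()] (may be `NULL`).
#' @param unreachable identifiers excluded from a tree (defaults to the
#'   tree's own `unreachable` component, or the digraph's attribute).
#' @param provenance named list recording root label, filter settings and
#'   input file names; written into every export.
#' @return object of class `export_bundle`.
#' @export
export_bundle <- function(x, annotations = NULL, unreachable = NULL,
                          provenance = list()) {
  if (inherits(x, "dominator_tree")) {
    nodes <- x$reachable
    edges <- dominator_tree_edges(x)
    labels <- x$labels[nodes]
    if (is.null(unreachable)) unreachable <- x$unreachable
    kind <- "tree"
  } else if (inherits(x, "rooted_digraph")) {
    nodes <- x$nodes
    edges <- x$edges
    labels <- x$labels
    if (is.null(unreachable)) unreachable <- attr(x, "unreachable") %||% character(0)
    kind <- "graph"
  } else {
    stop_pathdom("x must be a rooted_digraph or dominator_tree",
                 "pathdom_input_error")
  }
  extra <- setdiff(names(annotations), c(nodes, unreachable))
  if (length(extra) > 0L)
    stop_pathdom(paste0("annotated node(s) absent from the structure: ",
                        paste(extra, collapse = ", ")),
                 "pathdom_input_error")
  structure(
    list(kind = kind, root = x$root, nodes = nodes, edges = edges,
         labels = labels, annotations = annotations,
         unreachable = unreachable, provenance = provenance),
    class = "export_bundle"
  )
}

node_attrs <- function(bundle, v) {
  a <- bundle$annotations[[v]]
  list(
    label = unname(bundle$labels[v]) %||% v,
    frequency = if (is.null(a)) 0 else a$frequency,
    colour = if (is.null(a)) "none" else as.character(a$colour),
    role = if (is.null(a)) "neither" else a$role,
    is_complex = if (is.null(a)) FALSE else isTRUE(a$is_complex)
  )
}

#' Export an annotated graph or tree to a file
#'
#' Supported formats: `graphml` (GraphML with typed node attribute keys),
#' `dot` (Graphviz; complexes drawn with `shape=box`, mutated nodes filled
#' with their annotation colour) and `json` (a node-link structure with
#' fields `directed`, `kind`, `root`, `nodes[{id,label,frequency,colour,
#' role,is_complex}]`, `links[{source,target}]`, `unreachable`,
#' `provenance`; re-readable with [import_graph_json()]).
#'
#' @param bundle an [export_bundle()].
#' @param path output file path.
#' @param format one of `"graphml"`, `"dot"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(bundle, path, format = c("graphml", "dot", "json")) {
  stopifnot(inherits(bundle, "export_bundle"))
  if (length(format) != 1L || !(format %in% c("graphml", "dot", "json")))
    stop_pathdom(paste0("unknown export format '",
                        paste(format, collapse = ","), "'"),
                 "pathdom_usage_error")
  txt <- switch(format,
    graphml = render_graphml(bundle),
    dot = render_dot(bundle),
    json = render_json(bundle)
  )
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

render_graphml <- function(b) {
  keys <- c(
    '  <key id="d_label" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="d_frequency" for="node" attr.name="frequency" attr.type="double"/>',
    '  <key id="d_colour" for="node" attr.name="colour" attr.type="string"/>',
    '  <key id="d_role" for="node" attr.name="role" attr.type="string"/>',
    '  <key id="d_is_complex" for="node" attr.name="is_complex" attr.type="boolean"/>'
  )
  node_xml <- vapply(b$nodes, function(v) {
    a <- node_attrs(b, v)
    paste0('    <node id="', xml_escape(v), '">\n',
           '      <data key="d_label">', xml_escape(a$label), '</data>\n',
           '      <data key="d_frequency">', format(a$frequency, digits = 15),
           '</data>\n',
           '      <data key="d_colour">', xml_escape(a$colour), '</data>\n',
           '      <data key="d_role">', xml_escape(a$role), '</data>\n',
           '      <data key="d_is_complex">', tolower(a$is_complex),
           '</data>\n    </node>')
  }, character(1))
  edge_xml <- if (nrow(b$edges) > 0L)
    paste0('    <edge source="', xml_escape(b$edges[, 1L]),
           '" target="', xml_escape(b$edges[, 2L]), '"/>')
  else character(0)
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    '  <graph edgedefault="directed">',
    node_xml, edge_xml,
    '  </graph>', '</graphml>')
}

render_dot <- function(b) {
  pal <- c(red = "#e41a1c", blue = "#377eb8", grey = "#bdbdbd")
  node_lines <- vapply(b$nodes, function(v) {
    a <- node_attrs(b, v)
    attrs <- c(
      paste0('label="', dot_escape(a$label), '"'),
      if (a$is_complex) 'shape=box' else 'shape=ellipse',
      paste0('frequency="', format(a$frequency, digits = 15), '"'),
      paste0('role="', a$role, '"'),
      paste0('colour="', a$colour, '"'),
      if (a$colour %in% names(pal))
        c('style=filled', paste0('fillcolor="', pal[[a$colour]], '"'))
    )
    paste0('  "', dot_escape(v), '" [', paste(attrs, collapse = ", "), '];')
  }, character(1))
  edge_lines <- if (nrow(b$edges) > 0L)
    paste0('  "', dot_escape(b$edges[, 1L]), '" -> "',
           dot_escape(b$edges[, 2L]), '";')
  else character(0)
  c(paste0("digraph ", b$kind, " {"),
    '  rankdir=TB;',
    node_lines, edge_lines, "}")
}

render_json <- function(b) {
  nodes <- lapply(b$nodes, function(v) {
    a <- node_attrs(b, v)
    list(id = v, label = a$label, frequency = a$frequency,
         colour = a$colour, role = a$role, is_complex = a$is_complex)
  })
  links <- if (nrow(b$edges) > 0L)
    lapply(seq_len(nrow(b$edges)), function(i)
      list(source = b$edges[i, 1L], target = b$edges[i, 2L]))
  else list()
  obj <- list(directed = TRUE, kind = b$kind, root = b$root,
              nodes = nodes, links = links,
              unreachable = as.list(b$unreachable),
              provenance = b$provenance)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Re-read a node-link JSON export
#'
#' Inverse of [export_graph()] with `format = "json"`: reconstructs the
#' node set, edge set, per-node attributes, unreachable list and provenance
#' from the file.
#'
#' @param path path to a JSON file written by [export_graph()].
#' @return list with components `kind`, `root`, `nodes` (data frame of node
#'   attributes), `edges` (two-column character matrix), `unreachable`,
#'   `provenance`.
#' @export
import_graph_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  edges <- if (length(obj$links) > 0L)
    cbind(from = obj$links$source, to = obj$links$target)
  else matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to")))
  list(kind = obj$kind, root = obj$root, nodes = obj$nodes, edges = edges,
       unreachable = unlist(obj$unreachable) %||% character(0),
       provenance = obj$provenance)
}

#' Write a plain-text positional-importance report
#'
#' Summarises a dominator-tree bundle for reading without a graph viewer:
#' the root, reachable/excluded counts, the top mutated genes by frequency,
#' and a positional table giving each mutated node's depth in the dominator
#' tree and its number of descendants — the nodes it completely controls.
#' A mutated node with many descendants is a candidate master regulator
#' even at low mutation frequency; a mutated leaf is positionally
#' unimportant (a passenger candidate).
#'
#' @param bundle an [export_bundle()] built from a [dominator_tree()].
#' @param path output file path.
#' @param tree the `dominator_tree` the bundle was built from (used for
#'   depth/descendant computation); required for the positional table.
#' @param top number of genes in the top-mutated table.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path, tree = NULL, top = 15L) {
  stopifnot(inherits(bundle, "export_bundle"))
  lines <- c(
    "Pathway dominator analysis report",
    "=================================",
    paste0("Root: ", unname(bundle$labels[bundle$root]) %||% bundle$root,
           " (", bundle$root, ")"),
    paste0("Reachable nodes: ", length(bundle$nodes)),
    paste0("Excluded (unreachable) nodes: ", length(bundle$unreachable))
  )
  if (length(bundle$provenance) > 0L) {
    lines <- c(lines, "", "Provenance:")
    for (k in names(bundle$provenance))
      lines <- c(lines, paste0("  ", k, ": ",
                               paste(unlist(bundle$provenance[[k]]),
                                     collapse = ", ")))
  }

  ann <- bundle$annotations
  mutated <- names(ann)[vapply(ann, function(a) isTRUE(a$mutated), logical(1))]
  mutated <- intersect(mutated, bundle$nodes)
  lines <- c(lines, "", paste0("Mutated nodes: ", length(mutated)))
  if (length(mutated) > 0L) {
    freqs <- vapply(ann[mutated], `[[`, numeric(1), "frequency")
    ord <- order(-freqs, mutated)
    lines <- c(lines, "", "Top mutated genes by frequency:")
    for (i in utils::head(ord, top)) {
      v <- mutated[i]
      lines <- c(lines, sprintf("  %-20s freq=%.4f role=%s",
                                ann[[v]]$label, freqs[i], ann[[v]]$role))
    }
  }

  if (!is.null(tree)) {
    depth <- tree_depths(tree)
    desc <- tree_descendant_counts(tree)
    lines <- c(lines, "", "Positional importance (mutated nodes, ranked by",
               "frequency then by number of dominated descendants):")
    if (length(mutated) > 0L) {
      freqs <- vapply(ann[mutated], `[[`, numeric(1), "frequency")
      ord <- order(-freqs, -desc[mutated], mutated)
      for (i in ord) {
        v <- mutated[i]
        lines <- c(lines, sprintf("  %-20s freq=%.4f depth=%d descendants=%d",
                                  ann[[v]]$label, freqs[i], depth[[v]],
                                  desc[[v]]))
      }
    } else {
      lines <- c(lines, sprintf("  %-20s depth=0 descendants=%d (root)",
                                unname(bundle$labels[bundle$root]) %||% bundle$root,
                                if (length(desc)) desc[[tree$root]] else 0L))
    }
  }

  if (length(bundle$unreachable) > 0L) {
    lines <- c(lines, "", "Excluded from the tree (no directed path from root):")
    lines <- c(lines, paste0("  ", bundle$unreachable))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
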