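#' Rooted directed graphs
#'
#' A `rooted_digraph` is a directed graph with a designated root node, the
#' entry point of the signal in a pathway.  Nodes are opaque string
#' identifiers with optional display labels; edges are ordered pairs.
#' Duplicate edges are merged (edge-set semantics).  Self-loops are kept in
#' storage but ignored by the dominator computation, where they can never
#' change the result.
#'
#' @param nodes character vector of node identifiers (unique, non-empty).
#' @param edges two-column character matrix or data frame of (from, to)
#'   pairs; may have zero rows.
#' @param root node identifier of the signal entry point; must be a node.
#' @param labels optional named character vector of display labels, named by
#'   node identifier; defaults to the identifiers themselves.
#' @return an object of class `rooted_digraph` with components `nodes`,
#'   `edges` (deduplicated two-column character matrix), `root` and `labels`.
#' @examples
#' g <- rooted_digraph(c("R", "A", "B"),
#'                     rbind(c("R", "A"), c("A", "B")), root = "R")
#' reachable_set(g)
#' @export
rooted_digraph <- function(nodes, edges, root, labels = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L || anyNA(nodes) || any(!nzchar(nodes)))
    stop_pathdom("nodes must be a non-empty vector of non-empty strings",
                 "pathdom_input_error")
  if (anyDuplicated(nodes))
    stop_pathdom("duplicate node identifiers", "pathdom_input_error")
  edges <- as_edge_matrix(edges)
  bad <- setdiff(c(edges), nodes)
  if (length(bad) > 0L)
    stop_pathdom(paste0("edge endpoint(s) not in node set: ",
                        paste(sort(bad), collapse = ", ")),
                 "pathdom_input_error")
  if (length(root) != 1L || !(root %in% nodes))
    stop_pathdom(paste0("root '", root, "' is not a node of the graph"),
                 "pathdom_root_error")
  if (is.null(labels)) labels <- stats::setNames(nodes, nodes)
  labels <- labels[nodes]
  labels[is.na(labels)] <- nodes[is.na(labels)]
  names(labels) <- nodes
  # canonical order: nodes and edges sorted lexicographically
  nodes <- sort(nodes)
  if (nrow(edges) > 0L) {
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(
    list(nodes = nodes, edges = edges, root = as.character(root),
         labels = labels[nodes]),
    class = "rooted_digraph"
  )
}

as_edge_matrix <- function(edges) {
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(0), ncol = 2L)
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop_pathdom("edges must be a two-column matrix of (from, to) pairs",
                 "pathdom_input_error")
  mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

#' @export
print.rooted_digraph <- function(x, ...) {
  cat("Rooted digraph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges; root:", node_label(x, x$root), "\n")
  invisible(x)
}

node_label <- function(g, v) unname(g$labels[v])

# successor adjacency in lexicographic order (self-loops/parallels dropped)
successor_list <- function(g) {
  succ <- lapply(stats::setNames(nm = g$nodes), function(v) character(0))
  if (nrow(g$edges) > 0L) {
    e <- g$edges[g$edges[, 1L] != g$edges[, 2L], , drop = FALSE]
    if (nrow(e) > 0L) {
      sp <- split(e[, 2L], factor(e[, 1L], levels = g$nodes))
      for (v in names(sp)) succ[[v]] <- sort(unique(sp[[v]]))
    }
  }
  succ
}

bfs_from <- function(succ, start) {
  seen <- stats::setNames(logical(length(succ)), names(succ))
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nxt <- succ[[v]]
    nxt <- nxt[!seen[nxt]]
    if (length(nxt) > 0L) {
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  names(seen)[seen]
}

#' Nodes reachable from the root
#'
#' Returns the set of nodes that can be reached from the root by a directed
#' path (the root itself included).  Domination is only defined on this set.
#'
#' @param graph a [rooted_digraph()].
#' @return character vector of reachable node identifiers, sorted.
#' @export
reachable_set <- function(graph) {
  stopifnot(inherits(graph, "rooted_digraph"))
  sort(bfs_from(successor_list(graph), graph$root))
}

#' Test domination by exhaustive path blocking
#'
#' `u` dominates `v` when every directed path from the root to `v` passes
#' through `u`: in a signalling pathway, every signal reaching `v` must be
#' relayed through `u`.  This is the brute-force definition, evaluated by
#' deleting `u` and asking whether `v` is still reachable; it serves as the
#' ground-truth oracle for the fast algorithm in [dominator_tree()].  The
#' reflexive convention is used: every node dominates itself.
#'
#' @param graph a [rooted_digraph()].
#' @param u,v node identifiers, both reachable from the root.
#' @return `TRUE` or `FALSE`.
#' @export
dominates <- function(graph, u, v) {
  stopifnot(inherits(graph, "rooted_digraph"))
  reach <- reachable_set(graph)
  if (!(u %in% reach) || !(v %in% reach))
    stop_pathdom("domination is undefined for nodes unreachable from the root",
                 "pathdom_input_error")
  if (u == v) return(TRUE)
  if (u == graph$root) return(TRUE)
  succ <- successor_list(graph)
  succ[[u]] <- character(0)                    # delete u's outgoing edges
  succ <- lapply(succ, function(s) s[s != u])  # and its incoming edges
  !(v %in% bfs_from(succ, graph$root))
}

#' Dominator tree of a rooted digraph
#'
#' Computes the immediate dominator of every node reachable from the root
#' using the Lengauer-Tarjan semidominator algorithm (simple LINK/EVAL
#' variant with path compression, O(m log n)).  The immediate (least)
#' dominator of `v` is the dominator of `v` closest to `v` other than `v`
#' itself; the parent map of all immediate dominators forms the unique
#' dominator tree, in which `u` is an ancestor of `v` exactly when `u`
#' dominates `v` in the graph.
#'
#' Nodes with no directed path from the root have undefined dominators; they
#' are excluded from the tree and listed in the `unreachable` component
#' (real pathways routinely contain ligands upstream of the chosen root).
#' Ties in the depth-first numbering are fixed by iterating successors in
#' lexicographic node-identifier order, so the output is deterministic.
#'
#' @param graph a [rooted_digraph()].
#' @return an object of class `dominator_tree` with components:
#'   \describe{
#'     \item{root}{the root identifier}
#'     \item{idom}{named character vector mapping every non-root reachable
#'       node to its immediate dominator}
#'     \item{reachable}{sorted identifiers of nodes reachable from the root}
#'     \item{unreachable}{sorted identifiers excluded from the tree}
#'     \item{labels}{display labels for all graph nodes}
#'   }
#' @examples
#' g <- rooted_digraph(c("R", "A", "B", "C"),
#'                     rbind(c("R", "A"), c("R", "B"), c("A", "C"), c("B", "C")),
#'                     root = "R")
#' dt <- dominator_tree(g)
#' dt$idom[["C"]]  # "R": two disjoint paths reach C
#' @export
dominator_tree <- function(graph) {
  stopifnot(inherits(graph, "rooted_digraph"))
  succ <- successor_list(graph)
  root <- graph$root

  ## iterative DFS preorder numbering, successors in lexicographic order
  n_all <- length(graph$nodes)
  dfn <- stats::setNames(integer(n_all), graph$nodes)  # 0 = unvisited
  vertex <- character(n_all)
  parent_nm <- stats::setNames(character(n_all), graph$nodes)
  count <- 0L
  stack <- list(c(root, NA_character_))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[[1L]]
    if (dfn[[v]] != 0L) next
    count <- count + 1L
    dfn[[v]] <- count
    vertex[[count]] <- v
    parent_nm[[v]] <- top[[2L]]
    kids <- succ[[v]]
    kids <- kids[dfn[kids] == 0L]
    for (w in rev(kids)) stack[[length(stack) + 1L]] <- c(w, v)
  }
  k <- count
  reachable <- sort(vertex[seq_len(k)])
  unreachable <- setdiff(graph$nodes, reachable)

  idom_nm <- stats::setNames(character(0), character(0))
  if (k > 1L) {
    ## everything below works in DFS numbers 1..k
    parent <- integer(k)
    for (i in 2:k) parent[i] <- dfn[[parent_nm[[vertex[i]]]]]
    pred <- vector("list", k)
    if (nrow(graph$edges) > 0L) {
      e <- graph$edges[graph$edges[, 1L] != graph$edges[, 2L], , drop = FALSE]
      keep <- dfn[e[, 1L]] > 0L & dfn[e[, 2L]] > 0L
      e <- e[keep, , drop = FALSE]
      if (nrow(e) > 0L) {
        from_i <- unname(dfn[e[, 1L]])
        to_i <- unname(dfn[e[, 2L]])
        for (j in seq_along(to_i))
          pred[[to_i[j]]] <- c(pred[[to_i[j]]], from_i[j])
      }
    }

    semi <- seq_len(k)
    idom <- integer(k)
    ancestor <- integer(k)          # 0 = none (forest root)
    label <- seq_len(k)
    bucket <- vector("list", k)

    compress <- function(v) {
      path <- integer(0)
      while (ancestor[ancestor[v]] != 0L) {
        path <- c(path, v)
        v <- ancestor[v]
      }
      for (u in rev(path)) {
        a <- ancestor[u]
        if (semi[label[a]] < semi[label[u]]) label[u] <<- label[a]
        ancestor[u] <<- ancestor[a]
      }
    }
    eval_lt <- function(v) {
      if (ancestor[v] == 0L) return(v)
      compress(v)
      label[v]
    }

    for (w in k:2) {
      for (v in pred[[w]]) {
        u <- eval_lt(v)
        if (semi[u] < semi[w]) semi[w] <- semi[u]
      }
      bucket[[semi[w]]] <- c(bucket[[semi[w]]], w)
      ancestor[w] <- parent[w]                      # LINK (simple variant)
      p <- parent[w]
      for (v in bucket[[p]]) {
        u <- eval_lt(v)
        idom[v] <- if (semi[u] < semi[v]) u else p
      }
      bucket[p] <- list(NULL)
    }
    for (w in 2:k)
      if (idom[w] != semi[w]) idom[w] <- idom[idom[w]]

    non_root <- vertex[2:k]
    idom_nm <- stats::setNames(vertex[idom[2:k]], non_root)
    idom_nm <- idom_nm[order(names(idom_nm))]
  }

  structure(
    list(root = root, idom = idom_nm, reachable = reachable,
         unreachable = unreachable, labels = graph$labels),
    class = "dominator_tree"
  )
}

#' Edges of a dominator tree
#'
#' Returns the parent-to-child edges `(idom(y), y)` for every non-root
#' reachable node `y`.  A valid tree always has exactly
#' `length(tree$reachable) - 1` edges.
#'
#' @param tree a [dominator_tree()].
#' @return two-column character matrix of (from, to) pairs.
#' @export
dominator_tree_edges <- function(tree) {
  stopifnot(inherits(tree, "dominator_tree"))
  if (length(tree$idom) == 0L) return(matrix(character(0), ncol = 2L,
                                             dimnames = list(NULL, c("from", "to"))))
  cbind(from = unname(tree$idom), to = names(tree$idom))
}

#' Ancestors of a node in the dominator tree
#'
#' The ancestors of `v` (excluding `v` itself) are exactly the strict
#' dominators of `v` in the underlying graph.
#'
#' @param tree a [dominator_tree()].
#' @param v a reachable node identifier.
#' @return character vector from immediate dominator up to the root.
#' @export
tree_ancestors <- function(tree, v) {
  stopifnot(inherits(tree, "dominator_tree"))
  if (!(v %in% tree$reachable))
    stop_pathdom(paste0("node '", v, "' is not in the dominator tree"),
                 "pathdom_input_error")
  anc <- character(0)
  while (v != tree$root) {
    v <- tree$idom[[v]]
    anc <- c(anc, v)
  }
  anc
}

# depth of every reachable node (root = 0)
tree_depths <- function(tree) {
  depth <- stats::setNames(integer(length(tree$reachable)), tree$reachable)
  kids <- split(names(tree$idom), factor(unname(tree$idom), levels = tree$reachable))
  queue <- tree$root
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    ch <- kids[[v]]
    if (length(ch) > 0L) {
      depth[ch] <- depth[[v]] + 1L
      queue <- c(queue, ch)
    }
  }
  depth
}

# number of proper descendants of every reachable node
tree_descendant_counts <- function(tree) {
  depth <- tree_depths(tree)
  counts <- stats::setNames(integer(length(tree$reachable)), tree$reachable)
  for (v in names(tree$idom)) {
    a <- v
    while (a != tree$root) {
      a <- tree$idom[[a]]
      counts[[a]] <- counts[[a]] + 1L
    }
  }
  counts
}

#' @export
print.dominator_tree <- function(x, ...) {
  cat("Dominator tree rooted at", node_label(x, x$root) %||% x$root, "\n")
  cat("  reachable nodes: ", length(x$reachable),
      "; tree edges: ", length(x$idom), "\n", sep = "")
  if (length(x$unreachable) > 0L)
    cat("  excluded (unreachable from root):",
        paste(x$unreachable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dominator_tree <- function(object, ...) {
  depth <- tree_depths(object)
  desc <- tree_descendant_counts(object)
  out <- list(
    root = object$root,
    n_reachable = length(object$reachable),
    n_unreachable = length(object$unreachable),
    max_depth = if (length(depth)) max(depth) else 0L,
    table = data.frame(
      node = names(depth),
      label = unname(object$labels[names(depth)]),
      depth = unname(depth),
      descendants = unname(desc[names(depth)]),
      stringsAsFactors = FALSE
    )
  )
  out$table <- out$table[order(-out$table$descendants, out$table$node), ]
  rownames(out$table) <- NULL
  class(out) <- "summary.dominator_tree"
  out
}

#' @export
print.summary.dominator_tree <- function(x, ...) {
  cat("Dominator tree summary\n")
  cat("  root:", x$root, "| reachable:", x$n_reachable,
      "| excluded:", x$n_unreachable, "| max depth:", x$max_depth, "\n")
  print(utils::head(x$table, 10L))
  invisible(x)
}

#' @export
as.data.frame.dominator_tree <- function(x, ...) {
  depth <- tree_depths(x)
  desc <- tree_descendant_counts(x)
  data.frame(
    node = x$reachable,
    label = unname(x$labels[x$reachable]),
    idom = vapply(x$reachable, function(v)
      if (v == x$root) NA_character_ else x$idom[[v]], character(1)),
    depth = unname(depth[x$reachable]),
    descendants = unname(desc[x$reachable]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Plot a dominator tree
#'
#' Simple layered base-graphics drawing: depth on the vertical axis, siblings
#' spread horizontally.  Node fill colours follow the annotation colours if
#' supplied.
#'
#' @param x a [dominator_tree()].
#' @param annotations optional annotation map from [annotate_nodes()] used to
#'   colour nodes.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dominator_tree <- function(x, annotations = NULL, ...) {
  depth <- tree_depths(x)
  ord <- order(depth, names(depth))
  xs <- stats::setNames(numeric(length(depth)), names(depth))
  for (d in sort(unique(depth))) {
    at <- names(depth)[depth == d]
    xs[at] <- seq_along(at) / (length(at) + 1)
  }
  fill <- stats::setNames(rep("white", length(depth)), names(depth))
  if (!is.null(annotations)) {
    pal <- c(red = "#e41a1c", blue = "#377eb8", grey = "#999999", none = "white")
    for (v in names(depth)) {
      a <- annotations[[v]]
      if (!is.null(a) && !is.null(a$colour) && a$colour %in% names(pal))
        fill[[v]] <- pal[[a$colour]]
    }
  }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(max(depth) + 0.5, -0.5),
                 axes = FALSE, xlab = "", ylab = "depth", ...)
  for (v in names(x$idom)) {
    p <- x$idom[[v]]
    graphics::segments(xs[[p]], depth[[p]], xs[[v]], depth[[v]], col = "grey50")
  }
  graphics::points(xs, depth, pch = 21, bg = fill[names(depth)], cex = 2.2)
  graphics::text(xs, depth, labels = x$labels[names(depth)], pos = 3,
                 cex = 0.7, offset = 0.6)
  invisible(x)
}

#' Immediate dominators reconstructed from the brute-force oracle
#'
#' For every reachable non-root node, computes its full strict dominator set
#' with [dominates()] (by node removal) and picks the one closest to the
#' node, i.e. the strict dominator dominated by all the others.  Exists as an
#' independent check of [dominator_tree()]; quadratic, only suitable for
#' small graphs.
#'
#' @param graph a [rooted_digraph()].
#' @return named character vector mapping each non-root reachable node to its
#'   immediate dominator, names sorted.
#' @export
idom_by_oracle <- function(graph) {
  stopifnot(inherits(graph, "rooted_digraph"))
  reach <- reachable_set(graph)
  succ <- successor_list(graph)
  root <- graph$root
  ## removal reachability: nodes still reachable when u is deleted
  keeps <- lapply(stats::setNames(nm = reach), function(u) {
    if (u == root) return(character(0))
    s <- succ
    s[[u]] <- character(0)
    s <- lapply(s, function(x) x[x != u])
    bfs_from(s, root)
  })
  dominator_sets <- lapply(stats::setNames(nm = reach), function(v) {
    strict <- reach[vapply(reach, function(u)
      u != v && (u == root || !(v %in% keeps[[u]])), logical(1))]
    strict
  })
  non_root <- setdiff(reach, root)
  idom <- vapply(non_root, function(v) {
    doms <- dominator_sets[[v]]
    # the immediate dominator is the strict dominator with the largest
    # strict-dominator set (dominators of v form a chain)
    sizes <- vapply(doms, function(d) length(dominator_sets[[d]]), integer(1))
    doms[[which.max(sizes)]]
  }, character(1))
  idom[order(names(idom))]
}
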