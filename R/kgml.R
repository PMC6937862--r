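#' Parse a KEGG KGML pathway file
#'
#' Reads a pathway in KEGG Markup Language (KGML, the XML dialect behind
#' KEGG pathway maps) and captures its \code{entry} and \code{relation}
#' elements.  Entries of type \code{map} (links to other pathways) are kept
#' as metadata but never become graph nodes; \code{maplink} relations are
#' likewise excluded from the computable graph.  The display label of an
#' entry is the text of its first \code{graphics} \code{name} attribute up
#' to the first comma; the full comma-separated list is retained as the
#' entry's gene symbols.
#'
#' @param path path to a KGML (XML) file.
#' @return an object of class `pathway_graph` with components:
#'   \describe{
#'     \item{entries}{named list of entry records (`entry_id`, `entry_type`,
#'       `names`, `label`, `genes`, `components`)}
#'     \item{relations}{data frame with columns `source`, `target`,
#'       `relation_type` and `subtypes` (list column of subtype names)}
#'     \item{collapsed}{`FALSE` until [collapse_groups()] is applied}
#'     \item{title}{the pathway title attribute, if present}
#'   }
#' @export
parse_kgml <- function(path) {
  if (!file.exists(path))
    stop_pathdom(paste0("KGML file not found: ", path), "pathdom_input_error")
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_pathdom(paste0("malformed XML in ", path, ": ", conditionMessage(e)),
                 "pathdom_format_error"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    stop_pathdom("not a KGML document: missing <pathway> root element",
                 "pathdom_format_error")

  entry_nodes <- xml2::xml_find_all(root, "./entry")
  entries <- list()
  for (en in entry_nodes) {
    id <- xml2::xml_attr(en, "id")
    type <- xml2::xml_attr(en, "type")
    if (is.na(id))
      stop_pathdom("entry without id attribute", "pathdom_format_error")
    if (id %in% names(entries))
      stop_pathdom(paste0("duplicate entry id '", id, "'"),
                   "pathdom_format_error")
    kegg_names <- strsplit(xml2::xml_attr(en, "name") %||% "", " +")[[1]]
    gname <- xml2::xml_attr(xml2::xml_find_first(en, "./graphics"), "name")
    genes <- if (!is.na(gname) && nzchar(gname))
      trimws(strsplit(gname, ",")[[1]]) else character(0)
    label <- if (length(genes) > 0L) genes[[1L]] else
      if (length(kegg_names) > 0L) kegg_names[[1L]] else id
    comp <- xml2::xml_attr(xml2::xml_find_all(en, "./component"), "id")
    entries[[id]] <- list(
      entry_id = id,
      entry_type = if (is.na(type)) "other" else type,
      names = kegg_names,
      label = label,
      genes = genes,
      components = comp
    )
  }

  rel_nodes <- xml2::xml_find_all(root, "./relation")
  relations <- data.frame(
    source = xml2::xml_attr(rel_nodes, "entry1"),
    target = xml2::xml_attr(rel_nodes, "entry2"),
    relation_type = xml2::xml_attr(rel_nodes, "type"),
    stringsAsFactors = FALSE
  )
  relations$subtypes <- lapply(rel_nodes, function(rn)
    xml2::xml_attr(xml2::xml_find_all(rn, "./subtype"), "name"))
  bad <- setdiff(c(relations$source, relations$target), names(entries))
  if (length(bad) > 0L)
    stop_pathdom(paste0("relation endpoint(s) reference unknown entries: ",
                        paste(sort(unique(bad)), collapse = ", ")),
                 "pathdom_format_error")

  structure(
    list(entries = entries, relations = relations, collapsed = FALSE,
         title = xml2::xml_attr(root, "title")),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  types <- table(vapply(x$entries, `[[`, character(1), "entry_type"))
  cat("Pathway graph", if (!is.na(x$title %||% NA)) paste0("'", x$title, "'"),
      "\n  entries:", length(x$entries),
      paste0("(", paste(names(types), types, sep = ":", collapse = ", "), ")"),
      "\n  relations:", nrow(x$relations),
      if (x$collapsed) "\n  complexes collapsed" else "", "\n")
  invisible(x)
}

# transitive component -> enclosing top-level group map
group_membership <- function(entries) {
  owner <- character(0)
  for (e in entries) {
    if (e$entry_type == "group") {
      miss <- setdiff(e$components, names(entries))
      if (length(miss) > 0L)
        stop_pathdom(paste0("group '", e$entry_id,
                            "' references missing component id(s): ",
                            paste(miss, collapse = ", ")),
                     "pathdom_format_error")
      owner[e$components] <- e$entry_id
    }
  }
  # resolve nesting: follow ownership up to a group that is not itself owned
  resolve <- function(id) {
    while (id %in% names(owner)) id <- owner[[id]]
    id
  }
  stats::setNames(vapply(names(owner), resolve, character(1)), names(owner))
}

#' Collapse protein complexes into single nodes
#'
#' KGML represents protein complexes as \code{group} entries whose
#' \code{component} children are the member entries.  Complexes act as one
#' signalling unit, so each group becomes a single node: edges incident to
#' any member are re-attached to the group node, duplicates created by the
#' re-attachment are merged, and member entries stop being standalone nodes.
#' Nested groups are flattened transitively.  The operation is idempotent.
#'
#' @param pg a `pathway_graph` from [parse_kgml()].
#' @return the collapsed `pathway_graph`, with a `node_meta` component: for
#'   each graph-candidate node, its `label`, member gene symbols `genes`,
#'   and `is_complex` flag.
#' @export
collapse_groups <- function(pg) {
  stopifnot(inherits(pg, "pathway_graph"))
  owner <- group_membership(pg$entries)
  members <- names(owner)

  rel <- pg$relations
  if (nrow(rel) > 0L) {
    map_id <- function(id) if (id %in% members) owner[[id]] else id
    rel$source <- vapply(rel$source, map_id, character(1))
    rel$target <- vapply(rel$target, map_id, character(1))
    # merge duplicates created by re-attachment (subtypes unioned)
    key <- paste(rel$source, rel$target, rel$relation_type, sep = "\r")
    if (anyDuplicated(key)) {
      split_sub <- split(rel$subtypes, key)
      first <- !duplicated(key)
      merged <- rel[first, , drop = FALSE]
      merged$subtypes <- lapply(key[first], function(k)
        sort(unique(unlist(split_sub[[k]]))))
      rel <- merged
    }
    rownames(rel) <- NULL
  }

  entries <- pg$entries
  top_groups <- setdiff(unique(unname(owner)), members)
  node_meta <- list()
  for (id in names(entries)) {
    e <- entries[[id]]
    if (id %in% members) next            # absorbed into a complex
    if (e$entry_type == "map") next      # cross-pathway link, metadata only
    if (e$entry_type == "group") {
      # union of member gene symbols, transitively
      all_members <- names(owner)[unname(owner) == id]
      genes <- sort(unique(unlist(lapply(entries[all_members], `[[`, "genes"))))
      label <- if (length(genes) > 0L)
        paste0("[", paste(genes, collapse = "+"), "]") else paste0("[group ", id, "]")
      node_meta[[id]] <- list(label = label, genes = genes, is_complex = TRUE)
    } else {
      node_meta[[id]] <- list(label = e$label, genes = toupper(e$genes),
                              is_complex = FALSE)
    }
  }

  pg$relations <- rel
  pg$node_meta <- node_meta
  pg$collapsed <- TRUE
  pg
}

#' Designate the signal entry point and orient the graph
#'
#' Selects a node (a stimulus or receptor) as the root of the pathway and
#' builds the rooted digraph over which dominators are computed.  Edges
#' follow the relation direction source to target — the direction the signal
#' flows.  Relations carrying a \code{binding/association} subtype describe
#' complex formation with no inherent direction, so they contribute edges in
#' both directions.  Inhibition and activation are not distinguished: both
#' become identical directed edges.
#'
#' Nodes without a directed path from the chosen root are reported in the
#' `unreachable` attribute of the result, not treated as an error.
#'
#' @param pg a collapsed `pathway_graph` (see [collapse_groups()]).
#' @param root_label_or_id string matching exactly one node, by entry id or
#'   by case-insensitive display label.
#' @return a [rooted_digraph()] whose node identifiers are KGML entry ids;
#'   attributes: `unreachable` (identifiers with no directed path from the
#'   root) and `node_meta` (carried over from the pathway graph).
#' @export
set_root <- function(pg, root_label_or_id) {
  stopifnot(inherits(pg, "pathway_graph"))
  if (!isTRUE(pg$collapsed))
    stop_pathdom("collapse_groups() must be applied before set_root()",
                 "pathdom_input_error")
  ids <- names(pg$node_meta)
  labels <- vapply(pg$node_meta, `[[`, character(1), "label")
  hit <- ids[ids == root_label_or_id |
               tolower(labels) == tolower(root_label_or_id)]
  if (length(hit) == 0L)
    stop_pathdom(paste0("unknown root '", root_label_or_id,
                        "'; candidates: ",
                        paste(sort(unique(labels)), collapse = ", ")),
                 "pathdom_root_error")
  if (length(hit) > 1L)
    stop_pathdom(paste0("ambiguous root '", root_label_or_id,
                        "' matches entries: ", paste(hit, collapse = ", ")),
                 "pathdom_root_error")

  rel <- pg$relations
  edges <- matrix(character(0), ncol = 2L)
  if (nrow(rel) > 0L) {
    keep <- rel$relation_type != "maplink" &
      rel$source %in% ids & rel$target %in% ids
    rel <- rel[keep, , drop = FALSE]
    if (nrow(rel) > 0L) {
      fwd <- cbind(rel$source, rel$target)
      bidir <- vapply(rel$subtypes, function(s)
        any(s == "binding/association", na.rm = TRUE), logical(1))
      edges <- rbind(fwd, cbind(rel$target[bidir], rel$source[bidir]))
    }
  }
  g <- rooted_digraph(ids, edges, root = hit,
                      labels = stats::setNames(labels, ids))
  attr(g, "unreachable") <- setdiff(ids, reachable_set(g))
  attr(g, "node_meta") <- pg$node_meta
  g
}
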