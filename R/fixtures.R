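#' Generate a random rooted digraph
#'
#' Erdos-Renyi-style directed edges over `n` nodes plus a guaranteed
#' spanning arborescence from the root, so every node is reachable.  Fully
#' deterministic given `(n, p, seed)`; the caller's RNG state is left
#' untouched.
#'
#' @param n number of nodes (>= 1).
#' @param p probability of each ordered non-self pair being an extra edge.
#' @param seed integer seed.
#' @return a [rooted_digraph()] with nodes `n01..`, root `n01`; the
#'   `manifest` attribute records the seed and exact edge list.
#' @export
generate_random_rooted_digraph <- function(n, p, seed) {
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop_pathdom("n must be a positive integer", "pathdom_usage_error")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_pathdom("p must be a probability in [0, 1]", "pathdom_usage_error")
  n <- as.integer(n)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- with_seed(seed, {
    span <- if (n > 1L)
      cbind(ids[vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))],
            ids[2:n])
    else matrix(character(0), ncol = 2L)
    extra <- if (n > 1L) {
      pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      pick <- stats::runif(nrow(pairs)) < p
      as.matrix(pairs[pick, , drop = FALSE])
    } else matrix(character(0), ncol = 2L)
    rbind(span, extra)
  })
  g <- rooted_digraph(ids, edges, root = ids[[1L]])
  attr(g, "manifest") <- list(seed = seed, n = n, p = p,
                              edges = g$edges, root = ids[[1L]])
  g
}

#' Toy pathway with a feedback loop controlled only by the root
#'
#' Ten nodes R and A-I.  Two branches leave the root R and enter the
#' two-node feedback cycle between F and H at distinct nodes:
#' R-A-B-F and R-C-D-H, with F and H activating each other, and a short
#' tail H-G-I plus F-E downstream of the cycle.  Because the cycle can be
#' entered from either branch, no node on a branch dominates F or H: only R
#' completely controls them, while every other non-root node has a unique
#' immediate dominator on its own branch.
#'
#' @return a [rooted_digraph()] rooted at `"R"`.
#' @export
generate_fig1_fixture <- function() {
  edges <- rbind(
    c("R", "A"), c("A", "B"), c("B", "F"),
    c("R", "C"), c("C", "D"), c("D", "H"),
    c("F", "H"), c("H", "F"),
    c("F", "E"),
    c("H", "G"), c("G", "I")
  )
  rooted_digraph(c("R", LETTERS[1:9]), edges, root = "R")
}

#' Assemble a KGML fixture manifest
#'
#' A manifest fully describes a KGML file to be written by
#' [write_kgml_fixture()] and doubles as the oracle for parser tests: its
#' `counts` component states the entry/relation/group numbers a correct
#' parse must reproduce.
#'
#' @param entries list of entry records: `id`, `type`, `name` (KEGG ids),
#'   `graphics_name` (comma-separated symbols), optional `components`.
#' @param relations list of relation records: `entry1`, `entry2`, `type`,
#'   optional `subtypes` character vector.
#' @param title pathway title attribute.
#' @return list of class `kgml_manifest` with `entries`, `relations`,
#'   `title` and `counts`.
#' @export
kgml_manifest <- function(entries, relations, title = "synthetic pathway") {
  n_groups <- sum(vapply(entries, function(e)
    identical(e$type, "group"), logical(1)))
  n_map <- sum(vapply(entries, function(e)
    identical(e$type, "map"), logical(1)))
  component_ids <- unique(unlist(lapply(entries, function(e) e$components)))
  structure(
    list(entries = entries, relations = relations, title = title,
         counts = list(
           n_entries = length(entries),
           n_relations = length(relations),
           n_groups = n_groups,
           n_map = n_map,
           # nodes after collapse: non-map, non-component entries
           n_nodes_collapsed = sum(vapply(entries, function(e)
             !identical(e$type, "map") &&
               !(e$id %in% component_ids), logical(1)))
         )),
    class = "kgml_manifest"
  )
}

#' Generate a random KGML manifest
#'
#' Seed-deterministic pathway skeleton: `n_genes` gene entries (symbols
#' `GS01..`), `n_groups` two-member complexes over the first genes, one
#' `map` entry, and `n_relations` distinct relations between random
#' entries with random subtypes.
#'
#' @param n_genes number of gene entries.
#' @param n_relations number of relation elements.
#' @param n_groups number of two-member group entries (components are taken
#'   from the gene entries, disjointly).
#' @param seed integer seed.
#' @return a [kgml_manifest()].
#' @export
generate_kgml_manifest <- function(n_genes = 8L, n_relations = 10L,
                                   n_groups = 1L, seed = 1L) {
  if (2L * n_groups > n_genes)
    stop_pathdom("not enough genes to form the requested groups",
                 "pathdom_usage_error")
  with_seed(seed, {
    gene_ids <- as.character(seq_len(n_genes))
    entries <- lapply(seq_len(n_genes), function(i) list(
      id = gene_ids[[i]], type = "gene",
      name = sprintf("hsa:%d", 1000L + i),
      graphics_name = sprintf("GS%02d, ALT%02d", i, i)
    ))
    next_id <- n_genes
    for (k in seq_len(n_groups)) {
      next_id <- next_id + 1L
      entries[[next_id]] <- list(
        id = as.character(next_id), type = "group", name = "undefined",
        graphics_name = "",
        components = gene_ids[c(2L * k - 1L, 2L * k)]
      )
    }
    next_id <- next_id + 1L
    entries[[next_id]] <- list(
      id = as.character(next_id), type = "map", name = "path:hsa00000",
      graphics_name = "Other pathway"
    )
    all_ids <- vapply(entries, `[[`, character(1), "id")
    non_map <- all_ids[vapply(entries, function(e) e$type != "map", logical(1))]
    pool <- expand.grid(entry1 = non_map, entry2 = non_map,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$entry1 != pool$entry2, , drop = FALSE]
    pick <- pool[sample.int(nrow(pool), min(n_relations, nrow(pool))), ,
                 drop = FALSE]
    subtype_pool <- c("activation", "inhibition", "phosphorylation",
                      "expression", "binding/association")
    relations <- lapply(seq_len(nrow(pick)), function(i) list(
      entry1 = pick$entry1[[i]], entry2 = pick$entry2[[i]], type = "PPrel",
      subtypes = sample(subtype_pool, 1L)
    ))
    kgml_manifest(entries, relations,
                  title = sprintf("synthetic pathway seed %d", seed))
  })
}

#' Write a KGML file from a manifest
#'
#' Emits well-formed KGML consumable by [parse_kgml()]; entry and relation
#' counts match the manifest exactly, and output bytes are a pure function
#' of the manifest.
#'
#' @param manifest a [kgml_manifest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kgml_fixture <- function(manifest, path) {
  stopifnot(inherits(manifest, "kgml_manifest"))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<pathway name="path:synthetic" org="syn" number="00001" title="',
           xml_escape(manifest$title), '">')
  )
  for (e in manifest$entries) {
    lines <- c(lines, paste0(
      '  <entry id="', xml_escape(e$id), '" name="', xml_escape(e$name),
      '" type="', xml_escape(e$type), '">'))
    if (!is.null(e$graphics_name) && nzchar(e$graphics_name))
      lines <- c(lines, paste0(
        '    <graphics name="', xml_escape(e$graphics_name),
        '" type="rectangle"/>'))
    for (cid in e$components)
      lines <- c(lines, paste0('    <component id="', xml_escape(cid), '"/>'))
    lines <- c(lines, '  </entry>')
  }
  for (r in manifest$relations) {
    lines <- c(lines, paste0(
      '  <relation entry1="', xml_escape(r$entry1), '" entry2="',
      xml_escape(r$entry2), '" type="', xml_escape(r$type), '">'))
    for (s in r$subtypes)
      lines <- c(lines, paste0('    <subtype name="', xml_escape(s),
                               '" value="--&gt;"/>'))
    lines <- c(lines, '  </relation>')
  }
  lines <- c(lines, '</pathway>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Synthetic receptor-kinase cascade pathway manifest
#'
#' A deliberately synthetic ~40-node pathway shaped like a growth-factor
#' signalling cascade: a ligand-receptor spine feeding a lipid-kinase
#' complex, a second-messenger node and a central kinase; side branches to
#' a MAPK-like cascade and to downstream effector fan-outs (apoptosis,
#' cell-cycle, translation modules); one two-member complex; and a deep
#' feedback edge from a downstream kinase back to an upstream adaptor
#' substrate.  All symbols carry a `SYN` prefix: this is NOT a real KEGG
#' pathway, only a realistically shaped stand-in for exercising the full
#' pipeline.
#'
#' @return a [kgml_manifest()]; the root for tree analysis is the ligand
#'   `SYNGF1`.
#' @export
generate_cascade_fixture <- function() {
  sym <- c(
    "SYNGF1",                                  # 1 ligand (root)
    "SYNRTK1",                                 # 2 receptor
    "SYNIRS1",                                 # 3 adaptor substrate (feedback target)
    "SYNGRB1", "SYNSOS1", "SYNRAS1",           # 4-6 MAPK-like branch head
    "SYNPI3KA", "SYNPI3KB",                    # 7-8 complex members
    "SYNPIP3",                                 # 9 second messenger (compound)
    "SYNPDK1", "SYNAKT1",                      # 10-11 central kinases
    "SYNMTOR1", "SYNS6K1",                     # 12-13 downstream kinase pair
    "SYNRAF1", "SYNMEK1", "SYNERK1",           # 14-16 MAPK-like cascade
    "SYNGSK3", "SYNFOXO1", "SYNBAD1",          # 17-19 AKT effectors
    "SYNCCND1", "SYNCDK4", "SYNRB1",           # 20-22 cell-cycle module
    "SYNNFKB1", "SYNIKK1",                     # 23-24 NF-kB-like module
    "SYNTP53", "SYNMDM21",                     # 25-26 p53-like module
    "SYNEIF4B", "SYNEIF4E", "SYNRPS6",         # 27-29 translation module
    "SYNCASP9", "SYNBCL2",                     # 30-31 apoptosis module
    "SYNMYC1", "SYNJUN1", "SYNFOS1",           # 32-34 TF fan-out
    "SYNPTEN",                                 # 35 antagonist of PIP3 signal
    "SYNPKCA", "SYNPLCG1",                     # 36-37 side branch
    "SYNSTAT3", "SYNJAK1",                     # 38-39 side branch
    "SYNJNK1"                                  # 40
  )
  id_of <- stats::setNames(as.character(seq_along(sym)), sym)
  gene_entry <- function(s) list(
    id = id_of[[s]], type = if (s == "SYNPIP3") "compound" else "gene",
    name = if (s == "SYNPIP3") "cpd:C05981" else
      sprintf("hsa:%d", 2000L + match(s, sym)),
    graphics_name = s
  )
  entries <- lapply(sym, gene_entry)
  grp_id <- as.character(length(sym) + 1L)
  entries[[length(entries) + 1L]] <- list(
    id = grp_id, type = "group", name = "undefined", graphics_name = "",
    components = id_of[c("SYNPI3KA", "SYNPI3KB")]
  )
  r <- function(a, b, sub = "activation") list(
    entry1 = if (a == "PI3K") grp_id else id_of[[a]],
    entry2 = if (b == "PI3K") grp_id else id_of[[b]],
    type = "PPrel", subtypes = sub)
  relations <- list(
    r("SYNGF1", "SYNRTK1"),
    r("SYNRTK1", "SYNIRS1"), r("SYNRTK1", "SYNGRB1"), r("SYNRTK1", "SYNPLCG1"),
    r("SYNRTK1", "SYNJAK1"),
    r("SYNIRS1", "PI3K"),
    r("SYNGRB1", "SYNSOS1"), r("SYNSOS1", "SYNRAS1"),
    r("SYNRAS1", "SYNRAF1"), r("SYNRAS1", "PI3K"),
    r("SYNRAF1", "SYNMEK1"), r("SYNMEK1", "SYNERK1"),
    r("SYNERK1", "SYNMYC1"), r("SYNERK1", "SYNFOS1"), r("SYNERK1", "SYNJUN1"),
    r("PI3K", "SYNPIP3"),
    r("SYNPTEN", "SYNPIP3", "inhibition"),
    r("SYNPIP3", "SYNPDK1"), r("SYNPIP3", "SYNAKT1"),
    r("SYNPDK1", "SYNAKT1"), r("SYNPDK1", "SYNS6K1"),
    r("SYNAKT1", "SYNMTOR1"), r("SYNMTOR1", "SYNS6K1"),
    r("SYNS6K1", "SYNIRS1", "inhibition"),      # deep feedback loop
    r("SYNS6K1", "SYNRPS6"), r("SYNS6K1", "SYNEIF4B"),
    r("SYNMTOR1", "SYNEIF4E"),
    r("SYNAKT1", "SYNGSK3", "inhibition"), r("SYNAKT1", "SYNFOXO1", "inhibition"),
    r("SYNAKT1", "SYNBAD1", "inhibition"), r("SYNAKT1", "SYNMDM21"),
    r("SYNAKT1", "SYNIKK1"), r("SYNIKK1", "SYNNFKB1"),
    r("SYNMDM21", "SYNTP53", "inhibition"),
    r("SYNGSK3", "SYNCCND1", "inhibition"),
    r("SYNCCND1", "SYNCDK4"), r("SYNCDK4", "SYNRB1", "inhibition"),
    r("SYNBAD1", "SYNBCL2", "inhibition"), r("SYNBCL2", "SYNCASP9", "inhibition"),
    r("SYNPLCG1", "SYNPKCA"), r("SYNPKCA", "SYNJNK1"),
    r("SYNJAK1", "SYNSTAT3")
  )
  kgml_manifest(entries, relations, title = "synthetic cascade pathway")
}

#' Generate a synthetic mutation table
#'
#' Writes a TSV of mutation records for `genes` across samples `s001..`
#' such that each gene is mutated in exactly `round(rate * n_samples)`
#' seed-deterministically chosen samples; the manifest records the exact
#' mutated-sample sets, so expected frequencies are exact rather than
#' statistical.  Samples not hit by any gene receive one record for the
#' control gene `SYNCTRL` so that the table's distinct-sample count always
#' equals `n_samples`.
#'
#' @param genes character vector of gene symbols.
#' @param n_samples number of samples.
#' @param per_gene_rates numeric vector of target mutation rates in [0, 1],
#'   recycled against `genes`.
#' @param seed integer seed.
#' @param path output TSV path.
#' @param dataset dataset label written to every record.
#' @param mutation_types pool of type labels assigned round-robin.
#' @return invisibly, the manifest: list with `samples`, per-gene
#'   `mutated_samples` sets, `expected_frequency`, and `path`.
#' @export
generate_mutation_fixture <- function(genes, n_samples, per_gene_rates, seed,
                                      path,
                                      dataset = "synthetic",
                                      mutation_types = c("missense", "nonsense",
                                                         "frameshift", "silent")) {
  if (any(per_gene_rates < 0 | per_gene_rates > 1))
    stop_pathdom("rates must lie in [0, 1]", "pathdom_usage_error")
  rates <- rep_len(per_gene_rates, length(genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  sets <- with_seed(seed, {
    out <- lapply(seq_along(genes), function(i) {
      k <- round(rates[[i]] * n_samples)
      if (k > 0L) sort(sample(samples, k)) else character(0)
    })
    stats::setNames(out, toupper(genes))
  })
  rows <- data.frame(gene = character(0), sample = character(0),
                     mutation_type = character(0), dataset = character(0),
                     stringsAsFactors = FALSE)
  for (g in names(sets)) {
    ss <- sets[[g]]
    if (length(ss) > 0L)
      rows <- rbind(rows, data.frame(
        gene = g, sample = ss,
        mutation_type = mutation_types[(seq_along(ss) - 1L) %%
                                         length(mutation_types) + 1L],
        dataset = dataset, stringsAsFactors = FALSE))
  }
  uncovered <- setdiff(samples, unique(rows$sample))
  if (length(uncovered) > 0L)
    rows <- rbind(rows, data.frame(
      gene = "SYNCTRL", sample = uncovered, mutation_type = "silent",
      dataset = dataset, stringsAsFactors = FALSE))
  rows <- rows[order(rows$gene, rows$sample), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(
    seed = seed, samples = samples, mutated_samples = sets,
    expected_frequency = vapply(sets, length, integer(1)) / n_samples,
    control_gene = "SYNCTRL", path = path
  ))
}

#' Write a gene-role TSV
#'
#' @param roles named character vector gene -> role (`oncogene`,
#'   `tumour_suppressor` or `neither`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_role_fixture <- function(roles, path) {
  bad <- is.na(normalise_role(roles))
  if (any(bad))
    stop_pathdom(paste0("unknown role value(s): ",
                        paste(unique(roles[bad]), collapse = ", ")),
                 "pathdom_usage_error")
  utils::write.table(
    data.frame(gene = names(roles), role = unname(roles)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
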