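test_that("parse_kgml reproduces the fixture manifest counts", {
  man <- make_small_manifest()
  path <- write_tmp_kgml(man)
  pg <- parse_kgml(path)
  expect_s3_class(pg, "pathway_graph")
  expect_length(pg$entries, man$counts$n_entries)
  expect_equal(nrow(pg$relations), man$counts$n_relations)
  # 6 non-map entries are graph candidates
  non_map <- sum(vapply(pg$entries, function(e)
    e$entry_type != "map", logical(1)))
  expect_equal(non_map, 6L)
  # labels: graphics name up to the first comma
  expect_equal(pg$entries[["1"]]$label, "G1")
  expect_equal(pg$entries[["1"]]$genes, c("G1", "G1ALT"))
})

test_that("parse_kgml handles empty relation lists and map entries", {
  man <- kgml_manifest(
    entries = list(
      list(id = "1", type = "gene", name = "hsa:1", graphics_name = "AAA"),
      list(id = "2", type = "map", name = "path:x", graphics_name = "Other")
    ),
    relations = list()
  )
  pg <- parse_kgml(write_tmp_kgml(man))
  expect_equal(nrow(pg$relations), 0L)
  expect_length(pg$entries, 2L)         # map entry retained as metadata
  cg <- collapse_groups(pg)
  expect_named(cg$node_meta, "1")       # but excluded from graph nodes
})

test_that("parse_kgml rejects malformed input", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry id='1'", bad)
  expect_error(parse_kgml(bad), "malformed")
  notkgml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notes><x/></notes>", notkgml)
  expect_error(parse_kgml(notkgml), "pathway")
  expect_error(parse_kgml("no/such/file.xml"), "not found")
})

test_that("collapse_groups re-attaches, deduplicates, and flattens nested groups", {
  man <- make_small_manifest()
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(man)))
  expect_true(pg$collapsed)
  # components 1,2 absorbed into group 6
  expect_false(any(c("1", "2") %in% names(pg$node_meta)))
  expect_true(pg$node_meta[["6"]]$is_complex)
  expect_setequal(pg$node_meta[["6"]]$genes, c("G1", "G1ALT", "G2", "G2ALT"))
  # relation 3->1 became 3->6
  expect_true(any(pg$relations$source == "3" & pg$relations$target == "6"))

  # dedup: X->A and X->B with {A,B} grouped gives a single relation
  man2 <- kgml_manifest(
    entries = list(
      list(id = "1", type = "gene", name = "hsa:1", graphics_name = "A"),
      list(id = "2", type = "gene", name = "hsa:2", graphics_name = "B"),
      list(id = "3", type = "gene", name = "hsa:3", graphics_name = "X"),
      list(id = "4", type = "group", name = "undefined", graphics_name = "",
           components = c("1", "2"))
    ),
    relations = list(
      list(entry1 = "3", entry2 = "1", type = "PPrel", subtypes = "activation"),
      list(entry1 = "3", entry2 = "2", type = "PPrel", subtypes = "activation")
    )
  )
  pg2 <- collapse_groups(parse_kgml(write_tmp_kgml(man2)))
  expect_equal(nrow(pg2$relations), 1L)
  expect_equal(pg2$relations$source, "3")
  expect_equal(pg2$relations$target, "4")

  # nested groups flatten transitively
  man3 <- kgml_manifest(
    entries = list(
      list(id = "1", type = "gene", name = "hsa:1", graphics_name = "A"),
      list(id = "2", type = "gene", name = "hsa:2", graphics_name = "B"),
      list(id = "3", type = "gene", name = "hsa:3", graphics_name = "C"),
      list(id = "4", type = "group", name = "undefined", graphics_name = "",
           components = c("1", "2")),
      list(id = "5", type = "group", name = "undefined", graphics_name = "",
           components = c("4", "3")),
      list(id = "6", type = "gene", name = "hsa:6", graphics_name = "X")
    ),
    relations = list(
      list(entry1 = "6", entry2 = "1", type = "PPrel", subtypes = "activation")
    )
  )
  pg3 <- collapse_groups(parse_kgml(write_tmp_kgml(man3)))
  expect_setequal(names(pg3$node_meta), c("5", "6"))
  expect_setequal(pg3$node_meta[["5"]]$genes, c("A", "B", "C"))
  expect_equal(pg3$relations$target, "5")
})

test_that("collapse_groups is idempotent and errors on missing components", {
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(make_small_manifest())))
  pg2 <- collapse_groups(pg)
  expect_identical(pg2$node_meta, pg$node_meta)
  expect_identical(pg2$relations, pg$relations)

  man <- kgml_manifest(
    entries = list(
      list(id = "1", type = "group", name = "undefined", graphics_name = "",
           components = c("99"))
    ),
    relations = list()
  )
  expect_error(collapse_groups(parse_kgml(write_tmp_kgml(man))), "99")
})

test_that("every non-maplink relation between retained nodes yields an edge", {
  man <- generate_kgml_manifest(n_genes = 10, n_relations = 14, n_groups = 2,
                                seed = 31)
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(man)))
  g <- set_root(pg, names(pg$node_meta)[[1]])
  for (i in seq_len(nrow(pg$relations))) {
    r <- pg$relations[i, ]
    if (r$relation_type == "maplink") next
    if (!(r$source %in% names(pg$node_meta)) ||
        !(r$target %in% names(pg$node_meta))) next
    if (r$source == r$target) next  # self-loop after collapse may be dropped
    expect_true(any(g$edges[, 1] == r$source & g$edges[, 2] == r$target),
                label = sprintf("edge for relation %s->%s", r$source, r$target))
  }
})

test_that("set_root resolves labels, reports unreachable nodes, errors on bad roots", {
  man <- make_small_manifest()
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(man)))
  g <- set_root(pg, "g3")  # case-insensitive label match
  expect_equal(g$root, "3")
  # relation 4->3 carries binding/association: both directions present
  expect_true(any(g$edges[, 1] == "4" & g$edges[, 2] == "3"))
  expect_true(any(g$edges[, 1] == "3" & g$edges[, 2] == "4"))
  expect_type(attr(g, "unreachable"), "character")
  expect_error(set_root(pg, "NOPE"), "unknown root")

  # ambiguity: two entries sharing a label
  man2 <- kgml_manifest(
    entries = list(
      list(id = "1", type = "gene", name = "hsa:1", graphics_name = "DUP"),
      list(id = "2", type = "gene", name = "hsa:2", graphics_name = "DUP")
    ),
    relations = list(
      list(entry1 = "1", entry2 = "2", type = "PPrel", subtypes = "activation")
    )
  )
  pg2 <- collapse_groups(parse_kgml(write_tmp_kgml(man2)))
  expect_error(set_root(pg2, "dup"), "ambiguous")
  expect_error(set_root(parse_kgml(write_tmp_kgml(man2)), "dup"),
               "collapse_groups")
})

test_that("generated manifests round-trip through write + parse", {
  for (seed in c(1, 8, 21)) {
    man <- generate_kgml_manifest(n_genes = 8, n_relations = 10, n_groups = 1,
                                  seed = seed)
    pg <- parse_kgml(write_tmp_kgml(man))
    expect_length(pg$entries, man$counts$n_entries)
    expect_equal(nrow(pg$relations), man$counts$n_relations)
    cg <- collapse_groups(pg)
    expect_length(cg$node_meta, man$counts$n_nodes_collapsed)
  }
})
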