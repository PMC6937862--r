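# shared fixtures built in code

make_chain <- function(ids = c("R", "A", "B")) {
  edges <- cbind(ids[-length(ids)], ids[-1])
  rooted_digraph(ids, edges, root = ids[[1]])
}

make_diamond <- function() {
  rooted_digraph(c("R", "A", "B", "C"),
                 rbind(c("R", "A"), c("R", "B"), c("A", "C"), c("B", "C")),
                 root = "R")
}

# small KGML manifest matching the layout used in parser tests:
# 5 gene entries, 1 group of 2 components, 5 relations
make_small_manifest <- function() {
  entries <- c(
    lapply(1:5, function(i) list(
      id = as.character(i), type = "gene",
      name = sprintf("hsa:%d", 100 + i),
      graphics_name = sprintf("G%d, G%dALT", i, i)
    )),
    list(list(id = "6", type = "group", name = "undefined",
              graphics_name = "", components = c("1", "2")))
  )
  relations <- list(
    list(entry1 = "3", entry2 = "1", type = "PPrel", subtypes = "activation"),
    list(entry1 = "2", entry2 = "4", type = "PPrel", subtypes = "activation"),
    list(entry1 = "4", entry2 = "5", type = "PPrel", subtypes = "inhibition"),
    list(entry1 = "3", entry2 = "4", type = "PPrel", subtypes = "phosphorylation"),
    list(entry1 = "4", entry2 = "3", type = "PPrel",
         subtypes = "binding/association")
  )
  kgml_manifest(entries, relations)
}

write_tmp_kgml <- function(manifest, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pathway.xml")
  write_kgml_fixture(manifest, path)
  path
}

# ancestry check used by the property tests: is u an ancestor of v in tree?
is_tree_ancestor <- function(tree, u, v) u %in% tree_ancestors(tree, v)
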