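write_tmp_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "mut.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

ten_row_table <- function() {
  data.frame(
    gene = c("tp53", "TP53", "PIK3CA", "pten", "KRAS",
             "PIK3CA", "BRAF", "TP53", "PTEN", "EGFR"),
    sample = sprintf("s%02d", c(1, 2, 1, 3, 4, 2, 5, 2, 4, 1)),
    mutation_type = c("missense", "nonsense", "missense", "frameshift",
                      "missense", "missense", "nonsense", "silent",
                      "missense", "nonsense"),
    dataset = c(rep("breast", 6), rep("lung", 4)),
    stringsAsFactors = FALSE
  )
}

test_that("load_mutation_table uppercases genes and skips incomplete rows", {
  tab <- ten_row_table()
  rec <- load_mutation_table(write_tmp_tsv(tab))
  expect_equal(nrow(rec), 10L)
  expect_equal(attr(rec, "skipped"), 0L)
  expect_true(all(rec$gene == toupper(rec$gene)))

  tab2 <- tab
  tab2$sample[c(3, 7)] <- ""
  rec2 <- load_mutation_table(write_tmp_tsv(tab2))
  expect_equal(nrow(rec2), 8L)
  expect_equal(attr(rec2, "skipped"), 2L)

  expect_error(load_mutation_table(write_tmp_tsv(tab),
                                   column_map = list(gene = "nope",
                                                     sample = "sample")),
               "'gene' column")
})

test_that("the MAF preset reads the same records as an explicit column map", {
  tab <- ten_row_table()
  maf <- data.frame(Hugo_Symbol = tab$gene,
                    Tumor_Sample_Barcode = tab$sample,
                    Variant_Classification = tab$mutation_type,
                    stringsAsFactors = FALSE)
  rec_maf <- load_mutation_table(write_tmp_tsv(maf), maf_preset())
  rec_exp <- load_mutation_table(
    write_tmp_tsv(maf),
    column_map = list(gene = "Hugo_Symbol", sample = "Tumor_Sample_Barcode",
                      mutation_type = "Variant_Classification", dataset = NULL))
  expect_identical(rec_maf, rec_exp)
  expect_equal(unique(rec_maf$dataset), "maf")
})

test_that("filter_records applies intersection semantics, ALL disables a filter", {
  rec <- load_mutation_table(write_tmp_tsv(ten_row_table()))
  expect_identical(filter_records(rec), rec)
  mis <- filter_records(rec, mutation_types = "Missense")
  expect_equal(nrow(mis), sum(ten_row_table()$mutation_type == "missense"))
  both <- filter_records(rec, mutation_types = "nonsense",
                         datasets = "breast")
  # independent linear scan over the source table
  src <- ten_row_table()
  expect_equal(nrow(both),
               sum(src$mutation_type == "nonsense" & src$dataset == "breast"))
  none <- filter_records(rec, datasets = "kidney")
  expect_equal(nrow(none), 0L)
})

test_that("mutation frequencies follow the distinct-sample rule", {
  # 5 distinct samples; G1 mutated in {s1,s2}, G2 in {s1}, G3 never;
  # G1 has a duplicate record in s1 which must count once
  rec <- data.frame(
    gene = c("G1", "G1", "G1", "G2", "G4", "G5"),
    sample = c("s1", "s1", "s2", "s1", "s3", "s4"),
    mutation_type = "missense", dataset = "d",
    stringsAsFactors = FALSE
  )
  rec <- rbind(rec, data.frame(gene = "G6", sample = "s5",
                               mutation_type = "missense", dataset = "d"))
  ft <- compute_mutation_frequencies(rec, c("G1", "G2", "G3"))
  expect_equal(ft$total_samples, rep(5L, 3))
  got <- stats::setNames(ft$frequency, ft$gene)
  expect_equal(got[["G1"]], 0.4)
  expect_equal(got[["G2"]], 0.2)
  expect_equal(got[["G3"]], 0.0)
  expect_equal(stats::setNames(ft$mutated_samples, ft$gene)[["G1"]], 2L)
})

test_that("empty record sets give zero frequencies with a warning flag", {
  empty <- data.frame(gene = character(0), sample = character(0),
                      mutation_type = character(0), dataset = character(0))
  expect_warning(ft <- compute_mutation_frequencies(empty, c("A", "B")),
                 "no samples")
  expect_true(all(ft$frequency == 0))
  expect_true(attr(ft, "no_samples"))
})

test_that("frequencies are invariant to record order and duplicated rows", {
  rec <- load_mutation_table(write_tmp_tsv(ten_row_table()))
  genes <- c("TP53", "PIK3CA", "PTEN", "KRAS", "BRAF", "EGFR", "NOTHERE")
  base <- compute_mutation_frequencies(rec, genes)
  shuf <- rec[rev(seq_len(nrow(rec))), ]
  dup <- rbind(rec, rec)
  expect_equal(compute_mutation_frequencies(shuf, genes), base,
               ignore_attr = TRUE)
  expect_equal(compute_mutation_frequencies(dup, genes), base,
               ignore_attr = TRUE)
})

test_that("filtering commutes with loading a pre-filtered file", {
  tab <- ten_row_table()
  rec_all <- load_mutation_table(write_tmp_tsv(tab))
  a <- filter_records(rec_all, datasets = "breast")
  b <- load_mutation_table(write_tmp_tsv(tab[tab$dataset == "breast", ]))
  expect_equal(a, b, ignore_attr = TRUE)
  genes <- unique(tab$gene)
  expect_equal(compute_mutation_frequencies(a, genes),
               compute_mutation_frequencies(b, genes), ignore_attr = TRUE)
})

test_that("gene roles load with spelling normalisation and closed vocabulary", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "roles.tsv")
  writeLines(c("gene\trole", "PIK3CA\toncogene", "TP53\ttumor-suppressor",
               "PTEN\tTumour_Suppressor", "EGFR\tneither"), path)
  roles <- load_gene_roles(path)
  expect_equal(unname(unclass(roles)[c("TP53", "PTEN")]),
               rep("tumour_suppressor", 2))
  writeLines(c("X\tdriver"), path)
  expect_error(load_gene_roles(path), "unknown role")
})

test_that("node annotation applies the max-frequency and role-precedence rules", {
  man <- kgml_manifest(
    entries = list(
      list(id = "1", type = "gene", name = "hsa:1", graphics_name = "ONC1"),
      list(id = "2", type = "gene", name = "hsa:2", graphics_name = "TSG1"),
      list(id = "3", type = "gene", name = "hsa:3", graphics_name = "OTH1"),
      list(id = "4", type = "gene", name = "hsa:4", graphics_name = "COLD1"),
      list(id = "5", type = "group", name = "undefined", graphics_name = "",
           components = c("1", "2"))
    ),
    relations = list(
      list(entry1 = "5", entry2 = "3", type = "PPrel", subtypes = "activation"),
      list(entry1 = "3", entry2 = "4", type = "PPrel", subtypes = "activation")
    )
  )
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(man)))
  freq <- data.frame(gene = c("ONC1", "TSG1", "OTH1", "COLD1"),
                     mutated_samples = c(1L, 4L, 2L, 0L),
                     total_samples = 10L,
                     frequency = c(0.1, 0.4, 0.2, 0))
  dir <- withr::local_tempdir()
  rpath <- file.path(dir, "roles.tsv")
  write_role_fixture(c(ONC1 = "oncogene", TSG1 = "tumour_suppressor"), rpath)
  roles <- load_gene_roles(rpath)

  ann <- annotate_nodes(pg, freq, roles, mode = "categorical")
  # complex {oncogene 0.1, TSG 0.4}: freq = max = 0.4, role oncogene, red
  expect_equal(ann[["5"]]$frequency, 0.4)
  expect_equal(ann[["5"]]$role, "oncogene")
  expect_equal(ann[["5"]]$colour, "red")
  expect_true(ann[["5"]]$is_complex)
  # mutated neither-gene is grey; unmutated gene has colour none
  expect_equal(ann[["3"]]$colour, "grey")
  expect_equal(ann[["4"]]$colour, "none")
  expect_false(ann[["4"]]$mutated)
  # per-member breakdown retained
  expect_setequal(ann[["5"]]$members$gene, c("ONC1", "TSG1"))

  # gradient mode: bucket 0 iff unmutated, indices monotone in frequency
  ga <- annotate_nodes(pg, freq, roles, mode = "gradient")
  buckets <- vapply(ga, `[[`, numeric(1), "colour")
  freqs <- vapply(ga, `[[`, numeric(1), "frequency")
  expect_equal(buckets[freqs == 0], c(`4` = 0))
  expect_true(all(diff(buckets[order(freqs)]) >= 0))
  expect_equal(max(buckets), 5)

  # pure function: identical inputs give identical annotations
  expect_identical(annotate_nodes(pg, freq, roles, mode = "categorical"), ann)
})

test_that("annotation with no mutation data marks every node unmutated", {
  pg <- collapse_groups(parse_kgml(write_tmp_kgml(make_small_manifest())))
  ann <- annotate_nodes(pg, NULL, NULL)
  expect_true(all(vapply(ann, function(a) a$colour == "none", logical(1))))
  expect_true(all(vapply(ann, function(a) !a$mutated, logical(1))))
})
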