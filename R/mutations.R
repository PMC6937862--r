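#' Built-in MAF column preset
#'
#' Column mapping for Mutation Annotation Format (MAF) tables as distributed
#' by TCGA: `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`.
#' MAF has no dataset column; records loaded with this preset get the
#' dataset label `"maf"` unless one is supplied.
#'
#' @return named list usable as the `column_map` of [load_mutation_table()].
#' @export
maf_preset <- function() {
  list(gene = "Hugo_Symbol", sample = "Tumor_Sample_Barcode",
       mutation_type = "Variant_Classification", dataset = NULL)
}

#' Load a somatic mutation table
#'
#' Reads a tab-separated mutation table with one row per mutation call and
#' maps its columns onto the four fields used downstream: gene symbol,
#' sample barcode, mutation type and dataset (organ/tissue) label.  Gene
#' symbols are uppercased on ingest.  Rows with an empty gene or sample are
#' skipped and counted in the `skipped` attribute of the result.
#'
#' @param path path to a TSV file with a header row.
#' @param column_map named list binding `gene`, `sample`, `mutation_type`
#'   and `dataset` to column names of the file.  `mutation_type` and
#'   `dataset` may be `NULL`, in which case the fields default to
#'   `"unspecified"` / `default_dataset`.  See [maf_preset()].
#' @param default_dataset dataset label used when no dataset column is
#'   mapped.
#' @return data frame of class `mutation_records` with columns `gene`,
#'   `sample`, `mutation_type`, `dataset`; attribute `skipped` holds the
#'   number of dropped rows.
#' @export
load_mutation_table <- function(path,
                                column_map = list(gene = "gene",
                                                  sample = "sample",
                                                  mutation_type = "mutation_type",
                                                  dataset = "dataset"),
                                default_dataset = "maf") {
  if (!file.exists(path))
    stop_pathdom(paste0("mutation file not found: ", path),
                 "pathdom_input_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  for (field in c("gene", "sample")) {
    col <- column_map[[field]]
    if (is.null(col) || !(col %in% names(tab)))
      stop_pathdom(paste0("mutation table is missing the mapped '", field,
                          "' column", if (!is.null(col)) paste0(" '", col, "'")),
                   "pathdom_format_error")
  }
  for (field in c("mutation_type", "dataset")) {
    col <- column_map[[field]]
    if (!is.null(col) && !(col %in% names(tab)))
      stop_pathdom(paste0("mutation table is missing the mapped '", field,
                          "' column '", col, "'"), "pathdom_format_error")
  }
  get_col <- function(field, default) {
    col <- column_map[[field]]
    if (is.null(col)) rep(default, nrow(tab)) else tab[[col]]
  }
  rec <- data.frame(
    gene = toupper(trimws(tab[[column_map$gene]])),
    sample = trimws(tab[[column_map$sample]]),
    mutation_type = get_col("mutation_type", "unspecified"),
    dataset = get_col("dataset", default_dataset),
    stringsAsFactors = FALSE
  )
  ok <- nzchar(rec$gene) & !is.na(rec$gene) & nzchar(rec$sample) & !is.na(rec$sample)
  out <- rec[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(!ok)
  class(out) <- c("mutation_records", class(out))
  out
}

#' Filter mutation records by type and dataset
#'
#' Keeps records whose mutation type and dataset label fall in the selected
#' sets; matching is exact after case normalisation.  `"ALL"` disables a
#' filter, mirroring selecting every type/dataset in the interface.
#'
#' @param records a `mutation_records` data frame.
#' @param mutation_types character vector of mutation types to keep, or
#'   `"ALL"`.
#' @param datasets character vector of dataset labels to keep, or `"ALL"`.
#' @return the filtered records (possibly zero rows).
#' @export
filter_records <- function(records, mutation_types = "ALL", datasets = "ALL") {
  keep <- rep(TRUE, nrow(records))
  if (!identical(toupper(mutation_types), "ALL"))
    keep <- keep & tolower(records$mutation_type) %in% tolower(mutation_types)
  if (!identical(toupper(datasets), "ALL"))
    keep <- keep & tolower(records$dataset) %in% tolower(datasets)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene mutation frequencies
#'
#' For each gene of interest, counts the distinct samples carrying at least
#' one qualifying mutation record for that gene; the frequency is that count
#' divided by the number of distinct samples present in the (already
#' filtered) record set.  Duplicate (gene, sample) records count once;
#' genes absent from the records get frequency 0.  With zero samples all
#' frequencies are 0 and the result carries `no_samples = TRUE`.
#'
#' @param records filtered `mutation_records` (see [filter_records()]).
#' @param genes_of_interest character vector of gene symbols (matched
#'   case-insensitively; exact symbols, no alias resolution).
#' @return data frame of class `mutation_frequency_table` with columns
#'   `gene`, `mutated_samples`, `total_samples`, `frequency`, one row per
#'   gene of interest; attribute `no_samples` flags an empty selection.
#' @export
compute_mutation_frequencies <- function(records, genes_of_interest) {
  genes <- unique(toupper(genes_of_interest))
  total <- length(unique(records$sample))
  counts <- vapply(genes, function(g)
    length(unique(records$sample[records$gene == g])), integer(1))
  out <- data.frame(
    gene = genes,
    mutated_samples = unname(counts),
    total_samples = total,
    frequency = if (total > 0L) unname(counts) / total else rep(0, length(genes)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_samples") <- total == 0L
  if (total == 0L && length(genes) > 0L)
    warning("no samples in the filtered selection; all frequencies are 0")
  class(out) <- c("mutation_frequency_table", class(out))
  out
}

#' Write a mutation frequency table to TSV
#'
#' @param freq a `mutation_frequency_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(as.data.frame(freq)[, c("gene", "mutated_samples",
                                             "total_samples", "frequency")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene role annotations
#'
#' Reads a two-column TSV (gene, role) assigning each gene one of the three
#' roles `oncogene`, `tumour_suppressor` or `neither`.  The American
#' spelling `tumor_suppressor` (and the hyphenated forms) are accepted and
#' normalised.  Genes absent from the file default to `neither` at lookup
#' time.
#'
#' @param path path to the TSV file (header optional: a first line
#'   `gene<TAB>role` is recognised and skipped).
#' @return named character vector gene -> role, class `gene_roles`.
#' @export
load_gene_roles <- function(path) {
  if (!file.exists(path))
    stop_pathdom(paste0("role file not found: ", path), "pathdom_input_error")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop_pathdom("role file must have two tab-separated columns: gene, role",
                 "pathdom_format_error")
  if (nrow(tab) > 0L && tolower(tab[1, 1]) == "gene")
    tab <- tab[-1, , drop = FALSE]
  roles <- normalise_role(tab[[2L]])
  bad <- unique(tab[[2L]][is.na(roles)])
  if (length(bad) > 0L)
    stop_pathdom(paste0("unknown role value(s): ", paste(bad, collapse = ", "),
                        " (expected oncogene, tumour_suppressor or neither)"),
                 "pathdom_format_error")
  structure(stats::setNames(roles, toupper(trimws(tab[[1L]]))),
            class = "gene_roles")
}

normalise_role <- function(x) {
  x <- tolower(gsub("[- ]", "_", trimws(x)))
  x[x == "tumor_suppressor"] <- "tumour_suppressor"
  x[!(x %in% c("oncogene", "tumour_suppressor", "neither"))] <- NA_character_
  x
}

role_of <- function(roles, gene) {
  if (is.null(roles)) return("neither")
  r <- unclass(roles)[toupper(gene)]
  r[is.na(r)] <- "neither"
  unname(r)
}

#' Annotate pathway nodes with mutation frequencies, roles and colours
#'
#' Attaches to every graph node its mutation frequency, gene role and
#' display colour.  A node's frequency is the maximum over its member genes
#' (a complex is as mutated as its most mutated subunit); its role follows
#' the precedence oncogene > tumour_suppressor > neither across members.
#'
#' In `categorical` mode, mutated nodes (frequency > 0) are coloured
#' `red`, `blue` or `grey` for oncogenes, tumour suppressors and neither
#' respectively; unmutated nodes get colour `none`.  In `gradient` mode the
#' colour slot holds a bucket index: 0 for frequency 0, then 1..`n_buckets`
#' equal-width bins over (0, max observed frequency].
#'
#' @param pg a collapsed `pathway_graph`, or a [rooted_digraph()] returned
#'   by [set_root()] (which carries the node metadata).
#' @param freq a `mutation_frequency_table` (may be `NULL`: all nodes
#'   unmutated).
#' @param roles a `gene_roles` vector (may be `NULL`: all `neither`).
#' @param mode `"categorical"` or `"gradient"`.
#' @param n_buckets number of gradient bins (default 5).
#' @return named list (by node identifier) of annotations, each with fields
#'   `node`, `label`, `frequency`, `role`, `colour`, `mutated`,
#'   `is_complex` and `members` (per-member gene breakdown).
#' @export
annotate_nodes <- function(pg, freq = NULL, roles = NULL,
                           mode = c("categorical", "gradient"),
                           n_buckets = 5L) {
  mode <- match.arg(mode)
  meta <- if (inherits(pg, "pathway_graph")) {
    if (!isTRUE(pg$collapsed))
      stop_pathdom("collapse_groups() must be applied before annotation",
                   "pathdom_input_error")
    pg$node_meta
  } else if (inherits(pg, "rooted_digraph")) {
    attr(pg, "node_meta") %||%
      lapply(stats::setNames(nm = pg$nodes), function(v)
        list(label = node_label(pg, v), genes = toupper(node_label(pg, v)),
             is_complex = FALSE))
  } else {
    stop_pathdom("pg must be a pathway_graph or rooted_digraph",
                 "pathdom_input_error")
  }

  lookup <- if (is.null(freq)) character(0) else
    stats::setNames(freq$frequency, toupper(freq$gene))
  gene_freq <- function(g) {
    f <- lookup[toupper(g)]
    f[is.na(f)] <- 0
    unname(f)
  }

  ann <- lapply(names(meta), function(id) {
    m <- meta[[id]]
    genes <- m$genes
    member_freq <- if (length(genes) > 0L) gene_freq(genes) else numeric(0)
    member_role <- if (length(genes) > 0L) role_of(roles, genes) else character(0)
    f <- if (length(member_freq) > 0L) max(member_freq) else 0
    role <- if ("oncogene" %in% member_role) "oncogene"
      else if ("tumour_suppressor" %in% member_role) "tumour_suppressor"
      else "neither"
    list(node = id, label = m$label, frequency = f, role = role,
         mutated = f > 0,
         is_complex = isTRUE(m$is_complex),
         members = data.frame(gene = genes, frequency = member_freq,
                              role = member_role, stringsAsFactors = FALSE))
  })
  names(ann) <- names(meta)

  if (mode == "categorical") {
    for (id in names(ann)) {
      a <- ann[[id]]
      ann[[id]]$colour <- if (!a$mutated) "none" else
        switch(a$role, oncogene = "red", tumour_suppressor = "blue", "grey")
    }
  } else {
    fmax <- max(c(0, vapply(ann, `[[`, numeric(1), "frequency")))
    for (id in names(ann)) {
      f <- ann[[id]]$frequency
      ann[[id]]$colour <- if (f <= 0 || fmax <= 0) 0L else
        max(1L, ceiling(f / fmax * n_buckets))
    }
  }
  ann
}
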