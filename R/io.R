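# Readers and writers for the plain-text formats the pipeline consumes.

#' Write / read a gene table as GFF-like TSV
#'
#' Columns: gene_id, replicon, start, end, strand, cog_category, product.
#' The nucleotide sequence column, when present, is written separately with
#' [write_gene_fasta()]. Reading restores `length = end - start + 1`.
#'
#' @param genes Gene table tibble.
#' @param path File path.
#' @return `path` invisibly (writer); gene tibble (reader).
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes[c("gene_id", "replicon", "start", "end", "strand",
                           "cog_category", "product")], path)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", replicon = "c", start = "i", end = "i",
                    strand = "c", cog_category = "c", product = "c"
                  )) |>
    dplyr::mutate(length = .data$end - .data$start + 1L, .after = "strand")
}

#' Write gene sequences as FASTA
#'
#' @param genes Gene table with `gene_id` and `sequence`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_bad_input("Biostrings is required for FASTA output")
  }
  seqs <- Biostrings::DNAStringSet(stats::setNames(genes$sequence, genes$gene_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read similarity hits in BLAST tabular (outfmt 6) dialects
#'
#' The standard dialect has the 12 classic columns with `pident` on the 0-100
#' scale and needs a 2-column sequence-length sidecar (`gene_id`, `length`,
#' written as `<path>.lengths.tsv`); the extended dialect appends `qlen` and
#' `slen` as columns 13-14. [read_similarity_hits()] detects the dialect from
#' the column count and normalizes identity back to the 0-1 scale.
#'
#' @param hits Hit tibble (identity 0-1, with `query_length`,
#'   `subject_length`).
#' @param path File path.
#' @param dialect `"extended"` (14 columns) or `"standard"` (12 columns +
#'   sidecar).
#' @return `path` invisibly (writer); hit tibble (reader).
#' @export
write_similarity_hits <- function(hits, path, dialect = c("extended", "standard")) {
  dialect <- match.arg(dialect)
  core <- hits |>
    dplyr::mutate(pident = 100 * .data$identity) |>
    dplyr::select("query_id", "subject_id", "pident", "alignment_length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  if (dialect == "extended") {
    core$qlen <- hits$query_length
    core$slen <- hits$subject_length
  } else {
    lengths <- dplyr::bind_rows(
      tibble::tibble(gene_id = hits$query_id, length = hits$query_length),
      tibble::tibble(gene_id = hits$subject_id, length = hits$subject_length)
    ) |> dplyr::distinct()
    readr::write_tsv(lengths, paste0(path, ".lengths.tsv"), col_names = FALSE)
  }
  readr::write_tsv(core, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_hits
#' @param lengths_path Sidecar path for the standard dialect (defaults to
#'   `<path>.lengths.tsv`).
#' @export
read_similarity_hits <- function(path, lengths_path = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  base_names <- c("query_id", "subject_id", "pident", "alignment_length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  if (ncol(raw) == 14) {
    names(raw) <- c(base_names, "query_length", "subject_length")
  } else if (ncol(raw) == 12) {
    names(raw) <- base_names
    lengths_path <- lengths_path %||% paste0(path, ".lengths.tsv")
    lens <- readr::read_tsv(lengths_path, col_names = c("gene_id", "length"),
                            show_col_types = FALSE)
    lookup <- stats::setNames(lens$length, lens$gene_id)
    raw$query_length <- unname(lookup[raw$query_id])
    raw$subject_length <- unname(lookup[raw$subject_id])
  } else {
    abort_bad_input("expected a 12- or 14-column tabular hit file")
  }
  raw |>
    dplyr::mutate(identity = .data$pident / 100, .after = "subject_id") |>
    dplyr::select(-"pident")
}

#' Write / read networks as TSV edge lists and SIF
#'
#' TSV columns: node_a, node_b, sources (comma-joined). SIF rows:
#' `A pp B` (sources are not representable in SIF and default to
#' `"unspecified"` on read).
#'
#' @param network An `interolog_network` or canonical edge tibble.
#' @param path File path.
#' @return `path` invisibly (writers); an `interolog_network` (readers).
#' @export
write_network_tsv <- function(network, path) {
  edges <- if (inherits(network, "interolog_network")) network$edges else network
  if (!"sources" %in% names(edges)) edges$sources <- "unspecified"
  readr::write_tsv(edges[c("node_a", "node_b", "sources")], path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  merge_networks(edges)
}

#' @rdname write_network_tsv
#' @export
write_network_sif <- function(network, path) {
  edges <- if (inherits(network, "interolog_network")) network$edges else network
  writeLines(paste(edges$node_a, "pp", edges$node_b), path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[ \t]+")
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) abort_bad_input("SIF lines must be 'A <type> B'")
  edges <- canonical_edge(vapply(parts, `[`, character(1), 1),
                          vapply(parts, `[`, character(1), 3))
  merge_networks(edges)
}

#' Write / read an expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples in the remaining header
#' columns.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `path` invisibly (writer); numeric matrix (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_expr_matrix(df)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-delimited: set id, description, then member genes. The
#' description column is retained as `term_name` (it is part of the enrichment
#' result contract), which is why this reader is implemented here rather than
#' through a parser that discards it.
#'
#' @param path GMT file path.
#' @return Tibble (`term_id`, `term_name`, `genes` list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 3)) {
    abort_bad_input("GMT lines need at least id, description and one gene")
  }
  tibble::tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$term_id[i], sets$term_name[i], sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-gene differential-expression results as TSV
#'
#' @param results Result tibble from [de_rnaseq()] or [de_array()].
#' @param path File path.
#' @return `path` invisibly (writer); result tibble (reader).
#' @export
write_de_results <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a subnetwork as SIF plus a node-attribute TSV
#'
#' @param subnetwork An `expr_subnetwork`.
#' @param sif_path,attr_path Output paths.
#' @return `sif_path`, invisibly.
#' @export
write_subnetwork <- function(subnetwork, sif_path, attr_path) {
  write_network_sif(subnetwork, sif_path)
  attrs <- subnetwork$nodes
  if (!is.null(subnetwork$annotation) && nrow(subnetwork$annotation) > 0) {
    attrs <- dplyr::left_join(attrs,
                              subnetwork$annotation[c("gene_id", "log2fc", "p", "call")],
                              by = "gene_id")
  }
  readr::write_tsv(attrs, attr_path)
  invisible(sif_path)
}
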