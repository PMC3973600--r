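#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the number of annotated genes in a random draw of `n` genes
#' from a universe of `M` genes of which `K` carry the annotation — the
#' over-representation statistic behind classic GO-term enrichment.
#'
#' @param M Universe size.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param k Annotated genes in the query.
#' @return Exact upper-tail probability (vectorized).
#' @export
hypergeom_tail <- function(M, K, n, k) {
  if (any(k < 0 | k > n | n > M | K > M | K < 0)) {
    abort_bad_input("need 0 <= k <= n <= M and 0 <= K <= M")
  }
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' One upper-tail hypergeometric test per retained set; sets are restricted to
#' the universe before the size filter is applied, and Benjamini-Hochberg
#' correction runs across the retained sets only. The universe should be the
#' gene table for genome-wide queries or the network node set for module
#' queries.
#'
#' @param query Character vector of genes (must lie in `universe`).
#' @param sets Named list of gene vectors, or a tibble with columns
#'   `term_id`, `term_name`, `genes` (list-column), as from [read_gmt()].
#' @param universe Character vector of background genes.
#' @param min_set,max_set Inclusive bounds on the in-universe set size.
#' @return Tibble (`term_id`, `term_name`, `k`, `K`, `n`, `M`, `p`, `q`),
#'   sorted by `p`.
#' @export
enrich_sets <- function(query, sets, universe, min_set = 1L, max_set = Inf) {
  if (length(universe) == 0) abort_bad_input("universe must be non-empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) abort_bad_input("query genes must lie in the universe")
  if (is.data.frame(sets)) {
    set_list <- stats::setNames(sets$genes, sets$term_id)
    set_names <- stats::setNames(sets$term_name, sets$term_id)
  } else {
    set_list <- sets
    set_names <- stats::setNames(names(sets), names(sets))
  }
  trimmed <- lapply(set_list, intersect, universe)
  K <- lengths(trimmed)
  retained <- K >= min_set & K <= max_set
  trimmed <- trimmed[retained]
  if (length(trimmed) == 0) {
    return(tibble::tibble(term_id = character(0), term_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          M = integer(0), p = double(0), q = double(0)))
  }
  k <- unname(vapply(trimmed, function(s) length(intersect(s, query)), integer(1)))
  res <- tibble::tibble(
    term_id = names(trimmed),
    term_name = unname(set_names[names(trimmed)]),
    k = k,
    K = unname(K[retained]),
    n = length(query),
    M = length(universe)
  )
  res$p <- hypergeom_tail(res$M, res$K, res$n, res$k)
  res$q <- bh_fdr(res$p)
  dplyr::arrange(res, .data$p, .data$term_id)
}

#' Up/down tallies per COG functional category
#'
#' Multi-letter COG strings contribute one count to each letter (standard COG
#' convention); `-` or empty strings are grouped as `uncategorized`.
#' Percentages are relative to each category's gene total, rounded half-up to
#' two decimals. Categories with assigned genes but no calls are retained with
#' zeros.
#'
#' @param de Result tibble with `gene_id` and `call`.
#' @param cog Tibble with `gene_id` and `cog_category`.
#' @return Tibble (`cog_category`, `n_genes`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`).
#' @export
cog_tally <- function(de, cog) {
  calls <- stats::setNames(de$call, de$gene_id)
  expanded <- cog |>
    dplyr::mutate(cog_category = dplyr::if_else(
      .data$cog_category %in% c("-", "", NA_character_),
      "uncategorized", .data$cog_category
    )) |>
    dplyr::mutate(letter = strsplit(.data$cog_category, "")) |>
    tidyr::unnest("letter") |>
    dplyr::mutate(letter = dplyr::if_else(.data$cog_category == "uncategorized",
                                          "uncategorized", .data$letter)) |>
    dplyr::distinct(.data$gene_id, .data$letter)
  expanded$call <- unname(calls[expanded$gene_id])
  expanded |>
    dplyr::group_by(cog_category = .data$letter) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$call == "up", na.rm = TRUE),
      n_down = sum(.data$call == "down", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_up = round_half_up(100 * .data$n_up / .data$n_genes),
      pct_down = round_half_up(100 * .data$n_down / .data$n_genes)
    ) |>
    dplyr::arrange(.data$cog_category)
}

#' Per-replicon proportions of differentially expressed genes
#'
#' Tallies up- and down-regulated genes per replicon and appends a Total row;
#' percentages are `100 * count / n_genes`, rounded half-up to two decimals
#' (the convention of printed replicon tables).
#'
#' @param de Result tibble with `gene_id` and `call`.
#' @param gene_table Gene table with `gene_id` and `replicon` covering every
#'   called gene.
#' @return Tibble (`replicon`, `n_genes`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`) with a final `Total` row.
#' @export
replicon_table <- function(de, gene_table) {
  missing <- setdiff(de$gene_id, gene_table$gene_id)
  if (length(missing) > 0) {
    abort_bad_input(paste0("genes without a replicon: ",
                           paste(utils::head(missing, 5), collapse = ", "),
                           if (length(missing) > 5) " ..."))
  }
  calls <- stats::setNames(de$call, de$gene_id)
  counts <- gene_table |>
    dplyr::mutate(call = unname(calls[.data$gene_id])) |>
    dplyr::group_by(.data$replicon) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$call == "up", na.rm = TRUE),
      n_down = sum(.data$call == "down", na.rm = TRUE),
      .groups = "drop"
    )
  replicon_summary(counts)
}

#' Replicon proportion table from pre-tallied counts
#'
#' Computes the percentage columns and the Total row from per-replicon gene
#' and call counts (as printed in a study's replicon table).
#'
#' @param counts Tibble with `replicon`, `n_genes`, `n_up`, `n_down`.
#' @return Same shape as [replicon_table()].
#' @export
replicon_summary <- function(counts) {
  stopifnot(all(c("replicon", "n_genes", "n_up", "n_down") %in% names(counts)))
  total <- tibble::tibble(
    replicon = "Total",
    n_genes = sum(counts$n_genes),
    n_up = sum(counts$n_up),
    n_down = sum(counts$n_down)
  )
  dplyr::bind_rows(tibble::as_tibble(counts[c("replicon", "n_genes", "n_up", "n_down")]),
                   total) |>
    dplyr::mutate(
      pct_up = round_half_up(100 * .data$n_up / .data$n_genes),
      pct_down = round_half_up(100 * .data$n_down / .data$n_genes)
    )
}

#' Sliding-window profile of differential expression and GC content
#'
#' Walks each replicon in genomic order (genes sorted by start coordinate) in
#' windows of `window` genes every `step` genes; reports the percentage of up-
#' and down-calls among the genes actually in the window and their pooled GC
#' content. A trailing partial window is kept only when it holds at least half
#' a window's genes.
#'
#' @param gene_table Gene table with `gene_id`, `replicon`, `start` and a
#'   `sequence` column.
#' @param de Result tibble with `gene_id` and `call`.
#' @param window Genes per window (>= 1).
#' @param step Offset between window starts (defaults to `window`,
#'   i.e. non-overlapping).
#' @return Tibble (`replicon`, `window_index`, `n_genes`, `gene_ids`
#'   list-column, `pct_up`, `pct_down`, `gc_fraction`).
#' @export
sliding_window_profile <- function(gene_table, de, window = 50L, step = window) {
  if (window < 1) abort_bad_input("window must be >= 1")
  calls <- stats::setNames(de$call, de$gene_id)
  out <- list()
  for (rep_name in unique(gene_table$replicon)) {
    genes <- gene_table[gene_table$replicon == rep_name, , drop = FALSE]
    genes <- genes[order(genes$start), , drop = FALSE]
    n <- nrow(genes)
    starts <- seq(1L, n, by = step)
    wi <- 0L
    for (s in starts) {
      idx <- s:min(s + window - 1L, n)
      if (length(idx) < window && length(idx) < window / 2) next
      wi <- wi + 1L
      ids <- genes$gene_id[idx]
      w_calls <- unname(calls[ids])
      out[[length(out) + 1]] <- tibble::tibble(
        replicon = rep_name,
        window_index = wi,
        n_genes = length(idx),
        gene_ids = list(ids),
        pct_up = 100 * sum(w_calls == "up", na.rm = TRUE) / length(idx),
        pct_down = 100 * sum(w_calls == "down", na.rm = TRUE) / length(idx),
        gc_fraction = pooled_gc(genes$sequence[idx])
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Share of total expression held by the top-n genes
#'
#' Sum of the `n` largest expression values over the total; ties at the cutoff
#' are broken by gene id for determinism.
#'
#' @param values Non-negative expression values.
#' @param n How many top genes (default 10).
#' @param ids Optional gene ids for deterministic tie-breaking (defaults to
#'   names of `values`, else position labels).
#' @return Fraction in \[0, 1\].
#' @export
topn_share <- function(values, n = 10L, ids = NULL) {
  if (any(values < 0)) abort_bad_input("expression values must be non-negative")
  if (length(values) < n) abort_bad_input("fewer genes than n")
  total <- sum(values)
  if (total == 0) abort_bad_input("total expression is zero; share undefined")
  ids <- ids %||% names(values) %||% sprintf("g%06d", seq_along(values))
  ord <- order(-values, ids)
  sum(values[ord[seq_len(n)]]) / total
}

#' Exact intersection of two gene-id lists
#'
#' Identifiers are whitespace-trimmed and compared case-sensitively.
#'
#' @param a,b Character vectors of gene ids.
#' @return List with `shared` (sorted character) and `count`.
#' @export
table_intersection <- function(a, b) {
  shared <- sort(intersect(unique(trimws(a)), unique(trimws(b))))
  list(shared = shared, count = length(shared))
}

#' Assemble a run summary
#'
#' Collects the headline numbers of a full analysis — network statistics, the
#' platform Venn counts and correlation, the replicon proportion table and the
#' top-n expression share — into one list suitable for JSON serialization via
#' [write_run_summary()].
#'
#' @param network An `interolog_network`.
#' @param comparison A `platform_comparison` (optional).
#' @param replicon_tbl Output of [replicon_table()] (optional).
#' @param topn_share Value from [topn_share()] (optional).
#' @return A named list.
#' @export
run_summary <- function(network, comparison = NULL, replicon_tbl = NULL,
                        topn_share = NULL) {
  out <- list(network = as.list(glance(network)))
  if (!is.null(comparison)) out$platforms <- as.list(comparison$summary)
  if (!is.null(replicon_tbl)) out$replicons <- replicon_tbl
  if (!is.null(topn_share)) out$top_n_share <- topn_share
  out
}

#' Write a run summary as JSON
#'
#' @param summary List from [run_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
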