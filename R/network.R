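#' Canonicalize undirected edges
#'
#' Orders each endpoint pair lexicographically so that an undirected edge has
#' one representation; self-loops are rejected.
#'
#' @param u,v Character vectors of endpoint identifiers (recycled together).
#' @return Tibble with columns `node_a`, `node_b` where `node_a < node_b`.
#' @export
canonical_edge <- function(u, v) {
  if (any(u == v)) abort_bad_input("self-loops are not allowed")
  tibble::tibble(node_a = pmin(u, v), node_b = pmax(u, v))
}

#' Transfer reference interactions onto the target proteome
#'
#' Implements the interolog principle: a reference edge (x, y) becomes a target
#' edge (map\[x\], map\[y\]) when both endpoints have an ortholog and the images
#' differ. Transferred edges are canonicalized, de-duplicated and labelled with
#' the reference organism as their evidence source. The number of reference
#' edges dropped for lack of an ortholog is reported as a message.
#'
#' @param reference_edges Tibble with columns `node_a`, `node_b` (reference
#'   gene ids).
#' @param ortholog_pairs Tibble from [find_bbh()] (needs `target_gene`,
#'   `reference_gene`; one-to-one per organism).
#' @param organism Source label; defaults to the pairs' `organism` column.
#' @return Tibble (`node_a`, `node_b`, `sources`).
#' @export
transfer_edges <- function(reference_edges, ortholog_pairs, organism = NULL) {
  organism <- organism %||% unique(ortholog_pairs$organism) %||% "reference"
  stopifnot(length(organism) == 1)
  map <- stats::setNames(ortholog_pairs$target_gene, ortholog_pairs$reference_gene)
  a <- unname(map[reference_edges$node_a])
  b <- unname(map[reference_edges$node_b])
  unmapped <- is.na(a) | is.na(b)
  if (any(unmapped)) {
    message(sum(unmapped), " reference edge(s) dropped: unmapped endpoint")
  }
  keep <- !unmapped & a != b
  if (sum(unmapped) + sum(keep) < length(a)) {
    message(length(a) - sum(unmapped) - sum(keep),
            " reference edge(s) dropped: endpoints collapse to one gene")
  }
  if (!any(keep)) {
    return(tibble::tibble(node_a = character(0), node_b = character(0),
                          sources = character(0)))
  }
  canonical_edge(a[keep], b[keep]) |>
    dplyr::distinct() |>
    dplyr::mutate(sources = organism) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Merge transferred edge sets into one non-redundant network
#'
#' Takes any number of canonical edge tibbles (each optionally carrying a
#' `sources` column) and returns their union; an edge found in several inputs
#' keeps the union of its evidence sources. Merging is idempotent and
#' order-independent.
#'
#' @param ... Edge tibbles (`node_a`, `node_b`, optional `sources`), or a
#'   single list of them.
#' @return An `interolog_network` object: list with `nodes` (sorted character)
#'   and `edges` (tibble `node_a`, `node_b`, `sources` with comma-joined,
#'   sorted source labels).
#' @export
merge_networks <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  edges <- dplyr::bind_rows(lapply(inputs, function(e) {
    e <- tibble::as_tibble(e)
    if (!"sources" %in% names(e)) e$sources <- "unspecified"
    e[c("node_a", "node_b", "sources")]
  }))
  if (nrow(edges) > 0 && any(edges$node_a >= edges$node_b)) {
    abort_bad_input("merge_networks expects canonical edges (node_a < node_b)")
  }
  edges <- edges |>
    tidyr::separate_longer_delim("sources", delim = ",") |>
    dplyr::distinct() |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(sources = paste(sort(unique(.data$sources)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$node_a, .data$node_b)
  new_interolog_network(edges)
}

new_interolog_network <- function(edges, annotation = NULL) {
  structure(
    list(
      nodes = sort(unique(c(edges$node_a, edges$node_b))),
      edges = edges,
      annotation = annotation
    ),
    class = "interolog_network"
  )
}

#' Convert a network to an igraph graph
#'
#' @param network An `interolog_network`.
#' @return An undirected [igraph::graph] on the same node set.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interolog_network"))
  igraph::graph_from_data_frame(
    network$edges[c("node_a", "node_b")],
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Summary statistics of a network
#'
#' @param network An `interolog_network`.
#' @return List with `n_nodes`, `n_edges`, `n_components` and `degrees`
#'   (named integer vector over all nodes; isolated nodes have degree 0).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "interolog_network"))
  if (length(network$nodes) == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                degrees = stats::setNames(integer(0), character(0))))
  }
  g <- as_igraph(network)
  list(
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    n_components = igraph::count_components(g),
    degrees = igraph::degree(g)
  )
}

#' @export
print.interolog_network <- function(x, ...) {
  s <- network_stats(x)
  cat("<interolog_network>", s$n_nodes, "nodes,", s$n_edges, "edges,",
      s$n_components, "component(s)\n")
  if (!is.null(x$annotation)) {
    cat("  annotated:", sum(x$annotation$measured), "of", s$n_nodes,
        "nodes measured\n")
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of an interolog network
#'
#' @param x An `interolog_network`.
#' @param ... Unused.
#' @return Tibble with node, edge, component counts and degree summaries.
#' @export
glance.interolog_network <- function(x, ...) {
  s <- network_stats(x)
  tibble::tibble(
    n_nodes = s$n_nodes,
    n_edges = s$n_edges,
    n_components = s$n_components,
    mean_degree = if (s$n_nodes > 0) mean(s$degrees) else NA_real_,
    max_degree = if (s$n_nodes > 0) max(s$degrees) else NA_integer_
  )
}

#' Edge table of a network, one row per edge
#'
#' @param x An `interolog_network`.
#' @param ... Unused.
#' @return The canonical edge tibble.
#' @export
tidy.interolog_network <- function(x, ...) {
  x$edges
}
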