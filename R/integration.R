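#' Overlay expression results on an interolog network
#'
#' Attaches a per-node annotation (expression levels, fold change, p, q, call)
#' to every network node. Nodes absent from the expression results are flagged
#' unmeasured and are excluded from seeding in the subnetwork extractors.
#' With `platform = "both"` a node counts as measured only when it appears in
#' both result sets; the sequencing-arm values then feed the annotation (the
#' platform with the greater dynamic range).
#'
#' @param network An `interolog_network` from [merge_networks()].
#' @param rnaseq,array Result tibbles from [de_rnaseq()] / [de_array()].
#' @param platform Which platform(s) must have measured a node:
#'   `"rnaseq"`, `"array"` or `"both"`.
#' @return The network with an `annotation` tibble (`gene_id`, `value_a`,
#'   `value_b`, `fold_change`, `log2fc`, `p`, `q`, `call`, `measured`).
#' @export
overlay_expression <- function(network, rnaseq = NULL, array = NULL,
                               platform = c("rnaseq", "array", "both")) {
  stopifnot(inherits(network, "interolog_network"))
  platform <- match.arg(platform)
  primary <- switch(platform,
    rnaseq = rnaseq %||% abort_bad_input("rnaseq results required"),
    array = array %||% abort_bad_input("array results required"),
    both = rnaseq %||% abort_bad_input("rnaseq results required (primary under 'both')")
  )
  ann <- tibble::tibble(gene_id = network$nodes) |>
    dplyr::left_join(
      dplyr::select(primary, "gene_id", "value_a", "value_b", "log2fc", "p", "q", "call"),
      by = "gene_id"
    )
  measured <- !is.na(ann$p)
  if (platform == "both") {
    if (is.null(array)) abort_bad_input("array results required under 'both'")
    measured <- measured & ann$gene_id %in% array$gene_id
  }
  ann$measured <- measured
  ann$fold_change <- 2^ann$log2fc
  # genes unexpressed in B have ratio 0; unexpressed in A have ratio Inf
  zero_b <- measured & !is.na(ann$value_b) & !is.na(ann$value_a) &
    ann$value_b == 0 & ann$value_a > 0
  ann$fold_change[zero_b] <- 0
  ann$call[!measured] <- NA_character_
  network$annotation <- ann[c("gene_id", "value_a", "value_b", "fold_change",
                              "log2fc", "p", "q", "call", "measured")]
  network
}

new_expr_subnetwork <- function(nodes, edges, annotation) {
  structure(list(nodes = nodes, edges = edges, annotation = annotation),
            class = c("expr_subnetwork", "interolog_network"))
}

#' @export
print.expr_subnetwork <- function(x, ...) {
  cat("<expr_subnetwork>", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "seed"), "seeds ),", nrow(x$edges), "edges\n")
  invisible(x)
}

induced_edges <- function(network, nodes) {
  e <- network$edges
  e[e$node_a %in% nodes & e$node_b %in% nodes, , drop = FALSE]
}

#' Fold-change-thresholded subnetwork
#'
#' Reconstructs the "select strongly changed genes and map them onto the
#' network" procedure. Seed nodes are measured nodes whose expression ratio is
#' at least `fold` or at most `1/fold` (ratio-0 and ratio-infinity sentinels
#' qualify when the nonzero side reaches the expression floor). Non-seed
#' "linker" nodes adjacent to at least two seeds are added, the subgraph
#' induced on seeds plus linkers is taken, and only connected components
#' containing at least two seeds are kept.
#'
#' @param network An annotated network from [overlay_expression()].
#' @param fold Ratio threshold (> 1), default 5.
#' @param expression_floor Floor for the sentinel rule.
#' @return An `expr_subnetwork`: `nodes` tibble (`gene_id`, `role`), induced
#'   `edges`, and the annotation restricted to member nodes. Empty when there
#'   are no seeds (with a message).
#' @export
fold_threshold_subnetwork <- function(network, fold = 5, expression_floor = 1) {
  stopifnot(inherits(network, "interolog_network"))
  if (is.null(network$annotation)) abort_bad_input("network is not annotated; run overlay_expression()")
  if (fold <= 1) abort_bad_input("fold must exceed 1")
  ann <- network$annotation
  fc <- ann$fold_change
  sentinel_ok <- rep(TRUE, nrow(ann))
  up_inf <- is.infinite(fc)
  dn_zero <- !is.na(fc) & fc == 0
  sentinel_ok[up_inf] <- ann$value_b[up_inf] >= expression_floor
  sentinel_ok[dn_zero] <- ann$value_a[dn_zero] >= expression_floor
  is_seed <- ann$measured & !is.na(fc) & sentinel_ok & (fc >= fold | fc <= 1 / fold)
  seeds <- ann$gene_id[is_seed]
  if (length(seeds) == 0) {
    message("no nodes pass the fold threshold; empty subnetwork")
    return(new_expr_subnetwork(
      tibble::tibble(gene_id = character(0), role = character(0)),
      network$edges[0, ], ann[0, ]
    ))
  }
  e <- network$edges
  seed_touch <- c(e$node_a[e$node_b %in% seeds], e$node_b[e$node_a %in% seeds])
  touch_counts <- table(seed_touch)
  linkers <- setdiff(names(touch_counts)[touch_counts >= 2], seeds)
  members <- c(seeds, linkers)
  sub_edges <- induced_edges(network, members)
  g <- igraph::graph_from_data_frame(sub_edges[c("node_a", "node_b")],
                                     directed = FALSE, vertices = members)
  comp <- igraph::components(g)
  seeds_per_comp <- tapply(names(comp$membership) %in% seeds, comp$membership, sum)
  keep_comp <- as.integer(names(seeds_per_comp)[seeds_per_comp >= 2])
  keep_nodes <- names(comp$membership)[comp$membership %in% keep_comp]
  nodes <- tibble::tibble(
    gene_id = sort(keep_nodes),
    role = ifelse(sort(keep_nodes) %in% seeds, "seed", "linker")
  )
  new_expr_subnetwork(nodes, induced_edges(network, nodes$gene_id),
                      ann[ann$gene_id %in% nodes$gene_id, , drop = FALSE])
}

#' Aggregate z-score of a node set, with Monte-Carlo background correction
#'
#' Each node's p-value is transformed to `z = qnorm(1 - p)`; the aggregate is
#' `z_a = sum(z) / sqrt(k)`. The background-corrected score is
#' `s_a = (z_a - mu_k) / sigma_k` where `mu_k` and `sigma_k` are the mean and
#' SD of `z_a` over random k-node subsets of the background (seeded Monte
#' Carlo). p-values of exactly 0 or 1 are clamped to \[1e-15, 1 - 1e-15\].
#'
#' @param nodes Gene ids of the module.
#' @param p Named vector of per-node p-values covering `nodes` and the
#'   background.
#' @param background Gene ids to draw background sets from (defaults to all
#'   names of `p`).
#' @param n_background Number of Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @return One-row tibble (`k`, `z_a`, `mu_k`, `sigma_k`, `s_a`).
#' @export
score_module <- function(nodes, p, background = names(p),
                         n_background = 1000L, seed = 1L) {
  if (!all(nodes %in% names(p))) abort_bad_input("every node needs a p-value")
  z <- module_z(p)
  k <- length(nodes)
  z_a <- sum(z[nodes]) / sqrt(k)
  bg <- z[background]
  draws <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_background), function(i) sum(sample(bg, k)) / sqrt(k), numeric(1))
  })
  mu <- mean(draws); sigma <- stats::sd(draws)
  tibble::tibble(k = k, z_a = z_a, mu_k = mu, sigma_k = sigma,
                 s_a = (z_a - mu) / sigma)
}

module_z <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    message("p-values at 0 or 1 clamped to [1e-15, 1 - 1e-15]")
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  }
  stats::qnorm(1 - p)
}

#' Greedy search for active modules
#'
#' Scores connected node sets by the background-corrected aggregate z of
#' [score_module()] and grows one module from every seed: starting at a
#' measured node with p below `start_p`, repeatedly add the adjacent measured
#' node that maximally increases `s_a`, stopping when no addition improves the
#' score or `max_k` is reached. The background mean and SD of `z_a` are
#' estimated once per module size from `n_background` seeded random subsets of
#' the measured nodes. Overlapping results (Jaccard >= 0.5 with a
#' better-scoring kept module) are discarded.
#'
#' @param network An annotated network from [overlay_expression()].
#' @param seeds Seed nodes; defaults to measured nodes with `p < start_p`.
#' @param max_k Maximum module size.
#' @param n_background Monte-Carlo draws per module size.
#' @param start_p Seed-selection p-value bound.
#' @param seed Seed for the Monte-Carlo background.
#' @return An `active_modules` tibble, ranked by `s_a`: one row per module
#'   with `seed`, `k`, `z_a`, `s_a` and a `nodes` list-column.
#' @export
search_active_modules <- function(network, seeds = NULL, max_k = 30L,
                                  n_background = 1000L, start_p = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(network, "interolog_network"))
  if (is.null(network$annotation)) abort_bad_input("network is not annotated; run overlay_expression()")
  ann <- network$annotation[network$annotation$measured, , drop = FALSE]
  if (nrow(ann) == 0) abort_bad_input("no measured nodes")
  p <- stats::setNames(ann$p, ann$gene_id)
  z <- module_z(p)
  seeds <- seeds %||% names(p)[p < start_p]
  if (length(seeds) == 0) {
    return(structure(tibble::tibble(seed = character(0), k = integer(0),
                                    z_a = double(0), s_a = double(0),
                                    nodes = list()),
                     class = c("active_modules", class(tibble::tibble()))))
  }
  max_k <- min(max_k, length(z))
  # background: cumulative sums over random orderings give z_a for every k
  bg <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_background), function(i) {
      cumsum(sample(z, max_k)) / sqrt(seq_len(max_k))
    }, numeric(max_k)))
  })
  mu_k <- colMeans(bg)
  sigma_k <- apply(bg, 2, stats::sd)

  adj <- adjacency_list(network)
  grow <- function(s) {
    members <- s
    z_sum <- z[[s]]
    frontier <- setdiff(intersect(adj[[s]], names(z)), members)
    s_a <- (z_sum / 1 - mu_k[1]) / sigma_k[1]
    while (length(members) < max_k && length(frontier) > 0) {
      k1 <- length(members) + 1
      cand_s <- (z_sum + z[frontier]) / sqrt(k1)
      cand_s <- (cand_s - mu_k[k1]) / sigma_k[k1]
      best <- which.max(cand_s)
      if (cand_s[best] <= s_a) break
      pick <- frontier[best]
      members <- c(members, pick)
      z_sum <- z_sum + z[[pick]]
      s_a <- cand_s[[best]]
      frontier <- setdiff(union(frontier, intersect(adj[[pick]], names(z))), members)
    }
    list(seed = s, nodes = sort(members), k = length(members),
         z_a = z_sum / sqrt(length(members)), s_a = unname(s_a))
  }
  mods <- lapply(sort(seeds), grow)
  res <- tibble::tibble(
    seed = vapply(mods, `[[`, character(1), "seed"),
    k = vapply(mods, `[[`, integer(1), "k"),
    z_a = vapply(mods, `[[`, numeric(1), "z_a"),
    s_a = vapply(mods, `[[`, numeric(1), "s_a"),
    nodes = lapply(mods, `[[`, "nodes")
  ) |>
    dplyr::arrange(dplyr::desc(.data$s_a), .data$seed)
  kept <- list()
  keep_row <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ni <- res$nodes[[i]]
    overlap <- any(vapply(kept, function(kn) {
      length(intersect(ni, kn)) / length(union(ni, kn)) >= 0.5
    }, logical(1)))
    if (!overlap) {
      keep_row[i] <- TRUE
      kept[[length(kept) + 1]] <- ni
    }
  }
  out <- res[keep_row, , drop = FALSE]
  class(out) <- c("active_modules", class(tibble::tibble()))
  out
}

adjacency_list <- function(network) {
  e <- network$edges
  split(c(e$node_b, e$node_a), c(e$node_a, e$node_b))
}

#' Ego subnetwork around a focal node
#'
#' All nodes within `radius` edges of `seed_node`, with induced edges. The
#' default radius of 2 reproduces the "first neighbours, then their first
#' neighbours" dissection used for regulator-centred subnetworks.
#'
#' @param network An `interolog_network`.
#' @param seed_node Focal gene id (must be in the network).
#' @param radius Graph distance bound (>= 0).
#' @return An `expr_subnetwork` with roles `"seed"` (the focal node) and
#'   `"neighbor"`.
#' @export
ego_subnetwork <- function(network, seed_node, radius = 2L) {
  stopifnot(inherits(network, "interolog_network"))
  if (!seed_node %in% network$nodes) abort_bad_input(paste0("unknown node: ", seed_node))
  g <- as_igraph(network)
  members <- names(igraph::ego(g, order = radius, nodes = seed_node)[[1]])
  nodes <- tibble::tibble(
    gene_id = sort(members),
    role = ifelse(sort(members) == seed_node, "seed", "neighbor")
  )
  ann <- network$annotation
  if (!is.null(ann)) ann <- ann[ann$gene_id %in% members, , drop = FALSE]
  new_expr_subnetwork(nodes, induced_edges(network, members),
                      ann %||% tibble::tibble())
}
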