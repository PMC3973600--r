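test_that("gene tables lay genes end-to-end with valid coordinates", {
  cfg <- sim_config(seed = 3,
                    replicons = tibble::tibble(name = "r1", gene_count = 10L,
                                               gc_fraction = 0.5),
                    de_up_fraction = c(r1 = 0), de_down_fraction = c(r1 = 0),
                    planted_module_size = 5L)
  g <- simulate_gene_table(cfg)
  expect_equal(nrow(g), 10)
  expect_equal(g$start[1], 1L)
  expect_equal(g$start[-1], utils::head(g$end, -1) + 1L)
  expect_equal(g$length, g$end - g$start + 1L)
  expect_equal(g$length, nchar(g$sequence))
})

test_that("realized GC content tracks the configured fraction", {
  cfg <- sim_config(seed = 2,
                    replicons = tibble::tibble(name = "r1", gene_count = 100L,
                                               gc_fraction = 0.5),
                    de_up_fraction = c(r1 = 0), de_down_fraction = c(r1 = 0),
                    planted_module_size = 5L)
  g <- simulate_gene_table(cfg)
  gc <- sum(stringr::str_count(g$sequence, "[GC]")) / sum(nchar(g$sequence))
  expect_gte(gc, 0.47)
  expect_lte(gc, 0.53)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(replicons = tibble::tibble(name = "r1", gene_count = 0L,
                                                     gc_fraction = 0.5),
                          de_up_fraction = c(r1 = 0), de_down_fraction = c(r1 = 0)),
               "positive")
  expect_error(sim_config(de_up_fraction = c(pMHa = 1.5, pMHb = 0, chromosome = 0)),
               "fraction|\\[0, 1\\]")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(simulate_similarity_hits(tibble::tibble(gene_id = "a", length = 300L),
                                        tibble::tibble(gene_id = "b", length = 300L),
                                        ortholog_fraction = 1.2),
               "ortholog_fraction")
})

test_that("planted ortholog pairs are exactly round(fraction * n)", {
  cfg <- small_sim_config(seed = 4)
  g <- simulate_gene_table(cfg)
  ref <- simulate_gene_table(cfg, id_prefix = "REF")
  hits <- simulate_similarity_hits(g[1:100, ], ref, ortholog_fraction = 0.6,
                                   hit_noise_rate = 0, seed = 4)
  expect_equal(nrow(hits$ortholog_map), 60)
  # every planted pair passes the default thresholds in both directions
  thr <- hit_thresholds()
  expect_true(all(passes_thresholds(hits$forward, thr)))
  expect_true(all(passes_thresholds(hits$reverse, thr)))
})

test_that("zero ortholog fraction yields no bidirectional best hits", {
  cfg <- small_sim_config(seed = 5)
  g <- simulate_gene_table(cfg)
  ref <- simulate_gene_table(cfg, id_prefix = "REF")
  hits <- simulate_similarity_hits(g, ref, ortholog_fraction = 0,
                                   hit_noise_rate = 0.2, seed = 5)
  expect_equal(nrow(hits$ortholog_map), 0)
  expect_equal(nrow(find_bbh(hits$forward, hits$reverse)), 0)
})

test_that("reference networks are simple graphs with a connected planted module", {
  ids <- sprintf("g%02d", 1:30)
  net <- simulate_reference_network(ids, edge_count = 60, planted_module_size = 5,
                                    seed = 7)
  expect_equal(nrow(net$edges), 60)
  expect_true(all(net$edges$node_a < net$edges$node_b))
  expect_equal(anyDuplicated(net$edges), 0L)
  expect_length(net$module_nodes, 5)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  sub <- igraph::induced_subgraph(g, net$module_nodes)
  expect_true(igraph::is_connected(sub))
})

test_that("edge-count edge cases: empty, complete, infeasible", {
  ids <- paste0("g", 1:5)
  empty <- simulate_reference_network(ids, edge_count = 0, planted_module_size = 0,
                                      seed = 1)
  expect_equal(nrow(empty$edges), 0)
  complete <- simulate_reference_network(ids, edge_count = 10,
                                         planted_module_size = 5, seed = 1)
  expect_equal(nrow(complete$edges), 10)  # C(5,2): every pair present
  expect_setequal(paste(complete$edges$node_a, complete$edges$node_b),
                  apply(t(utils::combn(sort(ids), 2)), 1, paste, collapse = " "))
  expect_error(simulate_reference_network(ids, edge_count = 11,
                                          planted_module_size = 0, seed = 1),
               "exceeds")
  expect_error(simulate_reference_network(ids, edge_count = 2,
                                          planted_module_size = 5, seed = 1),
               "too small")
})

test_that("expression truth labels honour the configured DE fractions", {
  cfg <- small_sim_config(seed = 6)
  g <- simulate_gene_table(cfg)
  ex <- simulate_expression(g, cfg)
  tab <- table(ex$truth$label[g$replicon == "pA"])
  expect_equal(unname(tab[["up"]]), round(0.23 * 60))
  expect_equal(unname(tab[["down"]]), round(0.07 * 60))
  # no DE at all when fractions are zero
  cfg0 <- sim_config(seed = 6,
                     replicons = tibble::tibble(name = "r1", gene_count = 50L,
                                                gc_fraction = 0.5),
                     de_up_fraction = c(r1 = 0), de_down_fraction = c(r1 = 0),
                     planted_module_size = 5L)
  g0 <- simulate_gene_table(cfg0)
  ex0 <- simulate_expression(g0, cfg0)
  expect_true(all(ex0$truth$label == "unchanged"))
  expect_true(all(ex0$truth$true_log2fc == 0))
})

test_that("array compression scales realized log2 ratios as configured", {
  mean_planted_ratio <- function(compression, seed) {
    cfg <- sim_config(seed = seed,
                      replicons = tibble::tibble(name = "r1", gene_count = 400L,
                                                 gc_fraction = 0.6),
                      de_up_fraction = c(r1 = 0.5), de_down_fraction = c(r1 = 0),
                      fold_change_log2_mean = 2, fold_change_log2_sd = 0,
                      array_compression = compression, planted_module_size = 5L)
    g <- simulate_gene_table(cfg)
    ex <- simulate_expression(g, cfg)
    up <- ex$truth$label == "up"
    i <- ex$intensities
    mean(log2(rowMeans(i[up, 4:6]) / rowMeans(i[up, 1:3])))
  }
  half <- mean_planted_ratio(0.5, seed = 9)   # 200 planted genes at log2FC = 2
  expect_gte(half, 0.85)
  expect_lte(half, 1.15)
  full <- mean_planted_ratio(1, seed = 9)     # identity case: ratio equals truth
  expect_gte(full, 1.9)
  expect_lte(full, 2.1)
})

test_that("identical configurations reproduce byte-identical studies", {
  cfg <- small_sim_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("truth bundle is internally consistent", {
  cfg <- small_sim_config(seed = 12)
  st <- simulate_study(cfg)
  expect_true(all(st$truth$de_labels$gene_id %in% st$genes$gene_id))
  mapped <- st$truth$ortholog_maps$target_gene
  expect_true(all(st$truth$true_target_edges$node_a %in% mapped))
  expect_true(all(st$truth$true_target_edges$node_b %in% mapped))
  expect_length(st$truth$planted_module_nodes, cfg$planted_module_size)
  expect_true(all(st$truth$planted_module_nodes %in% st$genes$gene_id))
  # planted module genes are forced up so the active-module signal exists
  lab <- st$truth$de_labels
  expect_true(all(lab$label[lab$gene_id %in% st$truth$planted_module_nodes] == "up"))
})

test_that("realized per-replicon DE fractions stay within 3 binomial SDs", {
  cfg <- small_sim_config(seed = 13, genes_plasmid = 100L, genes_chr = 400L)
  g <- simulate_gene_table(cfg)
  ex <- simulate_expression(g, cfg)
  for (rep_name in c("pA", "chr")) {
    n <- sum(g$replicon == rep_name)
    p_cfg <- cfg$de_up_fraction[[rep_name]]
    realized <- mean(ex$truth$label[g$replicon == rep_name] == "up")
    expect_lte(abs(realized - p_cfg), 3 * sqrt(p_cfg * (1 - p_cfg) / n))
  }
})
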