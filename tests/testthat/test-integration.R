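# small annotated network used across the overlay/subnetwork tests
toy_annotated <- function(edges, fc, p = NULL, value_a = NULL) {
  net <- merge_networks(edges)
  ids <- names(fc)
  p <- p %||% stats::setNames(rep(0.0005, length(ids)), ids)
  value_a <- value_a %||% stats::setNames(rep(100, length(ids)), ids)
  res <- tibble::tibble(
    gene_id = ids,
    value_a = unname(value_a[ids]),
    value_b = ifelse(is.finite(unname(fc[ids])),
                     unname(value_a[ids]) * unname(fc[ids]), 100),
    log2fc = log2(unname(fc[ids])),
    p = unname(p[ids]),
    q = unname(p[ids]),
    call = "unchanged"
  )
  overlay_expression(net, rnaseq = res)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("overlay attaches fold changes and flags unmeasured nodes", {
  net <- merge_networks(edges_of(c("a", "b"), c("b", "c")))
  res <- tibble::tibble(gene_id = c("a", "b"), value_a = c(10, 10),
                        value_b = c(40, 10), log2fc = c(2, 0),
                        p = c(0.001, 0.9), q = c(0.01, 0.9),
                        call = c("up", "unchanged"))
  ann <- overlay_expression(net, rnaseq = res)$annotation
  expect_equal(ann$fold_change[ann$gene_id == "a"], 4)
  expect_false(ann$measured[ann$gene_id == "c"])
  expect_true(is.na(ann$call[ann$gene_id == "c"]))
  # "both" rule: only genes present on both platforms count as measured
  array_res <- res[1, ]
  both <- overlay_expression(net, rnaseq = res, array = array_res,
                             platform = "both")$annotation
  expect_true(both$measured[both$gene_id == "a"])
  expect_false(both$measured[both$gene_id == "b"])
})

test_that("fold-threshold subnetwork keeps seeds, linkers and 2-seed components", {
  # path s1 - x - s2: x links two seeds and is pulled in
  ann <- toy_annotated(edges_of(c("s1", "x"), c("x", "s2")),
                       fc = c(s1 = 8, x = 1, s2 = 1 / 8))
  sub <- fold_threshold_subnetwork(ann, fold = 5)
  expect_setequal(sub$nodes$gene_id, c("s1", "x", "s2"))
  expect_equal(nrow(sub$edges), 2)
  expect_equal(sort(sub$nodes$role), c("linker", "seed", "seed"))

  # an isolated seed with no second seed in its component is excluded
  ann2 <- toy_annotated(edges_of(c("s1", "x"), c("x", "s2"), c("lone", "y")),
                        fc = c(s1 = 8, x = 1, s2 = 8, lone = 10, y = 1))
  sub2 <- fold_threshold_subnetwork(ann2, fold = 5)
  expect_false("lone" %in% sub2$nodes$gene_id)

  # all nodes seeds on a triangle: the whole triangle survives
  ann3 <- toy_annotated(edges_of(c("a", "b"), c("b", "c"), c("a", "c")),
                        fc = c(a = 6, b = 7, c = 1 / 6))
  sub3 <- fold_threshold_subnetwork(ann3, fold = 5)
  expect_setequal(sub3$nodes$gene_id, c("a", "b", "c"))
  expect_equal(nrow(sub3$edges), 3)

  # no seeds: empty result with a message
  expect_message(
    empty <- fold_threshold_subnetwork(
      toy_annotated(edges_of(c("a", "b")), fc = c(a = 1, b = 2)), fold = 5),
    "no nodes"
  )
  expect_equal(nrow(empty$nodes), 0)
})

test_that("zero and infinity fold-change sentinels respect the expression floor", {
  ann <- toy_annotated(edges_of(c("z", "s"), c("s", "i"), c("i", "z")),
                       fc = c(z = 0, s = 6, i = Inf),
                       value_a = c(z = 50, s = 100, i = 0))
  ann$annotation$value_b[ann$annotation$gene_id == "i"] <- 30
  sub <- fold_threshold_subnetwork(ann, fold = 5, expression_floor = 1)
  expect_setequal(sub$nodes$gene_id, c("z", "s", "i"))
  # below the floor the sentinel no longer seeds
  ann$annotation$value_b[ann$annotation$gene_id == "i"] <- 0.5
  sub2 <- fold_threshold_subnetwork(ann, fold = 5, expression_floor = 1)
  expect_false("i" %in% sub2$nodes$gene_id[sub2$nodes$role == "seed"])
})

test_that("every linker in a result is adjacent to at least two seeds", {
  cfg <- small_sim_config(seed = 51)
  st <- simulate_study(cfg)
  pairs <- find_bbh(st$references$refA$hits$forward,
                    st$references$refA$hits$reverse, organism = "refA")
  net <- merge_networks(suppressMessages(
    transfer_edges(st$references$refA$network$edges, pairs)))
  res <- de_rnaseq(st$expression$counts, st$expression$design, st$genes)
  ann <- overlay_expression(net, rnaseq = res)
  sub <- fold_threshold_subnetwork(ann, fold = 5)
  seeds <- sub$nodes$gene_id[sub$nodes$role == "seed"]
  expect_gte(nrow(sub$nodes), length(seeds))
  for (lk in sub$nodes$gene_id[sub$nodes$role == "linker"]) {
    nbrs <- c(net$edges$node_b[net$edges$node_a == lk],
              net$edges$node_a[net$edges$node_b == lk])
    expect_gte(length(intersect(nbrs, seeds)), 2)
  }
})

test_that("module scoring matches the direct formula", {
  # single node at p = 0.5: z = qnorm(0.5) = 0
  one <- score_module("a", c(a = 0.5), background = c("a"), n_background = 10)
  expect_equal(one$z_a, 0, tolerance = 1e-12)
  # four nodes with z = 1 each: z_a = 4 / sqrt(4) = 2
  p1 <- stats::setNames(rep(1 - stats::pnorm(1), 4), letters[1:4])
  four <- score_module(letters[1:4], p1, n_background = 10)
  expect_equal(four$z_a, 2, tolerance = 1e-9)
  # direct-formula oracle for arbitrary fixed inputs
  p2 <- stats::setNames(c(0.01, 0.2, 0.6), c("x", "y", "z"))
  got <- score_module(c("x", "y"), p2, n_background = 50, seed = 2)
  expect_equal(got$z_a, sum(stats::qnorm(1 - p2[c("x", "y")])) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(got$s_a, (got$z_a - got$mu_k) / got$sigma_k, tolerance = 1e-9)
  # p of exactly 0/1 is clamped, not fatal
  expect_message(score_module("a", c(a = 0, b = 0.5), n_background = 10), "clamped")
})

test_that("background-corrected scores are standardized under the null", {
  p <- withr::with_seed(52, stats::setNames(stats::runif(200), sprintf("n%03d", 1:200)))
  s_a <- vapply(1:300, function(i) {
    nodes <- withr::with_seed(1000 + i, sample(names(p), 8))
    score_module(nodes, p, n_background = 400, seed = 7)$s_a
  }, numeric(1))
  expect_lt(abs(mean(s_a)), 0.15)
  expect_gt(stats::sd(s_a), 0.8)
  expect_lt(stats::sd(s_a), 1.2)
})

test_that("greedy search recovers a planted low-p module", {
  recov <- vapply(1:10, function(s) {
    ids <- sprintf("g%03d", 1:300)
    net <- simulate_reference_network(ids, edge_count = 900,
                                      planted_module_size = 15, seed = s)
    nw <- merge_networks(net$edges)
    p <- withr::with_seed(s + 100,
                          stats::setNames(stats::runif(length(nw$nodes)), nw$nodes))
    in_net <- intersect(net$module_nodes, nw$nodes)
    p[in_net] <- withr::with_seed(s + 200, stats::runif(length(in_net), 1e-6, 1e-3))
    nw$annotation <- tibble::tibble(
      gene_id = nw$nodes, value_a = 1, value_b = 1, fold_change = 1, log2fc = 0,
      p = unname(p[nw$nodes]), q = unname(p[nw$nodes]), call = "unchanged",
      measured = TRUE
    )
    mods <- search_active_modules(nw, max_k = 20, n_background = 300, seed = s)
    jaccard(mods$nodes[[1]], net$module_nodes)
  }, numeric(1))
  expect_true(all(recov >= 0.6))
  expect_gte(mean(recov), 0.8 * 15 / 20)  # >= 80% of planted nodes at max_k 20
})

test_that("null networks score below planted ones and trivial cases work", {
  ids <- sprintf("g%03d", 1:300)
  net <- simulate_reference_network(ids, edge_count = 900,
                                    planted_module_size = 15, seed = 3)
  nw <- merge_networks(net$edges)
  annotate_with <- function(nw, p) {
    nw$annotation <- tibble::tibble(
      gene_id = nw$nodes, value_a = 1, value_b = 1, fold_change = 1, log2fc = 0,
      p = unname(p[nw$nodes]), q = unname(p[nw$nodes]), call = "unchanged",
      measured = TRUE)
    nw
  }
  p_null <- withr::with_seed(61, stats::setNames(stats::runif(length(nw$nodes)),
                                                 nw$nodes))
  p_planted <- p_null
  p_planted[intersect(net$module_nodes, nw$nodes)] <- 1e-5
  null_best <- search_active_modules(annotate_with(nw, p_null), max_k = 20,
                                     n_background = 300, seed = 5)$s_a[1]
  planted_best <- search_active_modules(annotate_with(nw, p_planted), max_k = 20,
                                        n_background = 300, seed = 5)$s_a[1]
  expect_lt(null_best, planted_best)

  single <- merge_networks(edges_of(c("a", "b")))
  single$annotation <- tibble::tibble(gene_id = c("a", "b"), value_a = 1,
                                      value_b = 1, fold_change = 1, log2fc = 0,
                                      p = c(0.001, 0.9), q = c(0.001, 0.9),
                                      call = "unchanged", measured = c(TRUE, FALSE))
  mods <- search_active_modules(single, max_k = 5, n_background = 50, seed = 1)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$nodes[[1]], "a")  # unmeasured neighbours cannot be added
})

test_that("ego subnetworks honour the radius and nest by radius", {
  star <- merge_networks(edges_of(c("hub", "l1"), c("hub", "l2"), c("hub", "l3")))
  expect_setequal(ego_subnetwork(star, "hub", radius = 1)$nodes$gene_id,
                  c("hub", "l1", "l2", "l3"))
  chain <- merge_networks(edges_of(c("a", "b"), c("b", "c"), c("c", "d"),
                                   c("d", "e")))
  two <- ego_subnetwork(chain, "a", radius = 2)
  expect_setequal(two$nodes$gene_id, c("a", "b", "c"))
  expect_equal(nrow(two$edges), 2)
  zero <- ego_subnetwork(chain, "c", radius = 0)
  expect_equal(zero$nodes$gene_id, "c")
  expect_equal(nrow(zero$edges), 0)
  expect_error(ego_subnetwork(chain, "nope"), "unknown node")
  for (r in 0:3) {
    expect_true(all(ego_subnetwork(chain, "b", r)$nodes$gene_id %in%
                      ego_subnetwork(chain, "b", r + 1)$nodes$gene_id))
  }
})

test_that("subnetwork extraction on the packaged fold-change table is stable", {
  nif <- mhk_nif_subnetwork()
  net <- merge_networks(
    simulate_reference_network(nif$gene_id, edge_count = 220,
                               planted_module_size = 20, seed = 99)$edges
  )
  res <- tibble::tibble(
    gene_id = nif$gene_id,
    value_a = 100,
    value_b = 100 * nif$fold_change,
    log2fc = log2(nif$fold_change),
    p = 0.0005, q = 0.0005, call = "unchanged"
  )
  ann <- overlay_expression(net, rnaseq = res)
  s1 <- fold_threshold_subnetwork(ann, fold = 5)
  s2 <- fold_threshold_subnetwork(ann, fold = 5)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  seeds <- s1$nodes$gene_id[s1$nodes$role == "seed"]
  qualifying <- nif$gene_id[nif$fold_change >= 5 | nif$fold_change <= 1 / 5]
  expect_true(all(seeds %in% qualifying))
})
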