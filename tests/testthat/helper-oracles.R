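# Independent brute-force oracles and tiny fixture builders. These deliberately
# re-derive each quantity with plain loops / closed forms so that the vectorized
# implementations are checked against something they do not share code with.

make_hit <- function(query_id, subject_id, evalue = 1e-10, identity = 0.8,
                     alignment_length = 90L, query_length = 100L,
                     subject_length = 100L, bitscore = 100) {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id, identity = identity,
    alignment_length = alignment_length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = alignment_length, sstart = 1L, send = alignment_length,
    evalue = evalue, bitscore = bitscore,
    query_length = query_length, subject_length = subject_length
  )
}

oracle_best_hits <- function(hits, thr) {
  cov <- pmin(1, pmin(hits$alignment_length / hits$query_length,
                      hits$alignment_length / hits$subject_length))
  pass <- hits$evalue < thr$max_evalue & hits$identity >= thr$min_identity &
    cov >= thr$min_coverage & hits$query_id != hits$subject_id
  h <- as.data.frame(hits[pass, , drop = FALSE])
  out <- list()
  for (q in unique(h$query_id)) {
    hq <- h[h$query_id == q, , drop = FALSE]
    hq <- hq[order(hq$evalue, -hq$bitscore, hq$subject_id), , drop = FALSE]
    out[[q]] <- hq$subject_id[1]
  }
  out
}

oracle_bbh <- function(forward, reverse, thr = hit_thresholds()) {
  bf <- oracle_best_hits(forward, thr)
  br <- oracle_best_hits(reverse, thr)
  pairs <- stats::setNames(character(0), character(0))
  for (a in sort(names(bf))) {
    b <- bf[[a]]
    if (!is.null(br[[b]]) && br[[b]] == a) pairs[a] <- b
  }
  tibble::tibble(target_gene = as.character(names(pairs)),
                 reference_gene = unname(pairs))
}

# step-up BH by the definition: q_i = min over ranks j >= rank(i) of p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) min(sorted[i:m] * m / (i:m)),
                     numeric(1))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact hypergeometric upper tail by direct summation over outcomes
oracle_hyper_tail <- function(M, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(M - K, n - js)) / choose(M, n)
}

# random small hit tables with deliberate ties (same e-value and bitscore) and
# hits that fail exactly one of the three thresholds
random_toy_hits <- function(seed, n_target = 5, n_reference = 5) {
  withr::with_seed(seed, {
    tg <- paste0("t", seq_len(n_target))
    rg <- paste0("r", seq_len(n_reference))
    mk <- function(qs, ss) {
      grid <- expand.grid(q = qs, s = ss, stringsAsFactors = FALSE)
      grid <- grid[stats::runif(nrow(grid)) < 0.6, , drop = FALSE]
      n <- nrow(grid)
      make_hit(grid$q, grid$s,
               evalue = sample(c(1e-30, 1e-20, 1e-10, 1e-4), n, replace = TRUE,
                               prob = c(0.3, 0.3, 0.3, 0.1)),
               identity = sample(c(0.2, 0.5, 0.9), n, replace = TRUE,
                                 prob = c(0.15, 0.4, 0.45)),
               alignment_length = sample(c(60L, 90L), n, replace = TRUE,
                                         prob = c(0.2, 0.8)),
               bitscore = sample(c(50, 100), n, replace = TRUE))
    }
    list(forward = mk(tg, rg), reverse = mk(rg, tg))
  })
}

# edge tibble shorthand
edges_of <- function(...) {
  pairs <- list(...)
  canonical_edge(vapply(pairs, `[`, character(1), 1),
                 vapply(pairs, `[`, character(1), 2))
}

small_sim_config <- function(seed = 1L, genes_plasmid = 60L, genes_chr = 240L,
                             planted_module_size = 12L, ...) {
  sim_config(
    seed = seed,
    replicons = tibble::tibble(name = c("pA", "chr"),
                               gene_count = c(genes_plasmid, genes_chr),
                               gc_fraction = c(0.59, 0.63)),
    de_up_fraction = c(pA = 0.23, chr = 0.11),
    de_down_fraction = c(pA = 0.07, chr = 0.15),
    reference_edge_count = 600L,
    planted_module_size = planted_module_size,
    ...
  )
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
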