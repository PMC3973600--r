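#' Simulation configuration for a two-condition bacteroid-style study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate the
#' structure of a rhizobial bacteroid vs free-living comparison: three replicons
#' (two symbiosis plasmids with lower GC and strong plasmid-biased up-regulation,
#' one chromosome), planted orthologs against two reference organisms, reference
#' interaction networks carrying one planted high-DE module, negative-binomial
#' sequencing counts and log-normal array intensities whose true log2 ratios are
#' shrunk by a compression factor.
#'
#' @param seed Integer seed; together with the other fields it fully determines
#'   every simulated output.
#' @param replicons Tibble with columns `name`, `gene_count`, `gc_fraction`.
#' @param de_up_fraction,de_down_fraction Named numeric vectors (one entry per
#'   replicon) giving the fraction of genes planted as up-/down-regulated.
#' @param fold_change_log2_mean,fold_change_log2_sd Mean and SD of the absolute
#'   planted log2 fold change.
#' @param n_replicates Replicates per condition (>= 2).
#' @param nb_dispersion Negative-binomial dispersion (counts have
#'   variance mu + dispersion * mu^2).
#' @param array_compression Scalar in \[0, 1\] multiplying true log2 ratios on
#'   the array platform (dynamic-range compression).
#' @param ortholog_fraction Fraction of target genes given a planted ortholog in
#'   each reference proteome.
#' @param hit_noise_rate Number of spurious similarity hits generated per target
#'   gene (as a fraction of the target gene count).
#' @param reference_edge_count Edges in each simulated reference network.
#' @param planted_module_size Size of the connected module planted in the first
#'   reference network.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       replicons = tibble::tibble(
                         name = c("pMHa", "pMHb", "chromosome"),
                         gene_count = c(257L, 447L, 6562L),
                         gc_fraction = c(0.59, 0.59, 0.63)
                       ),
                       de_up_fraction = c(pMHa = 0.2296, pMHb = 0.2349, chromosome = 0.1070),
                       de_down_fraction = c(pMHa = 0.0700, pMHb = 0.0582, chromosome = 0.1456),
                       fold_change_log2_mean = 2,
                       fold_change_log2_sd = 0.5,
                       n_replicates = 3L,
                       nb_dispersion = 0.01,
                       array_compression = 0.5,
                       ortholog_fraction = 0.7,
                       hit_noise_rate = 0.1,
                       reference_edge_count = 3000L,
                       planted_module_size = 25L) {
  cfg <- list(
    seed = as.integer(seed),
    replicons = tibble::as_tibble(replicons),
    de_up_fraction = de_up_fraction,
    de_down_fraction = de_down_fraction,
    fold_change_log2_mean = fold_change_log2_mean,
    fold_change_log2_sd = fold_change_log2_sd,
    n_replicates = as.integer(n_replicates),
    nb_dispersion = nb_dispersion,
    array_compression = array_compression,
    ortholog_fraction = ortholog_fraction,
    hit_noise_rate = hit_noise_rate,
    reference_edge_count = as.integer(reference_edge_count),
    planted_module_size = as.integer(planted_module_size)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  r <- cfg$replicons
  if (!all(c("name", "gene_count", "gc_fraction") %in% names(r))) {
    abort_bad_input("replicons needs columns name, gene_count, gc_fraction")
  }
  if (any(r$gene_count <= 0)) abort_bad_input("replicon gene counts must be positive")
  if (any(r$gc_fraction < 0 | r$gc_fraction > 1)) abort_bad_input("gc_fraction must lie in [0, 1]")
  fracs <- c(cfg$de_up_fraction, cfg$de_down_fraction,
             cfg$array_compression, cfg$ortholog_fraction)
  if (any(fracs < 0 | fracs > 1)) abort_bad_input("fractions must lie in [0, 1]")
  for (nm in r$name) {
    up <- vec_get(cfg$de_up_fraction, nm) %||% abort_bad_input(paste0("missing de_up_fraction for ", nm))
    dn <- vec_get(cfg$de_down_fraction, nm) %||% abort_bad_input(paste0("missing de_down_fraction for ", nm))
    if (up + dn > 1) abort_bad_input("up + down fraction exceeds 1 for a replicon")
  }
  if (cfg$hit_noise_rate < 0 || cfg$hit_noise_rate > 1) abort_bad_input("hit_noise_rate must lie in [0, 1]")
  if (cfg$n_replicates < 2) abort_bad_input("n_replicates must be >= 2")
  if (cfg$nb_dispersion <= 0) abort_bad_input("nb_dispersion must be positive")
  if (sum(r$gene_count) < cfg$planted_module_size) {
    abort_bad_input("gene_count must be at least planted_module_size")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat("  replicons:", paste0(x$replicons$name, " (", x$replicons$gene_count, ")", collapse = ", "), "\n")
  cat("  replicates:", x$n_replicates, " dispersion:", x$nb_dispersion,
      " compression:", x$array_compression, "\n")
  cat("  orthologs:", x$ortholog_fraction, " noise:", x$hit_noise_rate,
      " ref edges:", x$reference_edge_count, " module:", x$planted_module_size, "\n")
  invisible(x)
}

cog_letters <- function() strsplit("JKLDVTMNUOCGEFHIPQRS", "")[[1]]

#' Simulate an annotated gene table with nucleotide sequences
#'
#' Genes are laid end-to-end along each replicon (1-based inclusive
#' coordinates, no overlaps). Each gene receives a random sequence whose GC
#' content matches the replicon's configured `gc_fraction` in expectation, a
#' strand, and a COG category (single letters; occasionally two-letter strings;
#' some genes uncategorized, encoded "-").
#'
#' @param config A [sim_config()].
#' @param id_prefix Prefix for generated gene identifiers.
#' @return Tibble with columns `gene_id`, `replicon`, `start`, `end`, `strand`,
#'   `length`, `cog_category`, `product`, `sequence`.
#' @export
simulate_gene_table <- function(config, id_prefix = "MHK") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 11L), {
    reps <- config$replicons
    out <- vector("list", nrow(reps))
    offset <- 0L
    for (i in seq_len(nrow(reps))) {
      n <- reps$gene_count[i]
      gc <- reps$gc_fraction[i]
      lengths <- 3L * sample(100:500, n, replace = TRUE)
      start <- cumsum(c(1L, utils::head(lengths, -1L)))
      seqs <- vapply(lengths, function(L) {
        paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                     prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
              collapse = "")
      }, character(1))
      cog_pool <- cog_letters()
      cog <- sample(cog_pool, n, replace = TRUE)
      two <- stats::runif(n) < 0.05
      cog[two] <- paste0(cog[two], sample(cog_pool, sum(two), replace = TRUE))
      cog[stats::runif(n) < 0.15] <- "-"
      out[[i]] <- tibble::tibble(
        gene_id = sprintf("%s_%05d", id_prefix, offset + seq_len(n)),
        replicon = reps$name[i],
        start = start,
        end = start + lengths - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        length = lengths,
        cog_category = cog,
        product = "hypothetical protein",
        sequence = seqs
      )
      offset <- offset + n
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate reciprocal similarity hits with planted orthologs
#'
#' A fraction of target genes is mapped one-to-one onto reference genes; each
#' planted pair receives a forward and a reverse hit that pass the default
#' interolog filtering thresholds (e-value < 1e-5, identity >= 0.3, coverage of
#' both sequences >= 0.7) with e-values well below the noise floor. Spurious
#' hits are then added: half fail the identity threshold outright, half pass
#' all thresholds but are non-reciprocal (directed at an already-mapped
#' reference gene whose best reverse hit is its planted partner), so planted
#' orthology is recoverable by bidirectional best hits.
#'
#' @param target_genes,reference_genes Gene tables (need `gene_id`, `length`).
#' @param ortholog_fraction Fraction of target genes with a planted ortholog.
#' @param hit_noise_rate Spurious hits per target gene.
#' @param seed Integer seed.
#' @return List with `forward`, `reverse` (similarity-hit tibbles) and
#'   `ortholog_map` (tibble `target_gene`, `reference_gene`).
#' @export
simulate_similarity_hits <- function(target_genes, reference_genes,
                                     ortholog_fraction = 0.7,
                                     hit_noise_rate = 0.1,
                                     seed = 1L) {
  if (nrow(target_genes) == 0 || nrow(reference_genes) == 0) {
    abort_bad_input("both gene lists must be non-empty")
  }
  if (ortholog_fraction < 0 || ortholog_fraction > 1) {
    abort_bad_input("ortholog_fraction must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    t_len <- stats::setNames(pmax(50L, target_genes$length %/% 3L), target_genes$gene_id)
    r_len <- stats::setNames(pmax(50L, reference_genes$length %/% 3L), reference_genes$gene_id)
    n_orth <- round(ortholog_fraction * nrow(target_genes))
    n_orth <- min(n_orth, nrow(reference_genes))
    tg <- sample(target_genes$gene_id, n_orth)
    rg <- sample(reference_genes$gene_id, n_orth)
    omap <- tibble::tibble(target_gene = tg, reference_gene = rg) |>
      dplyr::arrange(.data$target_gene)

    planted_hit <- function(q, s, qlen, slen) {
      n <- length(q)
      aln <- ceiling(0.85 * pmax(qlen, slen))
      ident <- stats::runif(n, 0.35, 0.95)
      tibble::tibble(
        query_id = q, subject_id = s,
        identity = ident,
        alignment_length = as.integer(aln),
        mismatch = as.integer(round((1 - ident) * aln)),
        gapopen = 0L,
        qstart = 1L, qend = pmin(as.integer(aln), qlen),
        sstart = 1L, send = pmin(as.integer(aln), slen),
        evalue = 10^(-stats::runif(n, 20, 80)),
        bitscore = round(50 + ident * aln, 1),
        query_length = qlen, subject_length = slen
      )
    }
    fwd <- planted_hit(omap$target_gene, omap$reference_gene,
                       unname(t_len[omap$target_gene]), unname(r_len[omap$reference_gene]))
    rev <- planted_hit(omap$reference_gene, omap$target_gene,
                       unname(r_len[omap$reference_gene]), unname(t_len[omap$target_gene]))

    n_noise <- round(hit_noise_rate * nrow(target_genes))
    if (n_noise > 0) {
      qn <- sample(target_genes$gene_id, n_noise, replace = TRUE)
      # weak hits: pass coverage/e-value but fail the identity threshold
      sn_weak <- sample(reference_genes$gene_id, n_noise, replace = TRUE)
      weak <- planted_hit(qn, sn_weak, unname(t_len[qn]), unname(r_len[sn_weak]))
      weak$identity <- stats::runif(n_noise, 0.05, 0.25)
      weak$evalue <- 10^(-stats::runif(n_noise, 6, 10))
      weak$bitscore <- round(30 + weak$identity * weak$alignment_length, 1)
      fwd <- dplyr::bind_rows(fwd, weak)
      # passing but non-reciprocal hits, only meaningful when orthologs exist:
      # aimed at mapped reference genes, with e-values above every planted hit
      if (n_orth > 0) {
        qp <- sample(target_genes$gene_id, n_noise, replace = TRUE)
        sp <- sample(omap$reference_gene, n_noise, replace = TRUE)
        keep <- !paste(qp, sp) %in% paste(omap$target_gene, omap$reference_gene)
        if (any(keep)) {
          nonrec <- planted_hit(qp[keep], sp[keep],
                                unname(t_len[qp[keep]]), unname(r_len[sp[keep]]))
          nonrec$evalue <- 10^(-stats::runif(sum(keep), 6, 9))
          fwd <- dplyr::bind_rows(fwd, nonrec)
        }
      }
    }
    list(forward = fwd, reverse = rev, ortholog_map = omap)
  })
}

# unrank linear indices 1..n(n-1)/2 into unordered pairs (i < j) of 1..n
pair_unrank <- function(k, n) {
  # i is the largest row whose block of (n - i) pairs starts at or before k
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  before <- (i - 1) * n - i * (i - 1) / 2
  j <- k - before + i
  cbind(as.integer(i), as.integer(j))
}

#' Simulate a reference interaction network with a planted module
#'
#' Builds a simple undirected graph (no self-loops, no parallel edges) on the
#' reference gene set. A connected module of `planted_module_size` genes is
#' planted first as a random spanning tree (its edges count toward
#' `edge_count`); remaining edges are sampled uniformly from the unused pairs.
#'
#' @param reference_genes Gene table or character vector of gene ids.
#' @param edge_count Total number of edges.
#' @param planted_module_size Size of the planted connected module (0 or 1
#'   plants nothing).
#' @param seed Integer seed.
#' @param module_nodes Optional gene ids to use as the planted module (sampled
#'   when `NULL`).
#' @return List with `edges` (canonical tibble `node_a`, `node_b`) and
#'   `module_nodes` (character).
#' @export
simulate_reference_network <- function(reference_genes, edge_count,
                                       planted_module_size = 0L, seed = 1L,
                                       module_nodes = NULL) {
  ids <- if (is.character(reference_genes)) reference_genes else reference_genes$gene_id
  n <- length(ids)
  max_edges <- n * (n - 1) / 2
  if (edge_count > max_edges) abort_bad_input("edge_count exceeds the maximum for a simple graph")
  tree_edges <- max(0L, as.integer(planted_module_size) - 1L)
  if (edge_count < tree_edges) {
    abort_bad_input("edge_count too small to connect the planted module")
  }
  withr::with_seed(as.integer(seed), {
    if (!is.null(module_nodes)) {
      stopifnot(all(module_nodes %in% ids))
      mod <- module_nodes
    } else {
      mod <- if (planted_module_size > 0) sample(ids, planted_module_size) else character(0)
    }
    edge_idx <- integer(0)
    if (length(mod) >= 2) {
      mod_pos <- match(mod, ids)
      parents <- vapply(2:length(mod_pos), function(i) {
        mod_pos[sample.int(i - 1L, 1L)]
      }, integer(1))
      a <- pmin(mod_pos[-1], parents)
      b <- pmax(mod_pos[-1], parents)
      edge_idx <- (a - 1) * n - a * (a - 1) / 2 + (b - a)
    }
    extra <- edge_count - length(edge_idx)
    if (extra > 0) {
      if (edge_count == max_edges) {
        edge_idx <- seq_len(max_edges)
      } else {
        pool <- edge_idx
        while (length(pool) < edge_count) {
          cand <- sample(max_edges, min(max_edges, edge_count + length(pool) + 10L))
          pool <- c(pool, setdiff(cand, pool))
        }
        edge_idx <- pool[seq_len(edge_count)]
      }
    }
    if (length(edge_idx) == 0) {
      edges <- tibble::tibble(node_a = character(0), node_b = character(0))
    } else {
      ij <- pair_unrank(sort(edge_idx), n)
      edges <- canonical_edge(ids[ij[, 1]], ids[ij[, 2]])
    }
    list(edges = edges, module_nodes = sort(mod))
  })
}

#' Simulate two-condition sequencing counts and array intensities
#'
#' Plants up-/down-regulated genes per replicon according to the configured
#' fractions, draws negative-binomial counts (condition-B means scaled by
#' 2^(true log2 fold change)) and log-normal intensities whose true log2 ratio
#' is multiplied by `array_compression`.
#'
#' @param gene_table Gene table from [simulate_gene_table()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to a sub-seed of `config$seed`).
#' @param force_up Gene ids forced to be strongly up-regulated (used by
#'   [simulate_study()] to make the planted network module differentially
#'   expressed); they receive log2 fold changes around
#'   `max(fold_change_log2_mean, 3)`.
#' @return List with `counts` and `intensities` (genes x 2*n_replicates
#'   matrices), `design` (tibble `sample`, `condition`) and `truth` (tibble
#'   `gene_id`, `label`, `true_log2fc`).
#' @export
simulate_expression <- function(gene_table, config, seed = NULL, force_up = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion <= 0) abort_bad_input("nb_dispersion must be positive")
  seed <- seed %||% derive_seed(config$seed, 17L)
  withr::with_seed(as.integer(seed), {
    n <- nrow(gene_table)
    label <- rep("unchanged", n)
    for (nm in unique(gene_table$replicon)) {
      idx <- which(gene_table$replicon == nm)
      n_up <- round((vec_get(config$de_up_fraction, nm) %||% 0) * length(idx))
      n_dn <- round((vec_get(config$de_down_fraction, nm) %||% 0) * length(idx))
      pick <- sample(idx, n_up + n_dn)
      label[pick[seq_len(n_up)]] <- "up"
      if (n_dn > 0) label[pick[n_up + seq_len(n_dn)]] <- "down"
    }
    label[gene_table$gene_id %in% force_up] <- "up"
    mag <- abs(stats::rnorm(n, config$fold_change_log2_mean, config$fold_change_log2_sd))
    mag <- pmax(mag, 1)   # planted genes are truly differential (>= 2-fold)
    lfc <- ifelse(label == "up", mag, ifelse(label == "down", -mag, 0))
    forced <- gene_table$gene_id %in% force_up
    if (any(forced)) {
      lfc[forced] <- abs(stats::rnorm(sum(forced), max(config$fold_change_log2_mean, 3), 0.3))
    }

    base_mean <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.2)
    r <- config$n_replicates
    size <- 1 / config$nb_dispersion
    mu_a <- base_mean
    mu_b <- base_mean * 2^lfc
    counts <- cbind(
      matrix(stats::rnbinom(n * r, mu = rep(mu_a, r), size = size), nrow = n),
      matrix(stats::rnbinom(n * r, mu = rep(mu_b, r), size = size), nrow = n)
    )
    log2_a <- log2(base_mean) + 6
    log2_b <- log2_a + config$array_compression * lfc
    noise <- function() matrix(stats::rnorm(n * r, 0, 0.25), nrow = n)
    intensities <- cbind(
      2^(matrix(rep(log2_a, r), nrow = n) + noise()),
      2^(matrix(rep(log2_b, r), nrow = n) + noise())
    )
    samples <- c(paste0("free_living_", seq_len(r)), paste0("bacteroid_", seq_len(r)))
    dimnames(counts) <- list(gene_table$gene_id, samples)
    dimnames(intensities) <- list(gene_table$gene_id, samples)
    list(
      counts = counts,
      intensities = intensities,
      design = tibble::tibble(
        sample = samples,
        condition = rep(c("free_living", "bacteroid"), each = r)
      ),
      truth = tibble::tibble(
        gene_id = gene_table$gene_id,
        label = label,
        true_log2fc = lfc
      )
    )
  })
}

#' Simulate a complete synthetic study with known truth
#'
#' Generates the target gene table, two reference proteomes with planted
#' orthologs and reciprocal similarity hits, one reference network per
#' organism (the first carries a planted connected module placed among
#' ortholog-mapped genes, which is forced to be up-regulated in the
#' expression data), and dual-platform expression matrices.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `references` (per-organism list of `genes`,
#'   `hits`, `network`), `expression`, and `truth` (ortholog maps, DE labels,
#'   implied target edge set, planted module nodes in target ids).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_gene_table(config)
  n_target <- nrow(genes)
  ref_sizes <- c(refA = max(10L, round(0.9 * n_target)), refB = max(10L, round(0.6 * n_target)))
  references <- list()
  truth_edges <- list()
  omap_list <- list()
  for (i in seq_along(ref_sizes)) {
    org <- names(ref_sizes)[i]
    ref_cfg <- sim_config(
      seed = derive_seed(config$seed, 100L + i),
      replicons = tibble::tibble(name = org, gene_count = ref_sizes[[i]], gc_fraction = 0.55),
      de_up_fraction = stats::setNames(0, org),
      de_down_fraction = stats::setNames(0, org),
      planted_module_size = 0L
    )
    ref_genes <- simulate_gene_table(ref_cfg, id_prefix = toupper(org))
    hits <- simulate_similarity_hits(
      genes, ref_genes,
      ortholog_fraction = config$ortholog_fraction,
      hit_noise_rate = config$hit_noise_rate,
      seed = derive_seed(config$seed, 200L + i)
    )
    module_nodes <- NULL
    if (i == 1 && config$planted_module_size > 0) {
      mapped <- hits$ortholog_map$reference_gene
      if (length(mapped) < config$planted_module_size) {
        abort_bad_input("too few mapped genes to plant the module; raise ortholog_fraction")
      }
      module_nodes <- withr::with_seed(derive_seed(config$seed, 300L + i),
                                       sample(mapped, config$planted_module_size))
    }
    net <- simulate_reference_network(
      ref_genes, config$reference_edge_count,
      planted_module_size = if (i == 1) config$planted_module_size else 0L,
      seed = derive_seed(config$seed, 400L + i),
      module_nodes = module_nodes
    )
    references[[org]] <- list(genes = ref_genes, hits = hits, network = net)
    omap_list[[org]] <- dplyr::mutate(hits$ortholog_map, organism = org)
    # target edges implied by this reference network (computed directly here,
    # independently of the interolog-transfer pipeline)
    m <- stats::setNames(hits$ortholog_map$target_gene, hits$ortholog_map$reference_gene)
    a <- unname(m[net$edges$node_a])
    b <- unname(m[net$edges$node_b])
    keep <- !is.na(a) & !is.na(b) & a != b
    truth_edges[[org]] <- unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "\t"))
  }
  all_edges <- sort(unique(unlist(truth_edges)))
  parts <- strsplit(all_edges, "\t", fixed = TRUE)
  true_target_edges <- tibble::tibble(
    node_a = vapply(parts, `[`, character(1), 1),
    node_b = vapply(parts, `[`, character(1), 2)
  )
  m1 <- references[[1]]$hits$ortholog_map
  planted_target <- sort(unname(
    stats::setNames(m1$target_gene, m1$reference_gene)[references[[1]]$network$module_nodes]
  ))
  expression <- simulate_expression(genes, config, force_up = planted_target)
  list(
    genes = genes,
    references = references,
    expression = expression,
    truth = list(
      ortholog_maps = dplyr::bind_rows(omap_list),
      de_labels = expression$truth,
      true_target_edges = true_target_edges,
      planted_module_nodes = planted_target
    )
  )
}
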