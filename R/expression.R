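#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * C / (N * L)` for `C` reads on a gene of `L` bases in a library
#' of `N` mapped reads; invariant under common scaling of `C` and `N`.
#'
#' @param count Read counts (non-negative).
#' @param total_mapped Library sizes (positive).
#' @param gene_length Gene lengths in bases (positive).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, total_mapped, gene_length) {
  if (any(total_mapped <= 0)) abort_bad_input("total_mapped must be positive")
  if (any(gene_length <= 0)) abort_bad_input("gene_length must be positive")
  if (any(count < 0)) abort_bad_input("count must be non-negative")
  1e9 * count / (total_mapped * gene_length)
}

#' Exact binomial test for a two-library count comparison
#'
#' Conditional on the pooled count `c1 + c2`, the count in library 1 is
#' binomial with success probability `N1 / (N1 + N2)` under the null of equal
#' relative expression. The two-sided p-value sums the probabilities of all
#' outcomes at most as likely as the observed one (the classic exact test for
#' digital expression data). Gene pairs with no reads at all get p = 1.
#'
#' @param c1,c2 Pooled condition counts (vectors, non-negative integers).
#' @param N1,N2 Library sizes (positive).
#' @return Numeric vector of two-sided p-values.
#' @export
count_test_pvalue <- function(c1, c2, N1, N2) {
  if (any(c1 < 0 | c2 < 0)) abort_bad_input("counts must be non-negative")
  if (any(N1 <= 0 | N2 <= 0)) abort_bad_input("library sizes must be positive")
  n <- max(length(c1), length(c2), length(N1), length(N2))
  c1 <- rep_len(as.numeric(c1), n); c2 <- rep_len(as.numeric(c2), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  empty <- (c1 + c2) == 0
  if (any(empty)) message(sum(empty), " gene(s) with zero pooled counts: p set to 1")
  p <- rep(1, n)
  idx <- which(!empty)
  p[idx] <- vapply(idx, function(i) {
    stats::binom.test(round(c1[i]), round(c1[i] + c2[i]),
                      p = N1[i] / (N1[i] + N2[i]))$p.value
  }, numeric(1))
  pmin(p, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort_bad_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' SAM d-statistic
#'
#' The moderated t-like statistic of Significance Analysis of Microarrays:
#' `d = (mean_b - mean_a) / (s + s0)` with the pooled standard error
#' `s = sqrt((1/n_a + 1/n_b) * (SS_a + SS_b) / (n_a + n_b - 2))` and fudge
#' constant `s0` guarding against small denominators.
#'
#' @param values_a,values_b Replicate vectors (length >= 2 each).
#' @param s0 Fudge constant (>= 0).
#' @return The d statistic (scalar).
#' @export
sam_d_statistic <- function(values_a, values_b, s0 = 0) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort_bad_input("need at least 2 replicates per group")
  }
  na <- length(values_a); nb <- length(values_b)
  ss <- sum((values_a - mean(values_a))^2) + sum((values_b - mean(values_b))^2)
  s <- sqrt((1 / na + 1 / nb) * ss / (na + nb - 2))
  (mean(values_b) - mean(values_a)) / (s + s0)
}

#' Parameters for the SAM permutation test
#'
#' @param n_permutations Number of label permutations (>= 1).
#' @param s0 Fudge constant; `NULL` means the median of gene-wise pooled
#'   standard errors, computed from the data.
#' @param seed Seed for permutation sampling.
#' @return A `sam_params` list.
#' @export
sam_params <- function(n_permutations = 1000L, s0 = NULL, seed = 1L) {
  if (n_permutations < 1) abort_bad_input("n_permutations must be >= 1")
  structure(list(n_permutations = as.integer(n_permutations), s0 = s0,
                 seed = as.integer(seed)),
            class = "sam_params")
}

# gene-wise d for every column-assignment in one pass
sam_d_matrix <- function(x, idx_a, idx_b, s0) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(x[, idx_a, drop = FALSE])
  mb <- rowMeans(x[, idx_b, drop = FALSE])
  ssa <- rowSums((x[, idx_a, drop = FALSE] - ma)^2)
  ssb <- rowSums((x[, idx_b, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  list(d = (mb - ma) / (s + s0), s = s)
}

#' SAM-style permutation test over an intensity matrix
#'
#' Computes the gene-wise d-statistic and a permutation p-value of |d| over
#' relabellings of the sample-to-condition assignment. When the requested
#' number of permutations reaches the number of distinct assignments, all of
#' them are enumerated (p = fraction of assignments, including the observed
#' one, with |d*| >= |d|); otherwise assignments are sampled and the add-one
#' corrected p = (b + 1) / (B + 1) is used. q-values are Benjamini-Hochberg.
#'
#' @param intensities Genes x samples matrix (rownames = gene ids) or a data
#'   frame with a `gene_id` column.
#' @param groups Condition label per sample column (two levels); the second
#'   level, in the order of appearance, is the "b" (numerator) condition.
#' @param params A [sam_params()].
#' @return Tibble (`gene_id`, `d`, `p`, `q`).
#' @export
sam_test <- function(intensities, groups, params = sam_params()) {
  x <- as_expr_matrix(intensities)
  groups <- as.character(groups)
  stopifnot(ncol(x) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) abort_bad_input("groups must have exactly two levels")
  idx_a <- which(groups == lev[1]); idx_b <- which(groups == lev[2])
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    abort_bad_input("need at least 2 replicates per group")
  }
  n <- ncol(x)
  obs <- sam_d_matrix(x, idx_a, idx_b, s0 = 0)
  s0 <- params$s0 %||% stats::median(obs$s)
  d_obs <- sam_d_matrix(x, idx_a, idx_b, s0)$d

  n_distinct <- choose(n, length(idx_a))
  if (params$n_permutations >= n_distinct) {
    message("enumerating all ", n_distinct, " distinct label assignments")
    combos <- utils::combn(n, length(idx_a), simplify = FALSE)
    ge <- numeric(nrow(x))
    for (cmb in combos) {
      d_perm <- sam_d_matrix(x, cmb, setdiff(seq_len(n), cmb), s0)$d
      ge <- ge + (abs(d_perm) >= abs(d_obs) - 1e-12)
    }
    p <- ge / n_distinct
  } else {
    perms <- withr::with_seed(params$seed, {
      replicate(params$n_permutations, sample(seq_len(n), length(idx_a)),
                simplify = FALSE)
    })
    b <- numeric(nrow(x))
    for (cmb in perms) {
      d_perm <- sam_d_matrix(x, cmb, setdiff(seq_len(n), cmb), s0)$d
      b <- b + (abs(d_perm) >= abs(d_obs) - 1e-12)
    }
    p <- (b + 1) / (params$n_permutations + 1)
  }
  p <- unname(pmin(p, 1))
  tibble::tibble(gene_id = rownames(x), d = unname(d_obs), p = p, q = bh_fdr(p))
}

#' Differential-expression calling thresholds
#'
#' Defaults: absolute log2 fold change at least 1 (ratio >= 2, inclusive) on
#' both platforms; FDR q <= 0.001 for the sequencing arm; p/q <= 0.05 for the
#' array arm; and an expression floor of 1 for the nonzero side when the other
#' side is zero (below it no call is made).
#'
#' @param min_abs_log2fc Inclusive bound on |log2 fold change|.
#' @param max_q_rnaseq Inclusive bound on the RNA-Seq q-value.
#' @param max_pq_array Inclusive bound on the array q-value.
#' @param expression_floor Minimum expression of the nonzero side in
#'   zero-vs-nonzero comparisons.
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(min_abs_log2fc = 1, max_q_rnaseq = 0.001,
                          max_pq_array = 0.05, expression_floor = 1) {
  if (min_abs_log2fc <= 0 || max_q_rnaseq <= 0 || max_pq_array <= 0 ||
      expression_floor <= 0) {
    abort_bad_input("thresholds must be positive")
  }
  structure(list(min_abs_log2fc = min_abs_log2fc, max_q_rnaseq = max_q_rnaseq,
                 max_pq_array = max_pq_array, expression_floor = expression_floor),
            class = "de_thresholds")
}

#' Classify genes as up, down or unchanged
#'
#' A gene is called up when `log2fc >= min_abs_log2fc` and its q-value passes
#' the platform's bound (`max_q_rnaseq` for the sequencing arm, `max_pq_array`
#' for the array arm); down symmetrically. Zero-vs-nonzero genes carry infinite
#' log2 fold changes and are called only when the nonzero side reaches the
#' expression floor; genes unexpressed in both conditions stay unchanged.
#'
#' @param results Tibble with columns `value_a`, `value_b`, `log2fc`, `q`.
#' @param thresholds A [de_thresholds()].
#' @param platform `"rnaseq"` or `"array"`.
#' @return `results` with a `call` column (`"up"`, `"down"`, `"unchanged"`).
#' @export
classify_de <- function(results, thresholds = de_thresholds(),
                        platform = c("rnaseq", "array")) {
  platform <- match.arg(platform)
  q_bound <- if (platform == "rnaseq") thresholds$max_q_rnaseq else thresholds$max_pq_array
  sig <- !is.na(results$q) & results$q <= q_bound
  lfc <- results$log2fc
  floor_ok <- rep(TRUE, nrow(results))
  zero_a <- results$value_a == 0 & results$value_b > 0
  zero_b <- results$value_b == 0 & results$value_a > 0
  floor_ok[zero_a] <- results$value_b[zero_a] >= thresholds$expression_floor
  floor_ok[zero_b] <- results$value_a[zero_b] >= thresholds$expression_floor
  both_zero <- results$value_a == 0 & results$value_b == 0
  call <- dplyr::case_when(
    both_zero | !sig | !floor_ok ~ "unchanged",
    lfc >= thresholds$min_abs_log2fc ~ "up",
    lfc <= -thresholds$min_abs_log2fc ~ "down",
    .default = "unchanged"
  )
  dplyr::mutate(results, call = call)
}

#' RNA-Seq differential expression: RPKM levels + exact count test
#'
#' Expression level per condition is the mean over replicates of per-sample
#' RPKM (per-sample library size = column sum). The test pools counts within
#' each condition and applies the exact binomial test of
#' [count_test_pvalue()]; q-values are Benjamini-Hochberg across genes and
#' calls follow the sequencing-arm thresholds. The log2 fold change is
#' bacteroid-style condition B over condition A (+/-Inf when one side is 0).
#'
#' @param counts Genes x samples count matrix (rownames = gene ids) or data
#'   frame with a `gene_id` column.
#' @param design Tibble with columns `sample`, `condition` (two levels).
#' @param gene_table Gene table supplying `gene_id` and `length`.
#' @param thresholds A [de_thresholds()].
#' @param conditions Optional length-2 character: (A, B). Defaults to the
#'   order of appearance in `design`.
#' @return Tibble (`gene_id`, `value_a`, `value_b`, `log2fc`, `p`, `q`,
#'   `call`).
#' @export
de_rnaseq <- function(counts, design, gene_table, thresholds = de_thresholds(),
                      conditions = NULL) {
  x <- as_expr_matrix(counts)
  conditions <- conditions %||% unique(design$condition)
  stopifnot(length(conditions) == 2)
  samples_a <- design$sample[design$condition == conditions[1]]
  samples_b <- design$sample[design$condition == conditions[2]]
  stopifnot(all(c(samples_a, samples_b) %in% colnames(x)))
  len <- stats::setNames(gene_table$length, gene_table$gene_id)[rownames(x)]
  if (any(is.na(len))) abort_bad_input("counts contain genes absent from gene_table")
  lib <- colSums(x)
  rpkm_mat <- 1e9 * sweep(x, 2, lib, "/") / as.numeric(len)
  value_a <- rowMeans(rpkm_mat[, samples_a, drop = FALSE])
  value_b <- rowMeans(rpkm_mat[, samples_b, drop = FALSE])
  c1 <- rowSums(x[, samples_a, drop = FALSE])
  c2 <- rowSums(x[, samples_b, drop = FALSE])
  N1 <- sum(lib[samples_a]); N2 <- sum(lib[samples_b])
  p <- count_test_pvalue(c1, c2, N1, N2)
  res <- tibble::tibble(
    gene_id = rownames(x),
    value_a = value_a,
    value_b = value_b,
    log2fc = log2(value_b / value_a),
    p = p,
    q = bh_fdr(p)
  )
  # 0/0 gives NaN; keep it as NA-like sentinel handled by classify_de
  res$log2fc[value_a == 0 & value_b == 0] <- NA_real_
  classify_de(res, thresholds, platform = "rnaseq")
}

#' Array differential expression: mean intensities + SAM permutation test
#'
#' Expression level per condition is the mean intensity over replicates; the
#' p/q-values come from [sam_test()] and calls follow the array-arm
#' thresholds.
#'
#' @param intensities Genes x samples intensity matrix or data frame.
#' @param design Tibble with columns `sample`, `condition`.
#' @param params A [sam_params()].
#' @param thresholds A [de_thresholds()].
#' @param conditions Optional length-2 character: (A, B).
#' @return Tibble (`gene_id`, `value_a`, `value_b`, `log2fc`, `d`, `p`, `q`,
#'   `call`).
#' @export
de_array <- function(intensities, design, params = sam_params(),
                     thresholds = de_thresholds(), conditions = NULL) {
  x <- as_expr_matrix(intensities)
  conditions <- conditions %||% unique(design$condition)
  stopifnot(length(conditions) == 2)
  samples_a <- design$sample[design$condition == conditions[1]]
  samples_b <- design$sample[design$condition == conditions[2]]
  stopifnot(all(c(samples_a, samples_b) %in% colnames(x)))
  sam <- sam_test(x[, c(samples_a, samples_b), drop = FALSE],
                  c(rep(conditions[1], length(samples_a)),
                    rep(conditions[2], length(samples_b))),
                  params)
  value_a <- rowMeans(x[, samples_a, drop = FALSE])
  value_b <- rowMeans(x[, samples_b, drop = FALSE])
  res <- tibble::tibble(
    gene_id = rownames(x),
    value_a = value_a,
    value_b = value_b,
    log2fc = log2(value_b / value_a),
    d = sam$d,
    p = sam$p,
    q = sam$q
  )
  res$log2fc[value_a == 0 & value_b == 0] <- NA_real_
  classify_de(res, thresholds, platform = "array")
}

#' Compare differential-expression results between platforms
#'
#' Computes the Venn decomposition of the two DE-call sets and Pearson's
#' correlation of log2 fold changes over genes measured on both platforms
#' (finite values only).
#'
#' @param results_a,results_b Result tibbles from [de_rnaseq()] / [de_array()]
#'   (need `gene_id`, `log2fc`, `call`).
#' @param labels Length-2 character naming the two platforms.
#' @return A `platform_comparison` object; see [glance.platform_comparison()]
#'   and [tidy.platform_comparison()].
#' @export
compare_platforms <- function(results_a, results_b, labels = c("rnaseq", "array")) {
  de_a <- results_a$gene_id[results_a$call != "unchanged"]
  de_b <- results_b$gene_id[results_b$call != "unchanged"]
  pairs <- dplyr::inner_join(
    dplyr::select(results_a, "gene_id", log2fc_a = "log2fc", call_a = "call"),
    dplyr::select(results_b, "gene_id", log2fc_b = "log2fc", call_b = "call"),
    by = "gene_id"
  )
  finite <- is.finite(pairs$log2fc_a) & is.finite(pairs$log2fc_b)
  if (sum(finite) < 2) abort_bad_input("fewer than 2 shared finite fold changes: correlation undefined")
  structure(
    list(
      summary = tibble::tibble(
        n_de_a_only = length(setdiff(de_a, de_b)),
        n_de_b_only = length(setdiff(de_b, de_a)),
        n_overlap = length(intersect(de_a, de_b)),
        pearson_r = stats::cor(pairs$log2fc_a[finite], pairs$log2fc_b[finite])
      ),
      pairs = pairs,
      labels = labels
    ),
    class = "platform_comparison"
  )
}

#' @export
print.platform_comparison <- function(x, ...) {
  s <- x$summary
  cat("<platform_comparison>", x$labels[1], "vs", x$labels[2], "\n")
  cat("  DE only in", x$labels[1], ":", s$n_de_a_only,
      " only in", x$labels[2], ":", s$n_de_b_only,
      " overlap:", s$n_overlap, "\n")
  cat("  Pearson r of log2 fold changes:", round(s$pearson_r, 3), "\n")
  invisible(x)
}

#' One-row summary of a platform comparison
#'
#' @param x A `platform_comparison`.
#' @param ... Unused.
#' @return Tibble with Venn counts and the Pearson correlation.
#' @export
glance.platform_comparison <- function(x, ...) x$summary

#' Per-gene pairing underlying a platform comparison
#'
#' @param x A `platform_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per shared gene.
#' @export
tidy.platform_comparison <- function(x, ...) x$pairs
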