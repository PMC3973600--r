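#' Filtering thresholds for pairwise similarity hits
#'
#' Defaults are the standard interolog-transfer settings: e-value strictly
#' below 1e-5, identity at least 0.3 (fraction scale) and coverage of both
#' sequences at least 0.7.
#'
#' @param max_evalue Exclusive upper bound on the e-value.
#' @param min_identity Inclusive lower bound on fractional identity.
#' @param min_coverage Inclusive lower bound on two-sided coverage
#'   (see [hit_coverage()]).
#' @return A `hit_thresholds` list.
#' @export
hit_thresholds <- function(max_evalue = 1e-5, min_identity = 0.3, min_coverage = 0.7) {
  if (max_evalue <= 0) abort_bad_input("max_evalue must be positive")
  if (min_identity < 0 || min_identity > 1) abort_bad_input("min_identity must lie in [0, 1]")
  if (min_coverage < 0 || min_coverage > 1) abort_bad_input("min_coverage must lie in [0, 1]")
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_coverage = min_coverage),
            class = "hit_thresholds")
}

#' Two-sided alignment coverage of a similarity hit
#'
#' Coverage is computed on both sequences and the smaller side is returned:
#' `min(alignment_length / query_length, alignment_length / subject_length)`,
#' clamped to \[0, 1\]. Taking the minimum makes the criterion symmetric in the
#' two search directions, which in turn makes bidirectional-best-hit detection
#' symmetric.
#'
#' @param hits Similarity-hit tibble with columns `alignment_length`,
#'   `query_length`, `subject_length`.
#' @return Numeric vector of coverages in \[0, 1\].
#' @export
hit_coverage <- function(hits) {
  if (any(hits$query_length <= 0 | hits$subject_length <= 0)) {
    abort_bad_input("sequence lengths must be positive")
  }
  pmin(1, pmin(hits$alignment_length / hits$query_length,
               hits$alignment_length / hits$subject_length))
}

#' Apply hit-filtering thresholds
#'
#' @param hits Similarity-hit tibble (`identity` on the 0-1 scale).
#' @param thresholds A [hit_thresholds()].
#' @return Logical vector: e-value strictly below the bound, identity and
#'   coverage at or above theirs.
#' @export
passes_thresholds <- function(hits, thresholds = hit_thresholds()) {
  hits$evalue < thresholds$max_evalue &
    hits$identity >= thresholds$min_identity &
    hit_coverage(hits) >= thresholds$min_coverage
}

#' Best passing hit per query
#'
#' Among hits passing the thresholds (self-hits excluded), selects for every
#' query the hit with the smallest e-value; ties are broken by the largest
#' bitscore, then the lexicographically smallest subject id. Duplicate
#' (query, subject) rows are collapsed to the best row first, with a warning.
#'
#' @inheritParams passes_thresholds
#' @return Tibble with one row per query that has at least one passing hit.
#' @export
best_hit_per_query <- function(hits, thresholds = hit_thresholds()) {
  kept <- hits[passes_thresholds(hits, thresholds) & hits$query_id != hits$subject_id, , drop = FALSE]
  kept <- dplyr::arrange(kept, .data$evalue, dplyr::desc(.data$bitscore), .data$subject_id)
  if (anyDuplicated(kept[c("query_id", "subject_id")])) {
    warning("duplicate (query, subject) hit rows; keeping the best by the tie rule",
            call. = FALSE)
    kept <- dplyr::distinct(kept, .data$query_id, .data$subject_id, .keep_all = TRUE)
  }
  dplyr::slice_head(dplyr::group_by(kept, .data$query_id), n = 1L) |>
    dplyr::ungroup()
}

#' Bidirectional best hits between two proteomes
#'
#' A pair (a, b) is reported when b is a's best hit in the forward search and
#' a is b's best hit in the reverse search, both after threshold filtering.
#' Each target gene appears in at most one pair per reference organism.
#'
#' @param hits_forward Hits from the target proteome against the reference.
#' @param hits_reverse Hits from the reference proteome against the target.
#' @param thresholds A [hit_thresholds()].
#' @param organism Label recorded in the `organism` column.
#' @return Tibble (`target_gene`, `reference_gene`, `organism`, `fwd_evalue`,
#'   `rev_evalue`, `fwd_identity`, `rev_identity`), sorted by `target_gene`.
#' @export
find_bbh <- function(hits_forward, hits_reverse, thresholds = hit_thresholds(),
                     organism = "reference") {
  best_f <- best_hit_per_query(hits_forward, thresholds)
  best_r <- best_hit_per_query(hits_reverse, thresholds)
  if (nrow(best_f) == 0 || nrow(best_r) == 0) {
    return(tibble::tibble(target_gene = character(0), reference_gene = character(0),
                          organism = character(0), fwd_evalue = double(0),
                          rev_evalue = double(0), fwd_identity = double(0),
                          rev_identity = double(0)))
  }
  dplyr::inner_join(
    dplyr::select(best_f, target_gene = "query_id", reference_gene = "subject_id",
                  fwd_evalue = "evalue", fwd_identity = "identity"),
    dplyr::select(best_r, reference_gene = "query_id", target_gene = "subject_id",
                  rev_evalue = "evalue", rev_identity = "identity"),
    by = c("target_gene", "reference_gene")
  ) |>
    dplyr::mutate(organism = organism, .after = "reference_gene") |>
    dplyr::arrange(.data$target_gene)
}
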