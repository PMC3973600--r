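# Internal helpers shared across modules.

# round half away from zero, to match printed table precision
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# deterministic sub-seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# element of a named vector, or NULL when the name is absent
vec_get <- function(v, nm) if (nm %in% names(v)) v[[nm]] else NULL

abort_bad_input <- function(msg) stop(msg, call. = FALSE)

# coerce a genes-by-samples table (matrix with rownames, or data frame with a
# gene_id column) to a numeric matrix with gene_id rownames
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort_bad_input("expression matrix needs gene ids as rownames")
    return(x)
  }
  x <- as.data.frame(x)
  if (!"gene_id" %in% names(x)) {
    abort_bad_input("expression table needs a 'gene_id' column or rownames")
  }
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

# fraction of G/C characters over a vector of nucleotide strings, pooled
pooled_gc <- function(sequences) {
  gc <- sum(stringr::str_count(sequences, "[GCgc]"))
  total <- sum(nchar(sequences))
  if (total == 0) return(NA_real_)
  gc / total
}
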