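# Small transcribed study tables shipped with the package.

rhizonet_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rhizonet")
  if (path == "") abort_bad_input(paste0("missing packaged file: ", file))
  path
}

#' Packaged study tables
#'
#' Three small tables transcribed from the published bacteroid vs free-living
#' analysis of *Mesorhizobium huakuii* 7653R:
#' `mhk_table1_counts()` — per-replicon gene and differential-call counts
#' behind the replicon proportion table; `mhk_nif_subnetwork()` — the 113
#' genes of the nitrogen-fixation subnetwork with their expression fold
#' changes; `mhk_ctra_subnetwork()` — the 30 genes of the CtrA-centred
#' two-hop subnetwork with their regulation calls.
#'
#' @return A tibble.
#' @name mhk_tables
NULL

#' @rdname mhk_tables
#' @export
mhk_table1_counts <- function() {
  readr::read_tsv(rhizonet_extdata("table1_replicon_counts.tsv"),
                  show_col_types = FALSE)
}

#' @rdname mhk_tables
#' @export
mhk_nif_subnetwork <- function() {
  readr::read_tsv(rhizonet_extdata("table3_nif_subnetwork.tsv"),
                  show_col_types = FALSE)
}

#' @rdname mhk_tables
#' @export
mhk_ctra_subnetwork <- function() {
  readr::read_tsv(rhizonet_extdata("table4_ctra_subnetwork.tsv"),
                  show_col_types = FALSE)
}
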