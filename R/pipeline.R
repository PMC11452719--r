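## End-to-end convenience driver over the synthetic generator and the
## preprocessing -> alignment -> deduplication -> annotation stages.

#' Run the full quantification pipeline on a simulated dataset
#'
#' Generates reference + truth + reads from a \code{\link{sim_config}}, then
#' runs UMI extraction and trimming, placement, directional deduplication
#' with remapping, hierarchical annotation and count-matrix assembly.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with reference, truth, metadata, preprocessed reads and trim
#'   report, alignment tally, molecules, placements, annotated molecules and
#'   count matrices.
#' @export
run_small_rna_pipeline <- function(config) {
  ref <- build_reference(config)
  truth <- simulate_molecules(config, ref$annotations)
  raw <- render_reads(truth, ref$genome, config)
  meta <- sim_cell_metadata(config)
  index <- build_index(ref$genome)

  pp <- preprocess_reads(raw$seq, raw$read_id, config$adapter_sequence,
                         cell = raw$cell)
  al <- align_batch(pp$reads, index)
  dd <- dedup_directional(al$reads, al$placements)
  rm_ <- remap_molecules(dd, index)
  assigned <- annotate_molecules(rm_$molecules, rm_$placements,
                                 ref$annotations)
  mats <- build_count_matrices(assigned, meta, ref$annotations)
  list(config = config, reference = ref, truth = truth, metadata = meta,
       preprocessed = pp, align_tally = al$tally,
       molecules = rm_$molecules, placements = rm_$placements,
       n_dropped_remap = rm_$n_dropped,
       assigned = assigned, matrices = mats)
}

#' Planted truth as a per-cell per-feature count matrix
#'
#' @param truth truth table from \code{\link{simulate_molecules}}.
#' @param cells cell universe (row order).
#' @param features feature universe (column order).
#' @return integer matrix of molecule counts.
#' @export
truth_count_matrix <- function(truth, cells, features) {
  tab <- table(factor(truth$cell, levels = cells),
               factor(truth$feature, levels = features))
  m <- matrix(as.integer(tab), nrow = length(cells),
              dimnames = list(cells, features))
  m
}
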