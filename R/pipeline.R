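#' Call fusions end-to-end
#'
#' Runs the full two-phase caller: phase-1 chimeric-read scan and
#' prefilters over genome alignments, then phase-2 fusion-contig
#' realignment and breakpoint quantification, returning the final fusion
#' report.
#'
#' @param segments Alignment-segment tibble (see [read_alignments()]).
#' @param gms A [gene_model_set()].
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param total_reads Total reads sequenced (the FFPM denominator).
#' @param aligner Contig realignment adapter (see [ideal_aligner()],
#'   [minimap2_aligner()]).
#' @param similarity A `similarity_map`.
#' @param red_herrings Optional unordered gene-pair exclusion list.
#' @param cell_barcodes Add a `CellBarcodes` column from tagged read
#'   names?
#' @param config A [fusion_config()].
#' @return A `fusion_report` tibble.
#' @examples
#' sim <- simulate_fusion_dataset(sim_spec(seed = 42, n_genes = 6,
#'   n_fusions = 1, background_reads = 12))
#' call_fusions(sim$segments, sim$gms, sim$genome,
#'              total_reads = nrow(sim$reads),
#'              aligner = ideal_aligner(sim$read_blocks))
#' @export
call_fusions <- function(segments, gms, genome, total_reads, aligner,
                         similarity = empty_similarity_map(),
                         red_herrings = NULL, cell_barcodes = FALSE,
                         config = fusion_config()) {
  p1 <- phase1_scan(segments, gms, total_reads, similarity = similarity,
                    red_herrings = red_herrings, config = config)
  rep <- phase2_quant(p1, gms, genome, aligner, similarity = similarity,
                      config = config)
  if (cell_barcodes) rep <- add_cell_barcodes(rep)
  rep
}
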