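#' Fusion-calling configuration
#'
#' Central collection of the tunable thresholds of the two-phase caller,
#' with the defaults used throughout. Distances are bases unless noted.
#'
#' @param min_identity Minimum per-segment alignment identity for a read
#'   segment to count as chimeric evidence (default 0.70).
#' @param max_locus_gap Same-chromosome, same-strand gap above which two
#'   segments of a read count as distinct genomic loci (default 100 kb).
#' @param boundary_near,boundary_far Phase-1 exon-boundary distance rules:
#'   a gene pair is retained when some read has both junction distances at
#'   most `boundary_near` (50), or when some read has one distance at most
#'   `boundary_near` and the other at most `boundary_far` (1000) and the
#'   pair has at least two supporting reads.
#' @param min_ffpm Minimum fusion expression in fusion reads per million
#'   total reads, applied in phase 1 per gene pair and in phase 2 per
#'   breakpoint (default 0.1 = 1 read per 10 M).
#' @param snap_dist Maximum distance (bases) for snapping a contig
#'   alignment end onto an exon boundary (default 3).
#' @param min_exon_bp Minimum cumulative exonic alignment per fused gene
#'   for a realigned read to count as fusion evidence (default 25).
#' @param min_reads_consensus,min_reads_nonconsensus Minimum supporting
#'   reads per breakpoint at consensus / non-consensus splice
#'   dinucleotides (defaults 1 and 2).
#' @param isoform_frac Within one fusion gene pair, breakpoints supported
#'   by fewer than this fraction of the dominant breakpoint's reads are
#'   discarded as noise (default 0.05).
#' @param consensus_sites List of length-2 character vectors of accepted
#'   (donor, acceptor) dinucleotides; default GT--AG only, with GC--AG and
#'   AT--AC as common extensions.
#' @param intron_cap Maximum intron length represented on a fusion contig
#'   (default 1000); longer introns keep `intron_flank` bases at each end.
#' @param intron_flank Flank retained from each side of a shrunk intron
#'   (default 500; two flanks equal `intron_cap`).
#' @param spacer_len Length of the `N` spacer between the two genes on a
#'   fusion contig (default 1000).
#' @param filter_paralogs Drop candidate pairs recorded as paralogs
#'   (default TRUE).
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(min_identity = 0.70,
                          max_locus_gap = 100000L,
                          boundary_near = 50L,
                          boundary_far = 1000L,
                          min_ffpm = 0.1,
                          snap_dist = 3L,
                          min_exon_bp = 25L,
                          min_reads_consensus = 1L,
                          min_reads_nonconsensus = 2L,
                          isoform_frac = 0.05,
                          consensus_sites = list(c("GT", "AG")),
                          intron_cap = 1000L,
                          intron_flank = 500L,
                          spacer_len = 1000L,
                          filter_paralogs = TRUE) {
  structure(as.list(environment()), class = "fusion_config")
}

#' Collect chimeric reads from alignment segments
#'
#' Retains only reads having at least two alignment segments at distinct
#' genomic loci — different chromosomes, opposite alignment strands, or a
#' same-chromosome gap larger than `max_locus_gap` — the signature of a
#' candidate fusion read. Segments of retained reads are returned sorted
#' by read coordinate.
#'
#' @param segments Alignment-segment tibble (see [read_alignments()]).
#' @param max_locus_gap Same-chromosome distinct-locus gap, bases.
#' @return The filtered, sorted segment tibble.
#' @export
collect_chimeric_reads <- function(segments, max_locus_gap = 100000L) {
  segments <- as_tibble(segments)
  segments |>
    group_by(.data$read_id) |>
    filter(n() >= 2 && has_distinct_loci(.data$chrom, .data$align_strand,
                                         .data$genome_start, .data$genome_end,
                                         max_locus_gap)) |>
    arrange(.data$read_start, .by_group = TRUE) |>
    ungroup()
}

has_distinct_loci <- function(chrom, strand, gstart, gend, max_gap) {
  n <- length(chrom)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (chrom[i] != chrom[j] || strand[i] != strand[j]) return(TRUE)
      gap <- max(gstart[i], gstart[j]) - min(gend[i], gend[j])
      if (gap > max_gap) return(TRUE)
    }
  }
  FALSE
}

#' Assign alignment segments to genes by maximal exonic overlap
#'
#' A segment is assigned to the gene whose (collapsed) exons it overlaps
#' by the most bases; a segment overlapping no exon — e.g. one lying
#' wholly within an intron or intergenic space — gets `NA` and is not
#' fusion evidence. Ties go to the lexicographically smaller gene id.
#'
#' @param segments Alignment-segment tibble.
#' @param gms A [gene_model_set()].
#' @return `segments` with `gene_id` and `exonic_overlap` columns added.
#' @export
assign_segment_gene <- function(segments, gms) {
  stopifnot(inherits(gms, "gene_model_set"))
  segments <- as_tibble(segments) |>
    select(-dplyr::any_of(c("gene_id", "exonic_overlap")))
  if (nrow(segments) == 0) {
    return(segments |> mutate(gene_id = character(0), exonic_overlap = integer(0)))
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(segments$genome_start + 1L, segments$genome_end))
  ex <- gms$exon_union
  ex_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, ex_gr, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(segments |> mutate(gene_id = NA_character_, exonic_overlap = 0L))
  }
  ov <- tibble(
    seg = S4Vectors::queryHits(hits),
    gene_id = ex$gene_id[S4Vectors::subjectHits(hits)],
    w = IRanges::width(IRanges::pintersect(
      IRanges::ranges(seg_gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(ex_gr)[S4Vectors::subjectHits(hits)]))
  ) |>
    group_by(.data$seg, .data$gene_id) |>
    summarise(w = sum(.data$w), .groups = "drop") |>
    group_by(.data$seg) |>
    arrange(desc(.data$w), .data$gene_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  segments |>
    mutate(.seg = row_number()) |>
    left_join(ov, by = c(".seg" = "seg")) |>
    mutate(exonic_overlap = dplyr::coalesce(.data$w, 0L)) |>
    select(-".seg", -"w")
}

#' Derive per-read fusion candidates from gene-assigned segments
#'
#' Walks consecutive segment pairs along each chimeric read. A pair whose
#' two segments are assigned to different genes and both reach the minimum
#' alignment identity yields one candidate, with the gene order taken 5'
#' to 3' along the read — flipped when both segments align antisense to
#' their genes' strands (the read is then the reverse complement of the
#' fusion transcript). Raw breakpoints are the junction-side alignment
#' ends, and each is scored by its distance to the nearest exon boundary
#' of the assigned gene. A read contributes at most one candidate per
#' ordered gene pair.
#'
#' @param segments Gene-assigned chimeric segments
#'   (see [assign_segment_gene()]).
#' @param gms A [gene_model_set()].
#' @param config A [fusion_config()].
#' @return Tibble of per-read candidates: `read_id`, `gene5`, `gene3`,
#'   breakpoint chrom/pos pairs (0-based junction coordinates), `dist5`,
#'   `dist3`, `identity5`, `identity3`.
#' @export
derive_candidates <- function(segments, gms, config = fusion_config()) {
  stopifnot(inherits(gms, "gene_model_set"))
  segments <- as_tibble(segments) |> arrange(.data$read_id, .data$read_start)
  if (!"identity" %in% names(segments)) {
    segments <- segments |>
      mutate(identity = ifelse(.data$block_len > 0,
                               .data$matches / .data$block_len, 0))
  }
  out <- list()
  for (rid in unique(segments$read_id)) {
    ss <- segments |> filter(.data$read_id == rid)
    if (nrow(ss) < 2) next
    for (k in seq_len(nrow(ss) - 1)) {
      s1 <- ss[k, ]; s2 <- ss[k + 1, ]
      if (is.na(s1$gene_id) || is.na(s2$gene_id)) next
      if (s1$gene_id == s2$gene_id) next
      if (s1$identity < config$min_identity || s2$identity < config$min_identity) next
      g1 <- gms$genes |> filter(.data$gene_id == s1$gene_id)
      g2 <- gms$genes |> filter(.data$gene_id == s2$gene_id)
      # junction sides: read-end of s1, read-start of s2, in genome coords
      j1 <- if (s1$align_strand == "+") s1$genome_end else s1$genome_start
      j2 <- if (s2$align_strand == "+") s2$genome_start else s2$genome_end
      antisense1 <- s1$align_strand != g1$strand
      antisense2 <- s2$align_strand != g2$strand
      flip <- antisense1 && antisense2
      d1 <- min_exon_boundary_distance(gms, s1$chrom, j1, gene_id = s1$gene_id)
      d2 <- min_exon_boundary_distance(gms, s2$chrom, j2, gene_id = s2$gene_id)
      row <- if (!flip) {
        tibble(read_id = rid, gene5 = s1$gene_id, gene3 = s2$gene_id,
               break5_chrom = s1$chrom, break5_pos = j1,
               break3_chrom = s2$chrom, break3_pos = j2,
               dist5 = d1$distance, dist3 = d2$distance,
               identity5 = s1$identity, identity3 = s2$identity)
      } else {
        tibble(read_id = rid, gene5 = s2$gene_id, gene3 = s1$gene_id,
               break5_chrom = s2$chrom, break5_pos = j2,
               break3_chrom = s1$chrom, break3_pos = j1,
               dist5 = d2$distance, dist3 = d1$distance,
               identity5 = s2$identity, identity3 = s1$identity)
      }
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    return(tibble(read_id = character(), gene5 = character(), gene3 = character(),
                  break5_chrom = character(), break5_pos = integer(),
                  break3_chrom = character(), break3_pos = integer(),
                  dist5 = integer(), dist3 = integer(),
                  identity5 = double(), identity3 = double()))
  }
  dplyr::bind_rows(out) |>
    distinct(.data$read_id, .data$gene5, .data$gene3, .keep_all = TRUE)
}

#' Phase-1 exon-boundary retention test
#'
#' A candidate gene pair is pursued when either (a) some supporting read
#' has both junction breakpoints within `boundary_near` bases of an exon
#' boundary, or (b) some read has one breakpoint within `boundary_near`
#' and the other within `boundary_far` bases and the pair is supported by
#' at least two reads.
#'
#' @param read_candidates Per-read candidate tibble
#'   (see [derive_candidates()]).
#' @param config A [fusion_config()].
#' @return The subset of `read_candidates` belonging to retained pairs.
#' @export
phase1_retention <- function(read_candidates, config = fusion_config()) {
  read_candidates |>
    group_by(.data$gene5, .data$gene3) |>
    filter({
      near <- pmax(.data$dist5, .data$dist3) <= config$boundary_near
      mixed <- pmin(.data$dist5, .data$dist3) <= config$boundary_near &
        pmax(.data$dist5, .data$dist3) <= config$boundary_far
      any(near) || (any(mixed) && dplyr::n_distinct(.data$read_id) >= 2)
    }) |>
    ungroup()
}

#' Fusion expression as reads per million (FFPM)
#'
#' `read_count / total_reads * 1e6`: one fusion read per ten million total
#' reads equals 0.1 FFPM, the default reporting floor.
#'
#' @param read_count Number of fusion-supporting reads.
#' @param total_reads Total sequenced reads in the sample (> 0).
#' @return FFPM value(s).
#' @examples
#' compute_ffpm(1, 1e7)  # 0.1
#' @export
compute_ffpm <- function(read_count, total_reads) {
  if (any(total_reads <= 0)) abort("total_reads must be positive")
  read_count * 1e6 / total_reads
}

#' Annotation and expression prefilter for phase-1 candidates
#'
#' Aggregates retained per-read candidates per ordered gene pair, computes
#' FFPM, and drops pairs that are (i) on the user-supplied red-herring /
#' known-normal list, (ii) genes with overlapping genomic coordinates,
#' (iii) recorded paralogs (when enabled), or (iv) below the minimum FFPM.
#'
#' @param read_candidates Retained per-read candidates
#'   (see [phase1_retention()]).
#' @param total_reads Total reads in the sample (FFPM denominator).
#' @param overlap_pairs Tibble `gene1`,`gene2` from
#'   [overlapping_gene_pairs()] (or NULL).
#' @param similarity A `similarity_map` supplying the paralog relation.
#' @param red_herrings Optional unordered pair list: a character vector of
#'   `"A--B"` strings or a two-column data frame.
#' @param config A [fusion_config()].
#' @return Tibble of retained candidates: `gene5`, `gene3`, `n_reads`,
#'   `ffpm`, `read_ids` (list-column), `annotations`.
#' @export
filter_candidates <- function(read_candidates, total_reads,
                              overlap_pairs = NULL,
                              similarity = empty_similarity_map(),
                              red_herrings = NULL,
                              config = fusion_config()) {
  cand <- read_candidates |>
    group_by(.data$gene5, .data$gene3) |>
    summarise(n_reads = dplyr::n_distinct(.data$read_id),
              read_ids = list(sort(unique(.data$read_id))), .groups = "drop") |>
    mutate(ffpm = compute_ffpm(.data$n_reads, total_reads),
           annotations = ".")
  if (nrow(cand) == 0) return(cand)

  key <- pair_key(cand$gene5, cand$gene3)
  drop <- rep(FALSE, nrow(cand))
  if (!is.null(red_herrings)) {
    rh_key <- normalize_pair_list(red_herrings)
    drop <- drop | key %in% rh_key
  }
  if (!is.null(overlap_pairs) && nrow(overlap_pairs) > 0) {
    drop <- drop | key %in% pair_key(overlap_pairs$gene1, overlap_pairs$gene2)
  }
  if (isTRUE(config$filter_paralogs)) {
    drop <- drop | is_paralog_pair(similarity, cand$gene5, cand$gene3)
  }
  drop <- drop | cand$ffpm < config$min_ffpm
  cand[!drop, , drop = FALSE]
}

normalize_pair_list <- function(x) {
  if (is.data.frame(x)) {
    pair_key(x[[1]], x[[2]])
  } else {
    parts <- stringr::str_split(x, stringr::fixed("--"))
    pair_key(purrr::map_chr(parts, 1), purrr::map_chr(parts, 2))
  }
}

#' Run the full phase-1 scan
#'
#' Chains [collect_chimeric_reads()], [assign_segment_gene()],
#' [derive_candidates()], [phase1_retention()] and [filter_candidates()].
#'
#' @param segments Alignment-segment tibble for all reads.
#' @param gms A [gene_model_set()].
#' @param total_reads Total reads in the sample.
#' @param similarity A `similarity_map` (paralog relation).
#' @param red_herrings Optional unordered pair list (see
#'   [filter_candidates()]).
#' @param config A [fusion_config()].
#' @return A `phase1_result` list: `candidates` (pair-level tibble),
#'   `read_candidates` (read-level tibble restricted to retained pairs),
#'   `total_reads`, `config`.
#' @export
phase1_scan <- function(segments, gms, total_reads,
                        similarity = empty_similarity_map(),
                        red_herrings = NULL,
                        config = fusion_config()) {
  chimeric <- collect_chimeric_reads(segments, config$max_locus_gap)
  assigned <- assign_segment_gene(chimeric, gms)
  rc <- derive_candidates(assigned, gms, config)
  rc <- phase1_retention(rc, config)
  cand <- filter_candidates(rc, total_reads,
                            overlap_pairs = overlapping_gene_pairs(gms),
                            similarity = similarity,
                            red_herrings = red_herrings, config = config)
  rc <- rc |>
    filter(paste(.data$gene5, .data$gene3) %in%
             paste(cand$gene5, cand$gene3))
  structure(list(candidates = cand, read_candidates = rc,
                 total_reads = total_reads, config = config),
            class = "phase1_result")
}

#' @export
print.phase1_result <- function(x, ...) {
  cat(sprintf("<phase1_result> %d candidate gene pair(s), %d supporting read(s), %d total reads\n",
              nrow(x$candidates), dplyr::n_distinct(x$read_candidates$read_id),
              x$total_reads))
  invisible(x)
}
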