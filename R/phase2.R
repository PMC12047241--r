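#' Contig realignment adapters
#'
#' Phase 2 realigns candidate reads to each fusion contig through an
#' adapter function with signature `f(read_ids, contig)` returning a
#' block-level alignment tibble (`read_id`, `contig_start`, `contig_end`,
#' `read_start`, `read_end`), one best alignment per read, unaligned
#' reads absent.
#'
#' `ideal_aligner` replays planned exon placements (e.g. a simulated
#' dataset's `read_blocks`): each planned genomic block is projected
#' through the contig's coordinate map; blocks from genes not on the
#' contig are dropped, so reads from unrelated genes yield no alignment.
#'
#' `minimap2_aligner` shells out to an external `minimap2` executable
#' (splice preset, base-level CIGAR) and parses the resulting PAF `cg`
#' tags into blocks. It requires `minimap2` on the PATH.
#'
#' @param read_blocks Planned block tibble with columns `read_id`,
#'   `gene_id`, `chrom`, `genome_start`, `genome_end`, `read_start`,
#'   `read_end`.
#' @return An adapter function.
#' @export
ideal_aligner <- function(read_blocks) {
  force(read_blocks)
  function(read_ids, contig) {
    rb <- read_blocks |>
      filter(.data$read_id %in% read_ids,
             .data$gene_id %in% c(contig$gene5, contig$gene3))
    if (nrow(rb) == 0) return(empty_contig_alignment())
    purrr::map_dfr(seq_len(nrow(rb)), function(k) {
      b <- rb[k, ]
      m1 <- genome_to_contig(contig, b$chrom, b$genome_start, gene_id = b$gene_id)
      m2 <- genome_to_contig(contig, b$chrom, b$genome_end - 1L, gene_id = b$gene_id)
      if (is.na(m1$contig_pos) || is.na(m2$contig_pos)) return(NULL)
      tibble(read_id = b$read_id,
             contig_start = min(m1$contig_pos, m2$contig_pos),
             contig_end = max(m1$contig_pos, m2$contig_pos) + 1L,
             read_start = b$read_start, read_end = b$read_end)
    })
  }
}

empty_contig_alignment <- function() {
  tibble(read_id = character(), contig_start = integer(),
         contig_end = integer(), read_start = integer(), read_end = integer())
}

#' @param reads Tibble with `read_id`, `seq` giving the read sequences.
#' @param minimap2 Path to the minimap2 executable.
#' @param args Extra command-line arguments.
#' @rdname ideal_aligner
#' @export
minimap2_aligner <- function(reads, minimap2 = "minimap2",
                             args = c("-x", "splice", "-c", "--secondary=no")) {
  force(reads); force(minimap2); force(args)
  function(read_ids, contig) {
    rd <- reads |> filter(.data$read_id %in% read_ids)
    if (nrow(rd) == 0) return(empty_contig_alignment())
    ref_fa <- tempfile(fileext = ".fa"); qry_fa <- tempfile(fileext = ".fa")
    out_paf <- tempfile(fileext = ".paf")
    on.exit(unlink(c(ref_fa, qry_fa, out_paf)), add = TRUE)
    readr::write_lines(c(paste0(">", contig$contig_id), contig$seq), ref_fa)
    readr::write_lines(rbind(paste0(">", rd$read_id), rd$seq), qry_fa)
    status <- suppressWarnings(
      system2(minimap2, c(args, shQuote(ref_fa), shQuote(qry_fa)),
              stdout = out_paf, stderr = FALSE))
    if (!identical(status, 0L)) {
      abort(sprintf("minimap2 failed (exit %s) on contig %s", status, contig$contig_id))
    }
    lines <- readr::read_lines(out_paf)
    if (length(lines) == 0) return(empty_contig_alignment())
    purrr::map_dfr(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      cg <- stringr::str_match(paste(f[-(1:12)], collapse = "\t"), "cg:Z:(\\S+)")[1, 2]
      if (is.na(cg)) return(NULL)
      cigar_to_blocks(f[1], as.integer(f[3]), as.integer(f[8]), f[5],
                      as.integer(f[2]), cg)
    }) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::arrange(.data$contig_start, .by_group = TRUE) |>
      dplyr::ungroup()
  }
}

# Walk a CIGAR over (read, contig) producing one block per gapless-on-
# contig run (N/D open a new block). Coordinates follow PAF conventions.
cigar_to_blocks <- function(read_id, qstart, tstart, strand, qlen, cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  blocks <- list()
  q <- qstart; t <- tstart
  bq <- q; bt <- t
  flush <- function() {
    if (t > bt) {
      blocks[[length(blocks) + 1]] <<- tibble(
        read_id = read_id, contig_start = bt, contig_end = t,
        read_start = bq, read_end = q)
    }
  }
  for (k in seq_along(ops)) {
    op <- ops[k]; L <- lens[k]
    if (op %in% c("M", "=", "X")) { q <- q + L; t <- t + L }
    else if (op == "I") { q <- q + L }
    else if (op %in% c("D", "N")) {
      if (op == "N" || L > 20) { flush(); t <- t + L; bq <- q; bt <- t }
      else t <- t + L
    }
  }
  flush()
  out <- dplyr::bind_rows(blocks)
  if (strand == "-" && nrow(out) > 0) {
    out <- out |> mutate(rs = qlen - .data$read_end, re = qlen - .data$read_start,
                         read_start = .data$rs, read_end = .data$re) |>
      select(-"rs", -"re")
  }
  out
}

#' Realign candidate reads to a fusion contig
#'
#' Invokes the supplied adapter and normalises the result: one alignment
#' per read, blocks sorted by contig coordinate, unaligned reads dropped.
#'
#' @param read_ids Character vector of candidate read ids.
#' @param contig A `fusion_contig`.
#' @param aligner An adapter from [ideal_aligner()] or
#'   [minimap2_aligner()].
#' @return Block-level alignment tibble.
#' @export
realign_to_contig <- function(read_ids, contig, aligner) {
  aln <- aligner(read_ids, contig)
  if (nrow(aln) == 0) return(empty_contig_alignment())
  aln |>
    group_by(.data$read_id) |>
    arrange(.data$contig_start, .by_group = TRUE) |>
    ungroup()
}

#' Snap alignment block ends onto nearby exon boundaries
#'
#' Any block start or end lying within `snap_dist` bases of a contig exon
#' boundary (but not already on one) is moved onto that boundary,
#' tolerating locally divergent alignment ends. Snapping never reorders
#' or inverts blocks, and is idempotent.
#'
#' @param alignments Block-level alignment tibble.
#' @param boundaries Sorted contig-coordinate exon boundaries (a
#'   `fusion_contig`'s `boundaries`, or any integer vector).
#' @param snap_dist Maximum snap distance in bases.
#' @return The alignment tibble with snapped `contig_start`/`contig_end`.
#' @export
snap_alignment_ends <- function(alignments, boundaries, snap_dist = 3L) {
  if (nrow(alignments) == 0 || length(boundaries) == 0) return(alignments)
  snap1 <- function(p) {
    d <- abs(boundaries - p)
    i <- which.min(d)  # ties: which.min takes the first = smaller boundary
    if (d[i] > 0 && d[i] <= snap_dist) boundaries[i] else p
  }
  out <- alignments |>
    mutate(new_start = purrr::map_int(.data$contig_start, ~ as.integer(snap1(.x))),
           new_end = purrr::map_int(.data$contig_end, ~ as.integer(snap1(.x))))
  ok <- out$new_start < out$new_end
  out$contig_start[ok] <- out$new_start[ok]
  out$contig_end[ok] <- out$new_end[ok]
  out |> select(-"new_start", -"new_end")
}

#' Classify realigned reads as fusion evidence
#'
#' A read counts as fusion evidence when its alignment crosses both genes
#' of the contig with a cumulative exonic alignment of at least
#' `min_exon_bp` bases within each gene, where bases falling in exon
#' regions recorded as sequence-similar between the two genes do not
#' count. The read's breakpoint pair is (end of its last 5'-gene block,
#' start of its first 3'-gene block), in contig coordinates.
#'
#' @param alignments Snapped block-level alignment tibble.
#' @param contig A `fusion_contig`.
#' @param similarity A `similarity_map`.
#' @param config A [fusion_config()].
#' @return Per-read tibble: `read_id`, `overlap5`, `overlap3`,
#'   `is_evidence`, `break5`, `break3`.
#' @export
classify_fusion_reads <- function(alignments, contig,
                                  similarity = empty_similarity_map(),
                                  config = fusion_config()) {
  if (nrow(alignments) == 0) {
    return(tibble(read_id = character(), overlap5 = integer(),
                  overlap3 = integer(), is_evidence = logical(),
                  break5 = integer(), break3 = integer()))
  }
  countable <- countable_exon_intervals(contig, similarity)
  alignments |>
    group_by(.data$read_id) |>
    dplyr::group_modify(function(df, key) {
      in5 <- (df$contig_start + df$contig_end) / 2 < contig$gene5_range[2]
      ov5 <- sum_interval_overlap(df[in5, ], countable$gene5)
      ov3 <- sum_interval_overlap(df[!in5, ], countable$gene3)
      evid <- any(in5) && any(!in5) &&
        ov5 >= config$min_exon_bp && ov3 >= config$min_exon_bp
      tibble(overlap5 = ov5, overlap3 = ov3, is_evidence = evid,
             break5 = if (any(in5)) max(df$contig_end[in5]) else NA_integer_,
             break3 = if (any(!in5)) min(df$contig_start[!in5]) else NA_integer_)
    }) |>
    ungroup()
}

sum_interval_overlap <- function(blocks, intervals) {
  if (nrow(blocks) == 0 || nrow(intervals) == 0) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(blocks))) {
    tot <- tot + sum(interval_overlap(blocks$contig_start[i], blocks$contig_end[i],
                                      intervals$start, intervals$end))
  }
  as.integer(tot)
}

# Contig exon intervals per gene with similar-region bases removed.
countable_exon_intervals <- function(contig, similarity) {
  sim <- similarity_regions(similarity, contig$gene5, contig$gene3)
  one_gene <- function(gid, side) {
    ex <- contig$exon_blocks |> filter(.data$gene_id == gid)
    iv <- IRanges::IRanges(ex$contig_start + 1L, ex$contig_end)
    if (nrow(sim) > 0) {
      reg <- if (side == 5) {
        # regions oriented to (gene5 first) query order
        similarity_regions(similarity, contig$gene5, contig$gene3)
      } else {
        similarity_regions(similarity, contig$gene3, contig$gene5)
      }
      sim_contig <- purrr::map_dfr(seq_len(nrow(reg)), function(k) {
        r <- reg[k, ]
        hit <- ex |> filter(.data$chrom == r$chrom_query,
                            .data$genome_start < r$end_query,
                            r$start_query < .data$genome_end)
        if (nrow(hit) == 0) return(NULL)
        purrr::map_dfr(seq_len(nrow(hit)), function(h) {
          b <- hit[h, ]
          gs <- max(b$genome_start, r$start_query)
          ge <- min(b$genome_end, r$end_query)
          c1 <- genome_to_contig(contig, b$chrom, gs, gene_id = gid)$contig_pos
          c2 <- genome_to_contig(contig, b$chrom, ge - 1L, gene_id = gid)$contig_pos
          tibble(start = min(c1, c2), end = max(c1, c2) + 1L)
        })
      })
      if (nrow(sim_contig) > 0) {
        iv <- IRanges::setdiff(iv, IRanges::IRanges(sim_contig$start + 1L,
                                                    sim_contig$end))
      }
    }
    tibble(start = IRanges::start(iv) - 1L, end = IRanges::end(iv))
  }
  list(gene5 = one_gene(contig$gene5, 5), gene3 = one_gene(contig$gene3, 3))
}

#' Classify the splice dinucleotides at a contig breakpoint pair
#'
#' The donor dinucleotide is the two contig bases immediately 3' of the
#' 5'-gene break; the acceptor is the two bases immediately 5' of the
#' 3'-gene break. Because shrunk introns keep their terminal flanks,
#' breakpoints at annotated exon junctions read the genuine intronic
#' GT/AG context. A breakpoint at the contig edge is non-consensus with
#' `edge = TRUE`.
#'
#' @param contig A `fusion_contig`.
#' @param break5,break3 Contig breakpoint pair (0-based; `break5` is an
#'   exclusive end, `break3` an inclusive start).
#' @param config A [fusion_config()] (uses `consensus_sites`).
#' @return Tibble `donor`, `acceptor`, `splice_class`, `edge`.
#' @export
classify_splice <- function(contig, break5, break3, config = fusion_config()) {
  clen <- nchar(contig$seq)
  purrr::map2_dfr(as.integer(break5), as.integer(break3), function(b5, b3) {
    edge <- (b5 + 2L > clen) || (b3 - 2L < 0L)
    donor <- if (b5 + 2L <= clen) substr(contig$seq, b5 + 1L, b5 + 2L) else NA_character_
    acceptor <- if (b3 - 2L >= 0L) substr(contig$seq, b3 - 1L, b3) else NA_character_
    consensus <- !edge && any(purrr::map_lgl(config$consensus_sites, function(s) {
      identical(donor, s[1]) && identical(acceptor, s[2])
    }))
    tibble(donor = donor, acceptor = acceptor,
           splice_class = if (consensus) "consensus" else "non_consensus",
           edge = edge)
  })
}

#' Tally breakpoint evidence on a fusion contig
#'
#' Groups fusion-evidence reads by their exact (post-snap) contig
#' breakpoint pair, attaches genomic breakpoints via the coordinate map,
#' classifies the splice dinucleotides, and computes per-breakpoint FFPM.
#'
#' @param evidence Output of [classify_fusion_reads()] (only
#'   `is_evidence` rows are tallied).
#' @param contig A `fusion_contig`.
#' @param total_reads Total reads in the sample.
#' @param config A [fusion_config()].
#' @return Tibble with one row per distinct breakpoint pair: contig and
#'   genomic breakpoints, dinucleotides, `splice_class`, `n_reads`,
#'   `read_ids` (list), `ffpm`.
#' @export
tally_breakpoints <- function(evidence, contig, total_reads,
                              config = fusion_config()) {
  ev <- evidence |> filter(.data$is_evidence)
  if (nrow(ev) == 0) return(empty_breakpoint_tally())
  tal <- ev |>
    group_by(.data$break5, .data$break3) |>
    summarise(n_reads = dplyr::n_distinct(.data$read_id),
              read_ids = list(sort(unique(.data$read_id))), .groups = "drop")
  g5 <- contig_to_genome(contig, tal$break5 - 1L)
  g3 <- contig_to_genome(contig, tal$break3)
  spl <- classify_splice(contig, tal$break5, tal$break3, config)
  tal |>
    mutate(
      fusion_name = contig$contig_id,
      gene5 = contig$gene5, gene3 = contig$gene3,
      breakpoint5 = format_breakpoint(g5$chrom, g5$pos, g5$strand),
      breakpoint3 = format_breakpoint(g3$chrom, g3$pos, g3$strand),
      donor = spl$donor, acceptor = spl$acceptor,
      splice_class = spl$splice_class,
      ffpm = compute_ffpm(.data$n_reads, total_reads)
    )
}

empty_breakpoint_tally <- function() {
  tibble(break5 = integer(), break3 = integer(), n_reads = integer(),
         read_ids = list(), fusion_name = character(), gene5 = character(),
         gene3 = character(), breakpoint5 = character(),
         breakpoint3 = character(), donor = character(),
         acceptor = character(), splice_class = character(), ffpm = double())
}

#' Final phase-2 breakpoint filters
#'
#' Per breakpoint: require the minimum FFPM, at least one read at
#' consensus splice sites and at least two reads at non-consensus sites;
#' then, within each fusion gene pair, discard isoforms (breakpoint
#' pairs) supported by fewer than `isoform_frac` of the dominant
#' isoform's reads.
#'
#' @param tallies Breakpoint tally tibble (possibly spanning several
#'   fusions; the isoform filter groups by `fusion_name`).
#' @param config A [fusion_config()].
#' @return The retained rows.
#' @export
apply_final_filters <- function(tallies, config = fusion_config()) {
  if (nrow(tallies) == 0) return(tallies)
  kept <- tallies |>
    filter(.data$ffpm >= config$min_ffpm,
           ifelse(.data$splice_class == "consensus",
                  .data$n_reads >= config$min_reads_consensus,
                  .data$n_reads >= config$min_reads_nonconsensus))
  if (nrow(kept) == 0) return(kept)
  kept |>
    group_by(.data$fusion_name) |>
    filter(.data$n_reads >= config$isoform_frac * max(.data$n_reads)) |>
    ungroup()
}

#' Run phase-2 quantification over phase-1 candidates
#'
#' For each retained candidate gene pair: build the fusion contig,
#' realign the pair's supporting reads, snap alignment ends, classify
#' fusion evidence, tally and filter breakpoints, and assemble the final
#' report. Reads supporting more than one reported fusion are flagged in
#' the `Annotations` column.
#'
#' @param phase1 A `phase1_result` from [phase1_scan()].
#' @param gms A [gene_model_set()].
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param aligner A realignment adapter (see [ideal_aligner()]).
#' @param similarity A `similarity_map`.
#' @param config A [fusion_config()].
#' @return A `fusion_report` tibble (see [write_fusion_report()] for the
#'   column dialect).
#' @export
phase2_quant <- function(phase1, gms, genome, aligner,
                         similarity = empty_similarity_map(),
                         config = fusion_config()) {
  stopifnot(inherits(phase1, "phase1_result"))
  rows <- list()
  for (k in seq_len(nrow(phase1$candidates))) {
    cand <- phase1$candidates[k, ]
    contig <- build_fusion_contig(gms, genome, cand$gene5, cand$gene3, config)
    aln <- realign_to_contig(cand$read_ids[[1]], contig, aligner)
    aln <- snap_alignment_ends(aln, contig$boundaries, config$snap_dist)
    ev <- classify_fusion_reads(aln, contig, similarity, config)
    tal <- tally_breakpoints(ev, contig, phase1$total_reads, config)
    rows[[length(rows) + 1]] <- tal
  }
  tal_all <- dplyr::bind_rows(rows)
  if (nrow(tal_all) > 0) tal_all <- apply_final_filters(tal_all, config)
  as_fusion_report(tal_all)
}

as_fusion_report <- function(tallies) {
  if (nrow(tallies) == 0) {
    rep <- tibble(FusionName = character(), LeftGene = character(),
                  LeftBreakpoint = character(), RightGene = character(),
                  RightBreakpoint = character(), NumLongReads = integer(),
                  LR_FFPM = double(), SpliceType = character(),
                  Annotations = character(), LongReadIds = character())
  } else {
    shared <- tallies |>
      tidyr::unnest("read_ids") |>
      group_by(.data$read_ids) |>
      filter(dplyr::n_distinct(.data$fusion_name) > 1) |>
      ungroup()
    rep <- tallies |>
      mutate(
        FusionName = .data$fusion_name,
        LeftGene = .data$gene5, LeftBreakpoint = .data$breakpoint5,
        RightGene = .data$gene3, RightBreakpoint = .data$breakpoint3,
        NumLongReads = as.integer(.data$n_reads),
        LR_FFPM = .data$ffpm,
        SpliceType = ifelse(.data$splice_class == "consensus",
                            "ONLY_REF_SPLICE", "INCL_NON_REF_SPLICE"),
        Annotations = ifelse(
          purrr::map_lgl(.data$read_ids, ~ any(.x %in% shared$read_ids)),
          "shared_supporting_reads", "."),
        LongReadIds = purrr::map_chr(.data$read_ids, paste, collapse = ",")
      ) |>
      select("FusionName":"LongReadIds") |>
      arrange(desc(.data$NumLongReads), .data$FusionName,
              .data$LeftBreakpoint, .data$RightBreakpoint)
  }
  class(rep) <- c("fusion_report", class(rep))
  rep
}

#' Read and write fusion reports
#'
#' The report is a tab-delimited table with one row per retained fusion
#' breakpoint: `#FusionName`, `LeftGene`, `LeftBreakpoint`
#' (`chrom:pos:strand`, 1-based), `RightGene`, `RightBreakpoint`,
#' `NumLongReads`, `LR_FFPM`, `SpliceType` (`ONLY_REF_SPLICE` or
#' `INCL_NON_REF_SPLICE`), `Annotations`, `LongReadIds` (comma-joined),
#' and optionally `CellBarcodes`. Rows are ordered by descending read
#' support, then fusion name. `read_fusion_report` round-trips exactly.
#'
#' @param report A `fusion_report` tibble.
#' @param path Output (input) TSV path.
#' @return `write_fusion_report`: `path`, invisibly;
#'   `read_fusion_report`: the report tibble.
#' @export
write_fusion_report <- function(report, path) {
  hdr <- names(report)
  hdr[1] <- paste0("#", hdr[1])
  lines <- paste(hdr, collapse = "\t")
  if (nrow(report) > 0) {
    body <- do.call(paste, c(purrr::map(report, as.character), sep = "\t"))
    lines <- c(lines, body)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_fusion_report
#' @export
read_fusion_report <- function(path) {
  rep <- readr::read_tsv(path, col_types = readr::cols(
    NumLongReads = readr::col_integer(), LR_FFPM = readr::col_double(),
    .default = readr::col_character()))
  names(rep)[1] <- sub("^#", "", names(rep)[1])
  class(rep) <- c("fusion_report", class(rep))
  rep
}
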