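#' Specification for a synthetic fusion transcriptome
#'
#' Describes a toy genome, its gene models, a plan of fusion transcripts
#' fused at exon junctions, background (non-fusion) transcripts, and an
#' error-bearing long-read set. Every quantity the downstream caller tests
#' is controlled here, and the whole dataset is deterministic under `seed`.
#'
#' Genes are placed one per chromosome so any fused pair constitutes two
#' distinct genomic loci, as for a genuine inter-chromosomal fusion. Every
#' simulated intron carries GT..AG terminal dinucleotides on the coding
#' strand, so fusion breakpoints constructed at exon junctions fall on
#' consensus splice sites by construction.
#'
#' @param seed Integer RNG seed; the same seed reproduces every emitted
#'   file byte-for-byte.
#' @param n_genes Number of genes (one per chromosome).
#' @param exons_per_gene Length-2 range for the exon count per gene.
#' @param exon_len,intron_len Length-2 base-pair ranges.
#' @param n_fusions Number of planned fusion transcripts (ignored when
#'   `fusion_plan` is supplied). Fusion partners are distinct genes, each
#'   used at most once; donor exons are internal (not the gene's last exon)
#'   and acceptor exons are never the first exon, so both breakpoints sit
#'   at genuine splice junctions.
#' @param fusion_reads Length-2 range for reads per planned fusion.
#' @param fusion_plan Optional tibble (`gene5`, `gene3`, `donor_exon`,
#'   `acceptor_exon`, `n_reads`) overriding the automatic plan. Exon
#'   indices are transcript 5' to 3' ranks.
#' @param background_reads Total non-chimeric reads, spread evenly over all
#'   genes.
#' @param sub_rate,ins_rate,del_rate Per-base i.i.d. error rates in [0,1].
#' @param truncation_prob Probability that a read is 3'-anchored truncated
#'   (keeping a uniform 50--100% suffix), emulating incomplete cDNAs.
#' @param strand_mode `"sense"` (reads in transcript orientation) or
#'   `"both"` (each read flipped to the antisense strand with probability
#'   1/2, as for unstranded cDNA).
#' @param cell_plan Optional single-cell plan: tibble (`barcode`, `fusion`
#'   (row index into the fusion plan), `n_umis`, `reads_per_umi`). When
#'   given, fusion read counts derive from the plan and all read names are
#'   tagged `barcode^umi^core`.
#' @return A `sim_spec` object (a validated list).
#' @export
sim_spec <- function(seed = 1L,
                     n_genes = 20L,
                     exons_per_gene = c(3L, 6L),
                     exon_len = c(100L, 300L),
                     intron_len = c(60L, 1500L),
                     n_fusions = 5L,
                     fusion_reads = c(3L, 10L),
                     fusion_plan = NULL,
                     background_reads = 200L,
                     sub_rate = 0.01,
                     ins_rate = 0,
                     del_rate = 0,
                     truncation_prob = 0,
                     strand_mode = c("sense", "both"),
                     cell_plan = NULL) {
  strand_mode <- match.arg(strand_mode)
  rates <- c(sub_rate, ins_rate, del_rate, truncation_prob)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (!is.null(fusion_plan)) fusion_plan <- as_tibble(fusion_plan)
  if (!is.null(cell_plan)) {
    cell_plan <- as_tibble(cell_plan)
    if (!"reads_per_umi" %in% names(cell_plan)) cell_plan$reads_per_umi <- 1L
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene), exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len), n_fusions = as.integer(n_fusions),
    fusion_reads = as.integer(fusion_reads), fusion_plan = fusion_plan,
    background_reads = as.integer(background_reads),
    sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
    truncation_prob = truncation_prob, strand_mode = strand_mode,
    cell_plan = cell_plan
  ), class = "sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic fusion transcriptome dataset
#'
#' Builds the genome and annotation, constructs the planned fusion and
#' background transcripts, simulates error-bearing long reads, and records
#' ideal (planned) alignments in both segment-level and exon-block-level
#' form. The result feeds the fusion caller directly (in memory) or via
#' [write_sim_dataset()] as standard FASTA/GTF/FASTQ/PAF/TSV files.
#'
#' @param spec A [sim_spec()].
#' @return A `sim_dataset` list with elements `genome`
#'   (\link[Biostrings]{DNAStringSet}), `gms` ([gene_model_set()]),
#'   `transcripts`, `truth`, `reads`, `segments` (ideal alignment
#'   segments), `read_blocks` (per-read exon-level placements), and the
#'   `spec` echo.
#' @export
simulate_fusion_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)

  ## ---- genome & annotation -------------------------------------------
  gene_tbl <- purrr::map_dfr(seq_len(spec$n_genes), function(i) {
    n_ex <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]), 1)
    tibble(gene_id = sprintf("G%02d", i), chrom = sprintf("chr%d", i),
           strand = sample(c("+", "-"), 1), n_exons = n_ex)
  })

  genome <- character(0)
  exon_rows <- list()
  for (i in seq_len(nrow(gene_tbl))) {
    g <- gene_tbl[i, ]
    ex_lens <- sample(seq(spec$exon_len[1], spec$exon_len[2]), g$n_exons,
                      replace = TRUE)
    in_lens <- if (g$n_exons > 1) {
      sample(seq(max(10L, spec$intron_len[1]), spec$intron_len[2]),
             g$n_exons - 1, replace = TRUE)
    } else integer(0)
    ex_seqs <- purrr::map_chr(ex_lens, random_dna)
    in_seqs <- purrr::map_chr(in_lens, function(l) {
      paste0("GT", random_dna(l - 4L), "AG")
    })
    pieces <- character(0)
    coding_start <- integer(g$n_exons); coding_end <- integer(g$n_exons)
    off <- 0L
    for (k in seq_len(g$n_exons)) {
      coding_start[k] <- off; coding_end[k] <- off + ex_lens[k]
      pieces <- c(pieces, ex_seqs[k])
      off <- off + ex_lens[k]
      if (k < g$n_exons) { pieces <- c(pieces, in_seqs[k]); off <- off + in_lens[k] }
    }
    region <- paste(pieces, collapse = "")
    L <- nchar(region)
    pad5 <- random_dna(sample(150:250, 1)); pad3 <- random_dna(sample(150:250, 1))
    if (g$strand == "+") {
      chrom_seq <- paste0(pad5, region, pad3)
      gstart <- nchar(pad5) + coding_start; gend <- nchar(pad5) + coding_end
    } else {
      chrom_seq <- paste0(pad5, revcomp(region), pad3)
      gstart <- nchar(pad5) + (L - coding_end); gend <- nchar(pad5) + (L - coding_start)
    }
    genome[g$chrom] <- chrom_seq
    exon_rows[[i]] <- tibble(
      gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1"),
      chrom = g$chrom, strand = g$strand,
      start = as.integer(gstart), end = as.integer(gend)
    )
  }
  genome <- Biostrings::DNAStringSet(genome)
  gms <- gene_model_set(dplyr::bind_rows(exon_rows))

  ## ---- fusion plan ----------------------------------------------------
  plan <- spec$fusion_plan
  if (is.null(plan)) {
    eligible5 <- gene_tbl |> filter(.data$n_exons >= 2)
    picked <- sample(eligible5$gene_id, 2L * spec$n_fusions)
    plan <- purrr::map_dfr(seq_len(spec$n_fusions), function(k) {
      g5 <- picked[2 * k - 1]; g3 <- picked[2 * k]
      n5 <- gene_tbl$n_exons[gene_tbl$gene_id == g5]
      n3 <- gene_tbl$n_exons[gene_tbl$gene_id == g3]
      tibble(gene5 = g5, gene3 = g3,
             donor_exon = sample(seq_len(n5 - 1L), 1),
             acceptor_exon = sample(2:n3, 1),
             n_reads = sample(seq(spec$fusion_reads[1], spec$fusion_reads[2]), 1))
    })
  }
  if (!is.null(spec$cell_plan)) {
    per_fusion <- spec$cell_plan |>
      group_by(.data$fusion) |>
      summarise(n_reads = sum(.data$n_umis * .data$reads_per_umi), .groups = "drop")
    plan$n_reads <- 0L
    plan$n_reads[per_fusion$fusion] <- per_fusion$n_reads
  }

  ## ---- transcript block plans ----------------------------------------
  tx_exons <- function(gene_id, ranks = NULL) {
    e <- gms$exons |> filter(.data$gene_id == !!gene_id) |> arrange(.data$exon_rank)
    if (!is.null(ranks)) e <- e |> filter(.data$exon_rank %in% ranks)
    e |> arrange(.data$exon_rank)
  }
  block_plan <- function(exs, segment) {
    tibble(chrom = exs$chrom, strand = exs$strand, gene_id = exs$gene_id,
           genome_start = exs$start, genome_end = exs$end, segment = segment)
  }
  spliced_seq <- function(exs) {
    paste(purrr::map_chr(seq_len(nrow(exs)), function(k) {
      s <- as.character(Biostrings::subseq(genome[[exs$chrom[k]]],
                                           exs$start[k] + 1L, exs$end[k]))
      if (exs$strand[k] == "-") revcomp(s) else s
    }), collapse = "")
  }

  transcripts <- list()
  if (nrow(plan) > 0) {
    for (k in seq_len(nrow(plan))) {
      p <- plan[k, ]
      e5 <- tx_exons(p$gene5, seq_len(p$donor_exon))
      n3 <- max(tx_exons(p$gene3)$exon_rank)
      e3 <- tx_exons(p$gene3, seq(p$acceptor_exon, n3))
      donor <- e5[nrow(e5), ]; acceptor <- e3[1, ]
      bp5 <- if (donor$strand == "+") format_breakpoint(donor$chrom, donor$end - 1L, "+")
             else format_breakpoint(donor$chrom, donor$start, "-")
      bp3 <- if (acceptor$strand == "+") format_breakpoint(acceptor$chrom, acceptor$start, "+")
             else format_breakpoint(acceptor$chrom, acceptor$end - 1L, "-")
      transcripts[[length(transcripts) + 1]] <- list(
        transcript_id = sprintf("fusion%02d|%s--%s", k, p$gene5, p$gene3),
        type = "fusion", gene5 = p$gene5, gene3 = p$gene3,
        breakpoint5 = bp5, breakpoint3 = bp3, n_reads = p$n_reads,
        fusion_index = k,
        blocks = dplyr::bind_rows(block_plan(e5, 1L), block_plan(e3, 2L)),
        seq = paste0(spliced_seq(e5), spliced_seq(e3))
      )
    }
  }
  per_gene_bg <- floor(spec$background_reads / spec$n_genes)
  extra <- spec$background_reads - per_gene_bg * spec$n_genes
  for (i in seq_len(nrow(gene_tbl))) {
    n_bg <- per_gene_bg + as.integer(i <= extra)
    if (n_bg == 0) next
    exs <- tx_exons(gene_tbl$gene_id[i])
    transcripts[[length(transcripts) + 1]] <- list(
      transcript_id = paste0(gene_tbl$gene_id[i], ".t1"),
      type = "background", gene5 = gene_tbl$gene_id[i], gene3 = NA_character_,
      breakpoint5 = NA_character_, breakpoint3 = NA_character_, n_reads = n_bg,
      fusion_index = NA_integer_,
      blocks = block_plan(exs, 1L), seq = spliced_seq(exs)
    )
  }

  truth <- purrr::map_dfr(transcripts, function(t) {
    if (t$type != "fusion") return(NULL)
    tibble(sample = "sim", gene5 = t$gene5, gene3 = t$gene3,
           breakpoint5 = t$breakpoint5, breakpoint3 = t$breakpoint3,
           num_reads = t$n_reads)
  })

  ## ---- reads with errors + ideal alignments --------------------------
  reads <- list(); segments <- list(); read_blocks <- list()
  read_counter <- 0L
  cell_queue <- NULL
  if (!is.null(spec$cell_plan)) {
    cell_queue <- spec$cell_plan |>
      tidyr::uncount(.data$n_umis, .id = "umi_idx") |>
      mutate(umi = purrr::map_chr(row_number(), ~ random_dna(8L)))
  }

  for (t in transcripts) {
    if (t$n_reads == 0) next
    name_tags <- NULL
    reps <- rep(1L, t$n_reads)
    if (!is.null(cell_queue) && t$type == "fusion") {
      cq <- cell_queue |> filter(.data$fusion == t$fusion_index)
      name_tags <- cq[rep(seq_len(nrow(cq)), cq$reads_per_umi), c("barcode", "umi")]
      reps <- rep(1L, nrow(name_tags))
    }
    n_reads_t <- if (is.null(name_tags)) t$n_reads else nrow(name_tags)
    for (r in seq_len(n_reads_t)) {
      read_counter <- read_counter + 1L
      core_id <- sprintf("read%05d|%s", read_counter, t$transcript_id)
      read_id <- core_id
      if (!is.null(name_tags)) {
        read_id <- paste(name_tags$barcode[r], name_tags$umi[r], core_id, sep = "^")
      } else if (!is.null(cell_queue) && t$type == "background") {
        bc <- sample(unique(cell_queue$barcode), 1)
        read_id <- paste(bc, random_dna(8L), core_id, sep = "^")
      }
      blocks <- t$blocks
      # optional 3'-anchored truncation: drop a 5' prefix of the transcript
      if (spec$truncation_prob > 0 && stats::runif(1) < spec$truncation_prob) {
        keep_frac <- stats::runif(1, 0.5, 1)
        tx_len <- sum(blocks$genome_end - blocks$genome_start)
        drop5 <- as.integer(floor((1 - keep_frac) * tx_len))
        blocks <- trim_blocks_5prime(blocks, drop5)
      }
      sim <- simulate_read_from_blocks(blocks, genome, spec$sub_rate,
                                       spec$ins_rate, spec$del_rate)
      if (spec$strand_mode == "both" && stats::runif(1) < 0.5) {
        sim <- flip_simulated_read(sim)
      }
      reads[[read_counter]] <- tibble(read_id = read_id, seq = sim$seq,
                                      transcript_id = t$transcript_id,
                                      type = t$type)
      segments[[read_counter]] <- sim$segments |> mutate(read_id = read_id)
      read_blocks[[read_counter]] <- sim$blocks |> mutate(read_id = read_id)
    }
  }

  structure(list(
    genome = genome, gms = gms,
    transcripts = purrr::map_dfr(transcripts, function(t) {
      tibble(transcript_id = t$transcript_id, type = t$type, gene5 = t$gene5,
             gene3 = t$gene3, breakpoint5 = t$breakpoint5,
             breakpoint3 = t$breakpoint3, n_reads = t$n_reads,
             seq = t$seq)
    }),
    fusion_plan = plan, truth = truth,
    reads = dplyr::bind_rows(reads),
    segments = dplyr::bind_rows(segments) |>
      select("read_id", dplyr::everything()),
    read_blocks = dplyr::bind_rows(read_blocks) |>
      select("read_id", dplyr::everything()),
    spec = spec
  ), class = "sim_dataset")
}

trim_blocks_5prime <- function(blocks, drop) {
  out <- list()
  for (k in seq_len(nrow(blocks))) {
    b <- blocks[k, ]
    len <- b$genome_end - b$genome_start
    if (drop >= len) { drop <- drop - len; next }
    if (drop > 0) {
      if (b$strand == "+") b$genome_start <- b$genome_start + drop
      else b$genome_end <- b$genome_end - drop
      drop <- 0L
    }
    out[[length(out) + 1]] <- b
  }
  dplyr::bind_rows(out)
}

# Apply i.i.d. per-base substitution/insertion/deletion to one exon block's
# transcript-orientation sequence; returns emitted characters and counts.
apply_block_errors <- function(chars, sub_rate, ins_rate, del_rate) {
  n <- length(chars)
  del <- stats::runif(n) < del_rate
  sub <- (stats::runif(n) < sub_rate) & !del
  ins <- stats::runif(n) < ins_rate
  if (any(sub)) {
    alts <- c("A", "C", "G", "T")
    chars[sub] <- purrr::map_chr(chars[sub], function(b) sample(setdiff(alts, b), 1))
  }
  pieces <- character(0)
  if (any(ins) || any(del)) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      v <- character(0)
      if (ins[i]) v <- sample(c("A", "C", "G", "T"), 1)
      if (!del[i]) v <- c(v, chars[i])
      out[[i]] <- v
    }
    pieces <- unlist(out)
  } else {
    pieces <- chars
  }
  list(seq = paste(pieces, collapse = ""), n_sub = sum(sub), n_ins = sum(ins),
       n_del = sum(del), emitted = length(pieces))
}

# Build one read from planned exon blocks: emit sequence with errors and
# record per-block read coordinates plus per-segment ideal alignments.
simulate_read_from_blocks <- function(blocks, genome, sub_rate, ins_rate, del_rate) {
  seq_parts <- character(nrow(blocks))
  res <- vector("list", nrow(blocks))
  off <- 0L
  blocks$read_start <- NA_integer_; blocks$read_end <- NA_integer_
  blocks$n_sub <- 0L; blocks$n_ins <- 0L; blocks$n_del <- 0L
  for (k in seq_len(nrow(blocks))) {
    b <- blocks[k, ]
    s <- as.character(Biostrings::subseq(genome[[b$chrom]],
                                         b$genome_start + 1L, b$genome_end))
    if (b$strand == "-") s <- revcomp(s)
    er <- apply_block_errors(strsplit(s, "")[[1]], sub_rate, ins_rate, del_rate)
    seq_parts[k] <- er$seq
    blocks$read_start[k] <- off
    blocks$read_end[k] <- off + er$emitted
    blocks$n_sub[k] <- er$n_sub; blocks$n_ins[k] <- er$n_ins; blocks$n_del[k] <- er$n_del
    off <- off + er$emitted
  }
  read_seq <- paste(seq_parts, collapse = "")
  segs <- blocks |>
    mutate(blen = .data$genome_end - .data$genome_start) |>
    group_by(.data$segment) |>
    summarise(
      chrom = first(.data$chrom), align_strand = first(.data$strand),
      gene_id = first(.data$gene_id),
      read_start = min(.data$read_start), read_end = max(.data$read_end),
      ref_len = sum(.data$blen),
      matches = sum(.data$blen - .data$n_sub - .data$n_del),
      block_len = sum(.data$blen + .data$n_ins),
      genome_start = min(.data$genome_start), genome_end = max(.data$genome_end),
      .groups = "drop"
    ) |>
    mutate(read_len = nchar(read_seq),
           identity = ifelse(.data$block_len > 0,
                             .data$matches / .data$block_len, 0))
  list(seq = read_seq, segments = segs, blocks = blocks)
}

# Reverse-complement a simulated read, flipping read coordinates and strands.
flip_simulated_read <- function(sim) {
  L <- nchar(sim$seq)
  flip_strand <- function(s) ifelse(s == "+", "-", "+")
  sim$seq <- revcomp(sim$seq)
  sim$segments <- sim$segments |>
    mutate(rs = L - .data$read_end, re = L - .data$read_start,
           read_start = .data$rs, read_end = .data$re,
           align_strand = flip_strand(.data$align_strand)) |>
    select(-"rs", -"re")
  sim$blocks <- sim$blocks |>
    mutate(rs = L - .data$read_end, re = L - .data$read_start,
           read_start = .data$rs, read_end = .data$re,
           strand = flip_strand(.data$strand)) |>
    select(-"rs", -"re")
  sim
}

#' Construct a single fusion transcript sequence and its truth breakpoints
#'
#' Joins the 5' partner's exons 1..`donor_exon` to the 3' partner's exons
#' `acceptor_exon`..last (transcript order; minus-strand genes contribute
#' reverse-complemented genomic sequence), returning the spliced sequence
#' and the genomic breakpoints of the junction.
#'
#' @param gms A [gene_model_set()].
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param gene5,gene3 Gene ids of the 5' and 3' partners.
#' @param donor_exon,acceptor_exon Exon ranks (transcript 5' to 3').
#' @return A list with `seq`, `breakpoint5`, `breakpoint3` (1-based
#'   `chrom:pos:strand` strings).
#' @export
construct_fusion_transcript <- function(gms, genome, gene5, donor_exon,
                                        gene3, acceptor_exon) {
  get_ex <- function(gid, ranks) {
    e <- gms$exons |> filter(.data$gene_id == gid) |> arrange(.data$exon_rank)
    if (nrow(e) == 0) abort(sprintf("unknown gene '%s'", gid))
    if (any(!ranks %in% e$exon_rank)) abort("exon rank out of range")
    e |> filter(.data$exon_rank %in% ranks) |> arrange(.data$exon_rank)
  }
  n3 <- max((gms$exons |> filter(.data$gene_id == gene3))$exon_rank)
  e5 <- get_ex(gene5, seq_len(donor_exon))
  e3 <- get_ex(gene3, seq(acceptor_exon, n3))
  splice <- function(exs) {
    paste(purrr::map_chr(seq_len(nrow(exs)), function(k) {
      s <- as.character(Biostrings::subseq(genome[[exs$chrom[k]]],
                                           exs$start[k] + 1L, exs$end[k]))
      if (exs$strand[k] == "-") revcomp(s) else s
    }), collapse = "")
  }
  donor <- e5[nrow(e5), ]; acceptor <- e3[1, ]
  list(
    seq = paste0(splice(e5), splice(e3)),
    breakpoint5 = if (donor$strand == "+")
      format_breakpoint(donor$chrom, donor$end - 1L, "+")
    else format_breakpoint(donor$chrom, donor$start, "-"),
    breakpoint3 = if (acceptor$strand == "+")
      format_breakpoint(acceptor$chrom, acceptor$start, "+")
    else format_breakpoint(acceptor$chrom, acceptor$end - 1L, "-")
  )
}

#' Write a simulated dataset as standard files
#'
#' Emits `genome.fa`, `annotation.gtf`, `reads.fastq`, `alignments.paf`
#' (the ideal segment-level alignments), and `truth.tsv` (the benchmark
#' truth dialect) into `dir`.
#'
#' @param sim A `sim_dataset` from [simulate_fusion_dataset()].
#' @param dir Output directory (created if needed).
#' @return A named list of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    fastq = file.path(dir, "reads.fastq"),
    paf = file.path(dir, "alignments.paf"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_gtf(sim$gms, paths$gtf)
  fq <- character(4L * nrow(sim$reads))
  fq[seq(1, length(fq), 4)] <- paste0("@", sim$reads$read_id)
  fq[seq(2, length(fq), 4)] <- sim$reads$seq
  fq[seq(3, length(fq), 4)] <- "+"
  fq[seq(4, length(fq), 4)] <- strrep("I", nchar(sim$reads$seq))
  readr::write_lines(fq, paths$fastq)
  write_paf(sim$segments, paths$paf,
            tlen = setNames(Biostrings::width(sim$genome), names(sim$genome)))
  readr::write_tsv(sim$truth, paths$truth)
  invisible(paths)
}
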