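#' Build a fusion contig for a candidate gene pair
#'
#' Models the proposed fusion as a single sequence: the 5' gene's
#' (collapsed) exon structure followed by the 3' gene's, each in
#' transcribed orientation (minus-strand genes reverse-complemented), with
#' every intron longer than `intron_cap` bases shrunk to its first and
#' last `intron_flank` bases — preserving the splice dinucleotides at both
#' intron ends — and a run of `N`s separating the two genes so that
#' realignments cannot bridge them spuriously. An exact bidirectional
#' contig/genome coordinate map is recorded alongside.
#'
#' @param gms A [gene_model_set()].
#' @param genome A \link[Biostrings]{DNAStringSet} of chromosome
#'   sequences.
#' @param gene5,gene3 Gene ids in transcribed fusion order.
#' @param config A [fusion_config()] (uses `intron_cap`, `intron_flank`,
#'   `spacer_len`).
#' @return A `fusion_contig` object: `contig_id` ("gene5--gene3"), `seq`,
#'   the coordinate `map` (one row per contig block), `exon_blocks`, the
#'   contig-coordinate exon `boundaries` per gene, and the per-gene contig
#'   ranges.
#' @export
build_fusion_contig <- function(gms, genome, gene5, gene3,
                                config = fusion_config()) {
  stopifnot(inherits(gms, "gene_model_set"))
  for (g in c(gene5, gene3)) {
    if (!g %in% gms$genes$gene_id) abort(sprintf("unknown gene '%s'", g))
    chrom <- gms$genes$chrom[gms$genes$gene_id == g]
    if (!chrom %in% names(genome)) {
      abort(sprintf("chromosome '%s' of gene '%s' absent from genome", chrom, g))
    }
  }

  gene_blocks <- function(gid) {
    ex <- gms$exon_union |> filter(.data$gene_id == gid) |> arrange(.data$start)
    strand <- ex$strand[1]; chrom <- ex$chrom[1]
    blocks <- list()
    for (k in seq_len(nrow(ex))) {
      blocks[[length(blocks) + 1]] <- tibble(
        chrom = chrom, genome_start = ex$start[k], genome_end = ex$end[k],
        strand = strand, gene_id = gid, type = "exon")
      if (k < nrow(ex)) {
        istart <- ex$end[k]; iend <- ex$start[k + 1]
        ilen <- iend - istart
        if (ilen <= config$intron_cap) {
          blocks[[length(blocks) + 1]] <- tibble(
            chrom = chrom, genome_start = istart, genome_end = iend,
            strand = strand, gene_id = gid, type = "intron")
        } else {
          blocks[[length(blocks) + 1]] <- tibble(
            chrom = chrom, genome_start = istart,
            genome_end = istart + config$intron_flank,
            strand = strand, gene_id = gid, type = "intron")
          blocks[[length(blocks) + 1]] <- tibble(
            chrom = chrom, genome_start = iend - config$intron_flank,
            genome_end = iend, strand = strand, gene_id = gid, type = "intron")
        }
      }
    }
    b <- dplyr::bind_rows(blocks)
    if (strand == "-") b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
    b
  }

  blocks5 <- gene_blocks(gene5)
  blocks3 <- gene_blocks(gene3)
  spacer <- tibble(chrom = NA_character_, genome_start = NA_integer_,
                   genome_end = NA_integer_, strand = "+",
                   gene_id = NA_character_, type = "spacer")
  map <- dplyr::bind_rows(blocks5, spacer, blocks3)
  map$len <- ifelse(map$type == "spacer", config$spacer_len,
                    map$genome_end - map$genome_start)
  map$contig_start <- cumsum(c(0L, map$len[-nrow(map)]))
  map$contig_end <- map$contig_start + map$len

  seqs <- purrr::map_chr(seq_len(nrow(map)), function(k) {
    m <- map[k, ]
    if (m$type == "spacer") return(strrep("N", config$spacer_len))
    s <- as.character(Biostrings::subseq(genome[[m$chrom]],
                                         m$genome_start + 1L, m$genome_end))
    if (m$strand == "-") revcomp(s) else s
  })

  exon_blocks <- map |> filter(.data$type == "exon")
  boundaries <- sort(unique(c(exon_blocks$contig_start, exon_blocks$contig_end)))

  structure(list(
    contig_id = paste0(gene5, "--", gene3),
    gene5 = gene5, gene3 = gene3,
    seq = paste(seqs, collapse = ""),
    map = map |> select("contig_start", "contig_end", "chrom",
                        "genome_start", "genome_end", "strand", "gene_id", "type"),
    exon_blocks = exon_blocks |>
      select("gene_id", "contig_start", "contig_end", "chrom",
             "genome_start", "genome_end", "strand"),
    boundaries = as.integer(boundaries),
    config = config
  ), class = "fusion_contig") |>
    fix_gene_ranges()
}

fix_gene_ranges <- function(fc) {
  m5 <- fc$map |> filter(.data$gene_id == fc$gene5)
  m3 <- fc$map |> filter(.data$gene_id == fc$gene3)
  fc$gene5_range <- c(min(m5$contig_start), max(m5$contig_end))
  fc$gene3_range <- c(min(m3$contig_start), max(m3$contig_end))
  fc
}

#' @export
print.fusion_contig <- function(x, ...) {
  cat(sprintf("<fusion_contig> %s: %d bp, %d mapped block(s)\n",
              x$contig_id, nchar(x$seq), nrow(x$map)))
  invisible(x)
}

#' Map positions between contig and genome coordinates
#'
#' Exact affine mapping within each contig block. `contig_to_genome` of a
#' spacer base returns `NA`; a position outside the contig is an error.
#' `genome_to_contig` of a base dropped by intron shrinking returns `NA`
#' (unmapped). All positions are 0-based.
#'
#' @param contig A `fusion_contig`.
#' @param pos Integer vector of 0-based contig positions.
#' @return For `contig_to_genome`, a tibble `contig_pos`, `chrom`, `pos`,
#'   `strand`, `gene_id`; for `genome_to_contig`, a tibble `chrom`,
#'   `genome_pos`, `contig_pos` (`NA` when unmapped).
#' @export
contig_to_genome <- function(contig, pos) {
  stopifnot(inherits(contig, "fusion_contig"))
  pos <- as.integer(pos)
  clen <- nchar(contig$seq)
  if (any(pos < 0 | pos >= clen)) {
    abort(sprintf("contig position outside [0, %d)", clen))
  }
  m <- contig$map
  purrr::map_dfr(pos, function(p) {
    row <- m |> filter(.data$contig_start <= p, p < .data$contig_end)
    row <- row[1, ]
    if (row$type == "spacer") {
      return(tibble(contig_pos = p, chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, gene_id = NA_character_))
    }
    g <- if (row$strand == "+") row$genome_start + (p - row$contig_start)
         else row$genome_end - 1L - (p - row$contig_start)
    tibble(contig_pos = p, chrom = row$chrom, pos = as.integer(g),
           strand = row$strand, gene_id = row$gene_id)
  })
}

#' @param chrom Chromosome name(s) for `genome_to_contig` (recycled).
#' @param gene_id Optional gene id restricting the genome-to-contig search
#'   (needed if the two genes' blocks could share coordinates).
#' @rdname contig_to_genome
#' @export
genome_to_contig <- function(contig, chrom, pos, gene_id = NULL) {
  stopifnot(inherits(contig, "fusion_contig"))
  pos <- as.integer(pos)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  m <- contig$map |> filter(.data$type != "spacer")
  if (!is.null(gene_id)) m <- m |> filter(.data$gene_id == !!gene_id)
  purrr::map_dfr(seq_len(n), function(i) {
    want_chrom <- chrom[i]; want_pos <- pos[i]
    row <- m |> filter(.data$chrom == want_chrom,
                       .data$genome_start <= want_pos,
                       want_pos < .data$genome_end)
    if (nrow(row) == 0) {
      return(tibble(chrom = chrom[i], genome_pos = pos[i],
                    contig_pos = NA_integer_))
    }
    row <- row[1, ]
    cp <- if (row$strand == "+") row$contig_start + (pos[i] - row$genome_start)
          else row$contig_start + (row$genome_end - 1L - pos[i])
    tibble(chrom = chrom[i], genome_pos = pos[i], contig_pos = as.integer(cp))
  })
}

#' Export fusion contigs for inspection
#'
#' Writes the contig sequences as FASTA and the block table (contig block
#' coordinates with their genomic sources, 1-based in the table) as a
#' BED-like TSV.
#'
#' @param contigs A list of `fusion_contig` objects.
#' @param fasta_path,blocks_path Output paths (either may be NULL to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_contigs <- function(contigs, fasta_path = NULL, blocks_path = NULL) {
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(purrr::map_chr(contigs, "seq"))
    names(ss) <- purrr::map_chr(contigs, "contig_id")
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  if (!is.null(blocks_path)) {
    tab <- purrr::map_dfr(contigs, function(fc) {
      fc$map |> mutate(contig = fc$contig_id, .before = 1)
    })
    readr::write_tsv(tab, blocks_path)
  }
  invisible(c(fasta_path, blocks_path))
}
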