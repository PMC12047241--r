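#' Gene model sets
#'
#' A `gene_model_set` holds reference gene structures: one record per gene,
#' each with one or more transcripts made of ordered exon intervals. All
#' internal coordinates are 0-based half-open; GTF input/output converts
#' to and from the conventional 1-based closed representation.
#'
#' The object bundles four tibbles:
#' \describe{
#'   \item{genes}{`gene_id`, `symbol`, `chrom`, `strand`, `span_start`,
#'     `span_end` — the span covers all exons of the gene.}
#'   \item{exons}{`gene_id`, `transcript_id`, `chrom`, `strand`, `start`,
#'     `end`, `exon_rank` (transcript 5' to 3' order).}
#'   \item{exon_union}{per-gene collapsed (reduced) exon intervals, used for
#'     exonic-overlap tests and fusion-contig construction.}
#'   \item{boundaries}{the exon-boundary index: every exon start and end of
#'     every transcript, tagged with the owning gene and the boundary side,
#'     sorted per chromosome.}
#' }
#'
#' @param exons A data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open). An optional
#'   `symbol` column supplies gene symbols (defaults to the gene id).
#' @return A `gene_model_set` object.
#' @examples
#' gms <- gene_model_set(tibble::tibble(
#'   gene_id = "G1", transcript_id = "G1.t1", chrom = "chr1", strand = "+",
#'   start = c(100, 300), end = c(200, 420)
#' ))
#' gms$genes
#' @export
gene_model_set <- function(exons) {
  exons <- as_tibble(exons)
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(exons) == 0) abort("exon table is empty")
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  if (any(exons$start >= exons$end)) {
    abort("every exon must satisfy start < end (0-based half-open)")
  }
  if (!"symbol" %in% names(exons)) exons$symbol <- exons$gene_id

  exons <- exons |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$gene_id, .data$transcript_id, .data$start)

  # one chrom/strand per gene
  bad <- exons |>
    group_by(.data$gene_id) |>
    summarise(nchrom = dplyr::n_distinct(.data$chrom),
              nstrand = dplyr::n_distinct(.data$strand), .groups = "drop") |>
    filter(.data$nchrom > 1 | .data$nstrand > 1)
  if (nrow(bad) > 0) {
    abort(paste0("gene(s) on multiple chromosomes or strands: ",
                 paste(bad$gene_id, collapse = ", ")))
  }

  # exons within a transcript must be non-overlapping
  ovl <- exons |>
    group_by(.data$gene_id, .data$transcript_id) |>
    filter(dplyr::lag(.data$end, default = -1L) > .data$start) |>
    ungroup()
  if (nrow(ovl) > 0) {
    abort(paste0("overlapping exons within transcript(s): ",
                 paste(unique(ovl$transcript_id), collapse = ", ")))
  }

  # exon_rank follows transcription: genomic order for '+', reversed for '-'
  exons <- exons |>
    group_by(.data$gene_id, .data$transcript_id) |>
    mutate(exon_rank = if (first(.data$strand) == "+") row_number()
           else rev(row_number())) |>
    ungroup()

  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(symbol = first(.data$symbol), chrom = first(.data$chrom),
              strand = first(.data$strand),
              span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop")

  exon_union <- exons |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end) |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      r <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      tibble(chrom = df$chrom[1], strand = df$strand[1],
             start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    ungroup() |>
    arrange(.data$gene_id, .data$start)

  boundaries <- dplyr::bind_rows(
    exons |> distinct(.data$chrom, pos = .data$start, .data$gene_id) |>
      mutate(side = "exon_start"),
    exons |> distinct(.data$chrom, pos = .data$end, .data$gene_id) |>
      mutate(side = "exon_end")
  ) |>
    distinct() |>
    arrange(.data$chrom, .data$pos, .data$gene_id)

  structure(
    list(genes = genes, exons = exons, exon_union = exon_union,
         boundaries = boundaries),
    class = "gene_model_set"
  )
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf(
    "<gene_model_set> %d genes, %d transcripts, %d exon records on %d chromosome(s)\n",
    nrow(x$genes), dplyr::n_distinct(x$exons$transcript_id), nrow(x$exons),
    dplyr::n_distinct(x$genes$chrom)))
  invisible(x)
}

#' Minimum distance from a position to an annotated exon boundary
#'
#' Scans the exon-boundary index for the boundary closest to `pos` on
#' `chrom` and reports the absolute distance in bases together with the
#' owning gene. A position that is itself a boundary has distance 0. Ties
#' are broken in favour of the boundary at the smaller genomic coordinate
#' (and then the lexicographically smaller gene id).
#'
#' @param gms A [gene_model_set()].
#' @param chrom Chromosome name (must exist in the index).
#' @param pos Integer vector of positions, in the same half-open convention
#'   as the index (exon starts are 0-based starts, exon ends are exclusive
#'   ends), so alignment-segment endpoints can be compared directly.
#' @param gene_id Optional single gene id: restrict the search to that
#'   gene's boundaries.
#' @return A tibble with one row per query: `pos`, `distance`,
#'   `nearest_gene_id`, `boundary_pos`.
#' @export
min_exon_boundary_distance <- function(gms, chrom, pos, gene_id = NULL) {
  stopifnot(inherits(gms, "gene_model_set"))
  assert_scalar_chr(chrom, "chrom")
  b <- gms$boundaries |> filter(.data$chrom == !!chrom)
  if (!is.null(gene_id)) b <- b |> filter(.data$gene_id == !!gene_id)
  if (nrow(b) == 0) {
    abort(sprintf("no exon boundaries indexed on chromosome '%s'%s", chrom,
                  if (is.null(gene_id)) "" else sprintf(" for gene '%s'", gene_id)))
  }
  purrr::map_dfr(as.integer(pos), function(p) {
    d <- abs(b$pos - p)
    dmin <- min(d)
    hits <- which(d == dmin)
    # ties: smaller coordinate, then smaller gene id
    hit <- hits[order(b$pos[hits], b$gene_id[hits])][1]
    tibble(pos = p, distance = dmin, nearest_gene_id = b$gene_id[hit],
           boundary_pos = b$pos[hit])
  })
}

#' Gene pairs with overlapping genomic spans
#'
#' Returns every unordered pair of distinct genes whose spans intersect on
#' the same chromosome, ignoring strand. Such pairs are excluded as fusion
#' candidates (read-through/overlap artifacts) and serve as proxy
#' equivalences in benchmarking.
#'
#' @param gms A [gene_model_set()].
#' @return A tibble with columns `gene1`, `gene2` (`gene1 < gene2`).
#' @export
overlapping_gene_pairs <- function(gms) {
  stopifnot(inherits(gms, "gene_model_set"))
  g <- gms$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$span_start + 1L, g$span_end))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  tibble(
    gene1 = pmin(g$gene_id[S4Vectors::queryHits(hits)],
                 g$gene_id[S4Vectors::subjectHits(hits)]),
    gene2 = pmax(g$gene_id[S4Vectors::queryHits(hits)],
                 g$gene_id[S4Vectors::subjectHits(hits)])
  ) |>
    distinct() |>
    arrange(.data$gene1, .data$gene2)
}

#' Exon sequence-similarity and paralog lookups
#'
#' Loads the optional plug-in tables describing (a) pairs of exonic regions
#' shared between two genes that are sequence-similar (e.g. precomputed from
#' an all-vs-all BLASTN of annotated exons) and (b) paralogous gene symbol
#' pairs. Both relations are symmetric. When a path is `NULL` or missing the
#' corresponding filter is disabled and a message is emitted.
#'
#' @param similarity_path TSV with columns `geneA`, `geneB`, `regionA`,
#'   `regionB`; regions as `chrom:start-end` (1-based closed).
#' @param paralog_path TSV with columns `symbolA`, `symbolB`.
#' @return A `similarity_map` object.
#' @export
read_similarity_map <- function(similarity_path = NULL, paralog_path = NULL) {
  regions <- tibble(gene1 = character(), gene2 = character(),
                    chrom1 = character(), start1 = integer(), end1 = integer(),
                    chrom2 = character(), start2 = integer(), end2 = integer())
  paralogs <- tibble(symbol1 = character(), symbol2 = character())

  if (!is.null(similarity_path) && file.exists(similarity_path)) {
    lines <- readr::read_lines(similarity_path)
    lines_keep <- which(!grepl("^#", lines) & nzchar(lines))
    rows <- purrr::map_dfr(lines_keep, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 4) {
        abort(sprintf("similarity file %s line %d: expected 4 tab-separated fields, got %d",
                      similarity_path, i, length(f)))
      }
      ra <- parse_region(f[3], similarity_path, i)
      rb <- parse_region(f[4], similarity_path, i)
      tibble(geneA = f[1], geneB = f[2],
             chromA = ra$chrom, startA = ra$start, endA = ra$end,
             chromB = rb$chrom, startB = rb$start, endB = rb$end)
    })
    if (nrow(rows) > 0) {
      swap <- rows$geneA > rows$geneB
      regions <- tibble(
        gene1  = ifelse(swap, rows$geneB, rows$geneA),
        gene2  = ifelse(swap, rows$geneA, rows$geneB),
        chrom1 = ifelse(swap, rows$chromB, rows$chromA),
        start1 = ifelse(swap, rows$startB, rows$startA),
        end1   = ifelse(swap, rows$endB, rows$endA),
        chrom2 = ifelse(swap, rows$chromA, rows$chromB),
        start2 = ifelse(swap, rows$startA, rows$startB),
        end2   = ifelse(swap, rows$endA, rows$endB)
      ) |> distinct()
    }
  } else if (!is.null(similarity_path)) {
    inform(sprintf("similarity file '%s' not found: exon-similarity filtering disabled",
                   similarity_path))
  }

  if (!is.null(paralog_path) && file.exists(paralog_path)) {
    lines <- readr::read_lines(paralog_path)
    lines_keep <- which(!grepl("^#", lines) & nzchar(lines))
    paralogs <- purrr::map_dfr(lines_keep, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2) {
        abort(sprintf("paralog file %s line %d: expected 2 tab-separated fields",
                      paralog_path, i))
      }
      tibble(symbol1 = min(f[1], f[2]), symbol2 = max(f[1], f[2]))
    }) |> distinct()
  } else if (!is.null(paralog_path)) {
    inform(sprintf("paralog file '%s' not found: paralog filtering disabled",
                   paralog_path))
  }

  structure(list(regions = regions, paralogs = paralogs),
            class = "similarity_map")
}

#' An empty similarity map (all similarity/paralog filters disabled)
#' @rdname read_similarity_map
#' @export
empty_similarity_map <- function() read_similarity_map(NULL, NULL)

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %d similar region pair(s), %d paralog pair(s)\n",
              nrow(x$regions), nrow(x$paralogs)))
  invisible(x)
}

parse_region <- function(x, path, line) {
  m <- stringr::str_match(x, "^([^:]+):(\\d+)-(\\d+)$")
  if (is.na(m[1, 1])) {
    abort(sprintf("file %s line %d: malformed region '%s' (expected chrom:start-end)",
                  path, line, x))
  }
  list(chrom = m[1, 2], start = as.integer(m[1, 3]) - 1L, end = as.integer(m[1, 4]))
}

#' Similar exon regions for an unordered gene pair
#'
#' Symmetric lookup: `similarity_regions(map, a, b)` and
#' `similarity_regions(map, b, a)` return the same regions, with the
#' `*_query`/`*_other` columns oriented to the order of the arguments.
#'
#' @param map A `similarity_map`.
#' @param gene_a,gene_b Gene identifiers.
#' @return Tibble of region pairs (0-based half-open), possibly empty.
#' @export
similarity_regions <- function(map, gene_a, gene_b) {
  stopifnot(inherits(map, "similarity_map"))
  g1 <- pmin(gene_a, gene_b); g2 <- pmax(gene_a, gene_b)
  hit <- map$regions |> filter(.data$gene1 == g1, .data$gene2 == g2)
  if (gene_a <= gene_b) {
    hit |> select(chrom_query = "chrom1", start_query = "start1", end_query = "end1",
                  chrom_other = "chrom2", start_other = "start2", end_other = "end2")
  } else {
    hit |> select(chrom_query = "chrom2", start_query = "start2", end_query = "end2",
                  chrom_other = "chrom1", start_other = "start1", end_other = "end1")
  }
}

#' Test whether two gene symbols are recorded as paralogs
#' @rdname similarity_regions
#' @export
is_paralog_pair <- function(map, gene_a, gene_b) {
  stopifnot(inherits(map, "similarity_map"))
  if (nrow(map$paralogs) == 0) return(rep(FALSE, max(length(gene_a), length(gene_b))))
  key <- pair_key(gene_a, gene_b)
  key %in% pair_key(map$paralogs$symbol1, map$paralogs$symbol2)
}
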