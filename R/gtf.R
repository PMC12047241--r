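#' Read gene models from a GTF file
#'
#' Parses a GENCODE-dialect GTF (tab-separated, 9 columns, attributes as
#' `key "value";` pairs) into a [gene_model_set()]. Only `gene`,
#' `transcript` and `exon` features are consulted; exon coordinates are
#' converted from 1-based closed to the package's internal 0-based
#' half-open convention. Malformed records raise an error naming the line
#' number; an exon lacking a `transcript_id` is an error.
#'
#' @param path Path to a GTF file.
#' @return A [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))

  recs <- purrr::map(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      abort(sprintf("GTF parse error at line %d of %s: expected 9 tab-separated fields, got %d",
                    i, path, length(f)))
    }
    feature <- f[3]
    if (!feature %in% c("gene", "transcript", "exon")) return(NULL)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      abort(sprintf("GTF parse error at line %d of %s: bad coordinates '%s'-'%s'",
                    i, path, f[4], f[5]))
    }
    if (!f[7] %in% c("+", "-")) {
      abort(sprintf("GTF parse error at line %d of %s: strand must be '+' or '-'",
                    i, path))
    }
    gene_id <- gtf_attr(f[9], "gene_id")
    if (is.na(gene_id)) {
      abort(sprintf("GTF parse error at line %d of %s: missing gene_id attribute",
                    i, path))
    }
    transcript_id <- gtf_attr(f[9], "transcript_id")
    if (feature == "exon" && is.na(transcript_id)) {
      abort(sprintf("GTF parse error at line %d of %s: exon without parent transcript_id",
                    i, path))
    }
    list(feature = feature, chrom = f[1], start = start - 1L, end = end,
         strand = f[7], gene_id = gene_id, transcript_id = transcript_id,
         symbol = gtf_attr(f[9], "gene_name"))
  })
  recs <- purrr::compact(recs)
  exon_recs <- purrr::keep(recs, ~ .x$feature == "exon")
  if (length(exon_recs) == 0) abort(sprintf("no exon features found in %s", path))

  symbols <- purrr::map_dfr(recs, function(r) {
    tibble(gene_id = r$gene_id, symbol = r$symbol %||% NA_character_)
  }) |>
    filter(!is.na(.data$symbol)) |>
    distinct(.data$gene_id, .keep_all = TRUE)

  exons <- purrr::map_dfr(exon_recs, function(r) {
    tibble(gene_id = r$gene_id, transcript_id = r$transcript_id,
           chrom = r$chrom, strand = r$strand, start = r$start, end = r$end)
  }) |>
    left_join(symbols, by = "gene_id") |>
    mutate(symbol = dplyr::coalesce(.data$symbol, .data$gene_id))

  gene_model_set(exons)
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))
  m[1, 2]
}

#' Write a gene model set as GTF
#'
#' Emits `gene`, `transcript` and `exon` features with 1-based closed
#' coordinates, so that [read_gene_models()] on the output reproduces the
#' input models exactly (coordinate round trip).
#'
#' @param gms A [gene_model_set()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gms, path, source = "lrfuse") {
  stopifnot(inherits(gms, "gene_model_set"))
  fmt <- function(chrom, feature, start0, end0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, source, feature, start0 + 1L, end0, strand, attrs)
  }
  out <- character(0)
  for (gi in seq_len(nrow(gms$genes))) {
    g <- gms$genes[gi, ]
    gattr <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)
    out <- c(out, fmt(g$chrom, "gene", g$span_start, g$span_end, g$strand, gattr))
    tx <- gms$exons |> filter(.data$gene_id == g$gene_id)
    for (tid in unique(tx$transcript_id)) {
      te <- tx |> filter(.data$transcript_id == tid) |> arrange(.data$start)
      tattr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                       g$gene_id, tid, g$symbol)
      out <- c(out, fmt(g$chrom, "transcript", min(te$start), max(te$end),
                        g$strand, tattr))
      for (ei in seq_len(nrow(te))) {
        out <- c(out, fmt(g$chrom, "exon", te$start[ei], te$end[ei], g$strand, tattr))
      }
    }
  }
  readr::write_lines(out, path)
  invisible(path)
}
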