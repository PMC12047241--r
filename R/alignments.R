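#' Read splice-aware long-read alignments as alignment segments
#'
#' Parses PAF (12+ tab-separated columns) or SAM (text, with supplementary
#' alignments as extra segments) into the unified alignment-segment table
#' consumed by the phase-1 scan. All coordinates are 0-based half-open;
#' read coordinates are in the read's original orientation.
#'
#' Identity is `matches / block_len`: PAF columns 10/11 directly, or for
#' SAM `(aligned_len - NM) / aligned_len` with `aligned_len` the CIGAR
#' M/I/D span. A SAM record lacking an `NM` tag falls back to identity 1
#' with a warning.
#'
#' @param path Path to a `.paf` or `.sam` file; the format is detected
#'   from the content, and a file that is neither raises an error.
#' @return A tibble with columns `read_id`, `read_len`, `read_start`,
#'   `read_end`, `align_strand`, `chrom`, `genome_start`, `genome_end`,
#'   `matches`, `block_len`, `identity`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  lines <- readr::read_lines(path)
  body <- lines[nzchar(lines)]
  if (length(body) == 0) abort(sprintf("alignment file is empty: %s", path))
  if (any(grepl("^@(HD|SQ|RG|PG|CO)\t", body)) || is_sam_body(body)) {
    parse_sam_segments(body, path)
  } else if (is_paf_body(body)) {
    parse_paf_segments(body, path)
  } else {
    abort(sprintf("file %s matches neither PAF nor SAM format", path))
  }
}

is_paf_body <- function(body) {
  f <- strsplit(body[!grepl("^@", body)][1], "\t", fixed = TRUE)[[1]]
  length(f) >= 12 && f[5] %in% c("+", "-") &&
    !anyNA(suppressWarnings(as.integer(f[c(2:4, 7:9, 10:12)])))
}

is_sam_body <- function(body) {
  rec <- body[!grepl("^@", body)]
  if (length(rec) == 0) return(FALSE)
  f <- strsplit(rec[1], "\t", fixed = TRUE)[[1]]
  length(f) >= 11 && !is.na(suppressWarnings(as.integer(f[2]))) &&
    grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[6])
}

parse_paf_segments <- function(body, path) {
  purrr::map_dfr(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      abort(sprintf("PAF parse error at line %d of %s: fewer than 12 columns", i, path))
    }
    tibble(
      read_id = f[1], read_len = as.integer(f[2]),
      read_start = as.integer(f[3]), read_end = as.integer(f[4]),
      align_strand = f[5], chrom = f[6],
      genome_start = as.integer(f[8]), genome_end = as.integer(f[9]),
      matches = as.integer(f[10]), block_len = as.integer(f[11])
    )
  }) |>
    mutate(identity = ifelse(.data$block_len > 0,
                             .data$matches / .data$block_len, 0))
}

parse_sam_segments <- function(body, path) {
  rec <- body[!grepl("^@", body)]
  missing_nm <- FALSE
  out <- purrr::map_dfr(seq_along(rec), function(i) {
    f <- strsplit(rec[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(sprintf("SAM parse error at record %d of %s: fewer than 11 fields", i, path))
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0) return(NULL)  # unmapped/secondary
    cigar <- f[6]
    if (cigar == "*") return(NULL)
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
    ref_span <- sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    read_aln <- sum(lens[ops %in% c("M", "I", "=", "X")])
    clip5 <- if (ops[1] %in% c("S", "H")) lens[1] else 0L
    clip3 <- if (ops[length(ops)] %in% c("S", "H")) lens[length(lens)] else 0L
    read_len <- clip5 + clip3 + read_aln
    reverse <- bitwAnd(flag, 16L) > 0
    rs <- if (reverse) clip3 else clip5
    aligned_len <- sum(lens[ops %in% c("M", "I", "D", "=", "X")])
    nm_tag <- stringr::str_match(paste(f[-(1:11)], collapse = "\t"),
                                 "NM:i:(\\d+)")[1, 2]
    if (is.na(nm_tag)) {
      missing_nm <<- TRUE
      matches <- aligned_len
    } else {
      matches <- aligned_len - as.integer(nm_tag)
    }
    tibble(
      read_id = f[1], read_len = read_len,
      read_start = rs, read_end = rs + read_aln,
      align_strand = if (reverse) "-" else "+", chrom = f[3],
      genome_start = as.integer(f[4]) - 1L,
      genome_end = as.integer(f[4]) - 1L + ref_span,
      matches = matches, block_len = aligned_len
    )
  })
  if (missing_nm) {
    warn("SAM record(s) without NM tag: identity assumed 1.0 for those segments")
  }
  out |> mutate(identity = ifelse(.data$block_len > 0,
                                  .data$matches / .data$block_len, 0))
}

#' Write alignment segments as PAF
#'
#' @param segments Segment tibble (as from [read_alignments()] or a
#'   simulated dataset's `segments` element).
#' @param path Output path.
#' @param tlen Named integer vector of chromosome lengths (defaults to the
#'   maximum end seen per chromosome).
#' @return `path`, invisibly.
#' @export
write_paf <- function(segments, path, tlen = NULL) {
  if (is.null(tlen)) {
    tl <- segments |> group_by(.data$chrom) |>
      summarise(len = max(.data$genome_end), .groups = "drop")
    tlen <- setNames(tl$len, tl$chrom)
  }
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                   segments$read_id, segments$read_len, segments$read_start,
                   segments$read_end, segments$align_strand, segments$chrom,
                   as.integer(tlen[segments$chrom]), segments$genome_start,
                   segments$genome_end, segments$matches, segments$block_len)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Count reads in a FASTQ file
#'
#' Used to establish the FFPM denominator when only alignments are
#' supplied to the caller.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Integer read count.
#' @export
count_fastq_reads <- function(path) {
  length(Biostrings::readDNAStringSet(path, format = "fastq"))
}
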