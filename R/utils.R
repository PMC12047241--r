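#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join distinct n row_number desc across all_of first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Intervals are 0-based half-open throughout the package internals; all
# user-facing report coordinates are 1-based.

#' Length of the intersection of two half-open intervals
#' @noRd
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Reverse complement of a DNA string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Format a 0-based position as a 1-based "chrom:pos:strand" breakpoint string
#' @noRd
format_breakpoint <- function(chrom, pos0, strand) {
  sprintf("%s:%d:%s", chrom, as.integer(pos0) + 1L, strand)
}

#' Parse "chrom:pos[:strand]" (1-based) into components (0-based pos)
#' @noRd
parse_breakpoint <- function(x) {
  parts <- stringr::str_split(x, stringr::fixed(":"))
  tibble(
    chrom  = purrr::map_chr(parts, 1),
    pos    = as.integer(purrr::map_chr(parts, 2)) - 1L,
    strand = purrr::map_chr(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_)
  )
}

#' Canonical unordered gene-pair key
#' @noRd
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what))
  }
  invisible(x)
}
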