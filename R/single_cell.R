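#' Encode and decode cell barcode / UMI read-name tags
#'
#' Single-cell runs carry the cell barcode and molecule UMI through the
#' whole pipeline inside the read name as `<barcode>^<umi>^<core_id>`
#' (delimiter configurable). Encoding sanitises the delimiter out of the
#' barcode and UMI; decoding an encoded name returns the original triple.
#'
#' @param barcode,umi,core_id Character vectors (recycled).
#' @param read_name Encoded read name(s).
#' @param delim Single-character delimiter, default `"^"`.
#' @return `encode_tagged_read_name`: character vector of names;
#'   `parse_tagged_read_name`: a tibble `barcode`, `umi`, `core_id`.
#' @export
encode_tagged_read_name <- function(barcode, umi, core_id, delim = "^") {
  clean <- function(x) gsub(delim, "_", x, fixed = TRUE)
  paste(clean(barcode), clean(umi), core_id, sep = delim)
}

#' @rdname encode_tagged_read_name
#' @export
parse_tagged_read_name <- function(read_name, delim = "^") {
  parts <- stringr::str_split(read_name, stringr::fixed(delim))
  bad <- purrr::map_lgl(parts, ~ length(.x) < 3 || any(!nzchar(.x[1:2])) || !nzchar(paste(.x[-(1:2)], collapse = delim)))
  if (any(bad)) {
    abort(sprintf("read name(s) not in <barcode>%s<umi>%s<core_id> form: %s",
                  delim, delim,
                  paste(utils::head(read_name[bad], 3), collapse = ", ")))
  }
  tibble(
    barcode = purrr::map_chr(parts, 1),
    umi = purrr::map_chr(parts, 2),
    core_id = purrr::map_chr(parts, ~ paste(.x[-(1:2)], collapse = delim))
  )
}

#' Build the per-cell fusion evidence matrix
#'
#' Expands a fusion report's supporting read names, decodes their
#' barcode/UMI tags, and counts, per (cell, fusion), the number of
#' distinct UMIs (duplicate UMIs collapse to one molecule). Set
#' `count = "reads"` to count reads instead.
#'
#' @param report A `fusion_report` tibble (with `LongReadIds`).
#' @param delim Tag delimiter.
#' @param count `"umis"` (default) or `"reads"`.
#' @param allow_untagged If TRUE, reads without a parseable tag are
#'   skipped with a warning instead of raising an error.
#' @return A `cell_fusion_matrix`: a long tibble `barcode`,
#'   `fusion_name`, `count`, with per-cell totals in
#'   `attr(, "cell_totals")`.
#' @export
build_cell_fusion_matrix <- function(report, delim = "^",
                                     count = c("umis", "reads"),
                                     allow_untagged = FALSE) {
  count <- match.arg(count)
  long <- as_tibble(report) |>
    select(fusion_name = "FusionName", "LongReadIds") |>
    mutate(read_id = stringr::str_split(.data$LongReadIds, stringr::fixed(","))) |>
    tidyr::unnest("read_id") |>
    select(-"LongReadIds")
  tagged <- stringr::str_count(long$read_id, stringr::fixed(delim)) >= 2
  if (any(!tagged)) {
    if (!allow_untagged) {
      abort(sprintf("untagged read name(s) in report: %s",
                    paste(utils::head(long$read_id[!tagged], 3), collapse = ", ")))
    }
    warn(sprintf("%d untagged read(s) skipped", sum(!tagged)))
    long <- long[tagged, , drop = FALSE]
  }
  tags <- parse_tagged_read_name(long$read_id, delim)
  long <- dplyr::bind_cols(long, tags)
  mat <- if (count == "umis") {
    long |>
      distinct(.data$barcode, .data$fusion_name, .data$umi) |>
      dplyr::count(.data$barcode, .data$fusion_name, name = "count")
  } else {
    long |>
      distinct(.data$barcode, .data$fusion_name, .data$read_id) |>
      dplyr::count(.data$barcode, .data$fusion_name, name = "count")
  }
  totals <- mat |> group_by(.data$barcode) |>
    summarise(total = sum(.data$count), .groups = "drop")
  structure(mat, cell_totals = totals,
            class = c("cell_fusion_matrix", class(mat)))
}

#' Somatic cell-level fusion filters
#'
#' Retains fusions with single-cell evidence consistent with a somatic,
#' tumor-restricted event: observed in at least `min_cells` tumor cells,
#' with at least `min_tumor_fraction` of fusion-positive annotated cells
#' being tumor, and absent from a matched normal sample's matrix when one
#' is provided. Barcodes missing from the annotation are warned about and
#' excluded from the fraction.
#'
#' @param matrix A `cell_fusion_matrix` (long tibble `barcode`,
#'   `fusion_name`, `count`).
#' @param cell_annotations Tibble `barcode`, `cell_type` (`"tumor"`
#'   marks tumor cells; any other label counts as non-tumor).
#' @param matched_normal Optional `cell_fusion_matrix` from a matched
#'   normal sample.
#' @param min_cells Minimum tumor cells with evidence (default 5).
#' @param min_tumor_fraction Minimum tumor fraction among annotated
#'   fusion-positive cells (default 0.8).
#' @return Tibble of retained fusions: `fusion_name`, `n_tumor_cells`,
#'   `n_normal_cells`, `tumor_fraction`.
#' @export
filter_somatic_cell_fusions <- function(matrix, cell_annotations,
                                        matched_normal = NULL,
                                        min_cells = 5L,
                                        min_tumor_fraction = 0.8) {
  ann <- as_tibble(cell_annotations)
  m <- as_tibble(matrix) |> filter(.data$count > 0)
  unknown <- setdiff(unique(m$barcode), ann$barcode)
  if (length(unknown) > 0) {
    warn(sprintf("%d barcode(s) missing from cell annotations; excluded from tumor fractions",
                 length(unknown)))
  }
  scored <- m |>
    left_join(ann, by = "barcode") |>
    group_by(.data$fusion_name) |>
    summarise(
      n_tumor_cells = dplyr::n_distinct(.data$barcode[.data$cell_type %in% "tumor"]),
      n_normal_cells = dplyr::n_distinct(
        .data$barcode[!is.na(.data$cell_type) & .data$cell_type != "tumor"]),
      tumor_fraction = ifelse(.data$n_tumor_cells + .data$n_normal_cells > 0,
                              .data$n_tumor_cells /
                                (.data$n_tumor_cells + .data$n_normal_cells), 0),
      .groups = "drop")
  keep <- scored |>
    filter(.data$n_tumor_cells >= min_cells,
           .data$tumor_fraction >= min_tumor_fraction)
  if (!is.null(matched_normal)) {
    normal_fusions <- unique(as_tibble(matched_normal)$fusion_name)
    keep <- keep |> filter(!.data$fusion_name %in% normal_fusions)
  }
  keep
}

#' Attach a CellBarcodes column to a fusion report
#'
#' Derives the distinct cell barcodes supporting each report row from the
#' tagged read names in `LongReadIds`.
#'
#' @param report A `fusion_report`.
#' @param delim Tag delimiter.
#' @return The report with a `CellBarcodes` column (comma-joined).
#' @export
add_cell_barcodes <- function(report, delim = "^") {
  bc <- purrr::map_chr(strsplit(report$LongReadIds, ",", fixed = TRUE),
                       function(ids) {
    paste(sort(unique(parse_tagged_read_name(ids, delim)$barcode)), collapse = ",")
  })
  report$CellBarcodes <- bc
  report
}

#' Write a cell-fusion matrix
#'
#' Writes the long-form TSV (`barcode`, `fusion_name`, `count`) and,
#' optionally, a MatrixMarket sparse triplet with row (fusion) and column
#' (barcode) name files.
#'
#' @param matrix A `cell_fusion_matrix`.
#' @param tsv_path Long TSV path (NULL to skip).
#' @param mtx_prefix Prefix for `<prefix>.mtx`, `<prefix>.rows.txt`,
#'   `<prefix>.cols.txt` (NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_cell_fusion_matrix <- function(matrix, tsv_path = NULL, mtx_prefix = NULL) {
  written <- character(0)
  if (!is.null(tsv_path)) {
    readr::write_tsv(as_tibble(matrix), tsv_path)
    written <- c(written, tsv_path)
  }
  if (!is.null(mtx_prefix)) {
    fus <- sort(unique(matrix$fusion_name))
    cells <- sort(unique(matrix$barcode))
    sm <- Matrix::sparseMatrix(
      i = match(matrix$fusion_name, fus), j = match(matrix$barcode, cells),
      x = matrix$count, dims = c(length(fus), length(cells)))
    mtx <- paste0(mtx_prefix, ".mtx")
    Matrix::writeMM(sm, mtx)
    readr::write_lines(fus, paste0(mtx_prefix, ".rows.txt"))
    readr::write_lines(cells, paste0(mtx_prefix, ".cols.txt"))
    written <- c(written, mtx, paste0(mtx_prefix, ".rows.txt"),
                 paste0(mtx_prefix, ".cols.txt"))
  }
  invisible(written)
}
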