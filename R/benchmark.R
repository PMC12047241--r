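#' Match a predicted gene pair against a truth set
#'
#' A side matches via identity, recorded paralogy, or genomic overlap
#' (the proxy equivalences). In `strict` mode the predicted 5'/3' order
#' must match the truth order; `allow_reverse` additionally accepts the
#' swapped order.
#'
#' @param gene5,gene3 Predicted gene pair (single values).
#' @param truth Tibble with `gene5`, `gene3` columns.
#' @param mode `"strict"` or `"allow_reverse"`.
#' @param similarity A `similarity_map` (paralog relation).
#' @param overlap_pairs Tibble `gene1`,`gene2` of overlapping-coordinate
#'   gene pairs (or NULL).
#' @return The index of the first matching truth row, or `NA_integer_`.
#' @export
gene_pair_match <- function(gene5, gene3, truth,
                            mode = c("strict", "allow_reverse"),
                            similarity = empty_similarity_map(),
                            overlap_pairs = NULL) {
  mode <- match.arg(mode)
  if (nrow(truth) == 0) return(NA_integer_)
  side <- function(a, b) side_matches(a, b, similarity, overlap_pairs)
  fwd <- side(gene5, truth$gene5) & side(gene3, truth$gene3)
  hit <- fwd
  if (mode == "allow_reverse") {
    hit <- hit | (side(gene5, truth$gene3) & side(gene3, truth$gene5))
  }
  if (!any(hit)) NA_integer_ else which(hit)[1]
}

side_matches <- function(a, b, similarity, overlap_pairs) {
  out <- a == b
  if (nrow(similarity$paralogs) > 0) out <- out | is_paralog_pair(similarity, a, b)
  if (!is.null(overlap_pairs) && nrow(overlap_pairs) > 0) {
    out <- out | pair_key(a, b) %in% pair_key(overlap_pairs$gene1,
                                              overlap_pairs$gene2)
  }
  out
}

#' Compare two fusion breakpoint pairs
#'
#' Each pair is first sorted canonically by (chromosome, position) so
#' breakpoint order is ignored. `exact` requires both coordinates equal;
#' `fuzzy` allows each to lie within `window` bases (default 5) of its
#' counterpart. Strand fields in `chrom:pos:strand` strings are ignored.
#'
#' @param pred_bkpts,truth_bkpts Character vectors of two breakpoint
#'   strings each (`chrom:pos[:strand]`, 1-based).
#' @param mode `"exact"` or `"fuzzy"`.
#' @param window Fuzzy window in bases.
#' @return Logical scalar.
#' @export
breakpoint_match <- function(pred_bkpts, truth_bkpts,
                             mode = c("exact", "fuzzy"), window = 5L) {
  mode <- match.arg(mode)
  canon <- function(x) {
    b <- parse_breakpoint(x)
    b[order(b$chrom, b$pos), , drop = FALSE]
  }
  p <- canon(pred_bkpts); t <- canon(truth_bkpts)
  if (!all(p$chrom == t$chrom)) return(FALSE)
  if (mode == "exact") all(p$pos == t$pos)
  else all(abs(p$pos - t$pos) <= window)
}

#' Score one method's predictions against a truth set
#'
#' Predictions are first filtered to the minimum read support. Each truth
#' entry matched by at least one prediction is one TP (however many
#' predictions match it); unmatched truth entries are FNs; unmatched
#' predictions are FPs. When a cross-method prediction table is supplied,
#' only fusions uniquely predicted by this method are scored as FPs.
#'
#' @param preds Prediction tibble: `gene5`, `gene3`, `num_reads`, and
#'   optionally `breakpoint5`, `breakpoint3`.
#' @param truth Truth tibble: `gene5`, `gene3` (+ breakpoints when
#'   breakpoint scoring is on).
#' @param min_reads Minimum read support.
#' @param mode Gene-pair matching mode (see [gene_pair_match()]).
#' @param bkpt_mode `"ignore"` (default), `"exact"` or `"fuzzy"`.
#' @param similarity,overlap_pairs Proxy equivalences.
#' @param other_methods_preds Optional tibble of the other methods'
#'   predictions (`method`, `gene5`, `gene3`) enabling unique-FP scoring.
#' @return A list with `tp`, `fp`, `fn` tibbles and a `summary` row
#'   (`TP`, `FP`, `FN`, `precision`, `recall`, `f1`, `flagged`).
#' @export
score_predictions <- function(preds, truth, min_reads = 1L,
                              mode = c("strict", "allow_reverse"),
                              bkpt_mode = c("ignore", "exact", "fuzzy"),
                              similarity = empty_similarity_map(),
                              overlap_pairs = NULL,
                              other_methods_preds = NULL) {
  mode <- match.arg(mode); bkpt_mode <- match.arg(bkpt_mode)
  preds <- as_tibble(preds) |> filter(.data$num_reads >= min_reads)
  truth <- as_tibble(truth)
  matched_truth <- integer(0)
  fp_rows <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    j <- gene_pair_match(preds$gene5[i], preds$gene3[i], truth, mode,
                         similarity, overlap_pairs)
    ok <- !is.na(j)
    if (ok && bkpt_mode != "ignore") {
      ok <- breakpoint_match(c(preds$breakpoint5[i], preds$breakpoint3[i]),
                             c(truth$breakpoint5[j], truth$breakpoint3[j]),
                             mode = bkpt_mode)
    }
    if (ok) matched_truth <- c(matched_truth, j) else fp_rows[i] <- TRUE
  }
  fp <- preds[fp_rows, , drop = FALSE]
  if (!is.null(other_methods_preds) && nrow(fp) > 0) {
    other_keys <- pair_key(other_methods_preds$gene5, other_methods_preds$gene3)
    fp <- fp[!pair_key(fp$gene5, fp$gene3) %in% other_keys, , drop = FALSE]
  }
  tp_idx <- sort(unique(matched_truth))
  fn <- truth[setdiff(seq_len(nrow(truth)), tp_idx), , drop = FALSE]
  s <- pr_summary(length(tp_idx), nrow(fp), nrow(fn))
  list(tp = truth[tp_idx, , drop = FALSE], fp = fp, fn = fn, summary = s)
}

pr_summary <- function(TP, FP, FN) {
  flagged <- (TP + FP) == 0
  precision <- if (flagged) 1 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(TP = TP, FP = FP, FN = FN, precision = precision, recall = recall,
         f1 = f1, flagged = flagged)
}

#' Precision-recall curve and area under it
#'
#' Evaluates precision and recall at each minimum-read-support threshold
#' and integrates precision over recall by the trapezoid rule. Points
#' where no predictions survive the threshold carry precision 1 with a
#' flag and are excluded from the integration. The curve is extended
#' horizontally from the highest-precision point to recall 0; when
#' several thresholds give the same recall, the best precision at that
#' recall defines the curve.
#'
#' @inheritParams score_predictions
#' @param thresholds Integer vector of minimum read supports (default
#'   `1:max(preds$num_reads)`).
#' @return A `fusion_pr` object: `points` (one row per threshold) and
#'   `auc`.
#' @export
pr_curve_auc <- function(preds, truth, thresholds = NULL,
                         mode = c("strict", "allow_reverse"),
                         bkpt_mode = c("ignore", "exact", "fuzzy"),
                         similarity = empty_similarity_map(),
                         overlap_pairs = NULL,
                         other_methods_preds = NULL) {
  mode <- match.arg(mode); bkpt_mode <- match.arg(bkpt_mode)
  preds <- as_tibble(preds)
  if (is.null(thresholds)) {
    thresholds <- if (nrow(preds) == 0) 1L else seq_len(max(preds$num_reads))
  }
  points <- purrr::map_dfr(thresholds, function(th) {
    s <- score_predictions(preds, truth, min_reads = th, mode = mode,
                           bkpt_mode = bkpt_mode, similarity = similarity,
                           overlap_pairs = overlap_pairs,
                           other_methods_preds = other_methods_preds)$summary
    dplyr::bind_cols(tibble(threshold = th), s)
  })
  structure(list(points = points, auc = pr_auc_from_points(points)),
            class = "fusion_pr")
}

#' Trapezoidal PR-AUC from curve points
#'
#' @param points A tibble with `precision`, `recall` and (optionally)
#'   `flagged` columns.
#' @return The AUC in [0, 1]; 0 (with a message) when no usable points
#'   exist.
#' @export
pr_auc_from_points <- function(points) {
  pts <- points
  if ("flagged" %in% names(pts)) pts <- pts |> filter(!.data$flagged)
  if (nrow(pts) == 0) {
    inform("no unflagged precision-recall points: AUC = 0")
    return(0)
  }
  best <- pts |>
    group_by(.data$recall) |>
    summarise(precision = max(.data$precision), .groups = "drop") |>
    arrange(.data$recall)
  r <- c(0, best$recall)
  p <- c(max(best$precision), best$precision)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' @export
print.fusion_pr <- function(x, ...) {
  cat(sprintf("<fusion_pr> %d threshold point(s), AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Build a multi-method agreement ("wisdom of the crowds") proxy truth set
#'
#' Filters each method's calls to the minimum read support, groups
#' unordered gene pairs into proxy-equivalence classes (identity,
#' paralogy, genomic overlap on either side), and keeps classes called by
#' at least `min_methods` distinct methods.
#'
#' @param preds_all Tibble of all methods' predictions: `method`,
#'   `gene5`, `gene3`, `num_reads`.
#' @param min_reads Minimum per-method read support.
#' @param min_methods Minimum number of agreeing methods (2, 3 or 4 in
#'   the standard sweep).
#' @param similarity,overlap_pairs Proxy equivalences.
#' @return Tibble of truth pairs: `gene5`, `gene3` (canonical order),
#'   `n_methods`, `methods`.
#' @export
build_proxy_truth <- function(preds_all, min_reads = 1L, min_methods = 2L,
                              similarity = empty_similarity_map(),
                              overlap_pairs = NULL) {
  p <- as_tibble(preds_all) |>
    filter(.data$num_reads >= min_reads) |>
    mutate(g1 = pmin(.data$gene5, .data$gene3),
           g2 = pmax(.data$gene5, .data$gene3)) |>
    distinct(.data$method, .data$g1, .data$g2)
  if (nrow(p) == 0) {
    return(tibble(gene5 = character(), gene3 = character(),
                  n_methods = integer(), methods = character()))
  }
  pairs <- p |> distinct(.data$g1, .data$g2)
  n <- nrow(pairs)
  # union-find over proxy-equivalent unordered pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  side <- function(a, b) side_matches(a, b, similarity, overlap_pairs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      eq <- (side(pairs$g1[i], pairs$g1[j]) && side(pairs$g2[i], pairs$g2[j])) ||
        (side(pairs$g1[i], pairs$g2[j]) && side(pairs$g2[i], pairs$g1[j]))
      if (eq) parent[find(j)] <- find(i)
    }
  }
  pairs$class <- purrr::map_int(seq_len(n), find)
  p2 <- p |> left_join(pairs, by = c("g1", "g2"))
  p2 |>
    group_by(.data$class) |>
    summarise(gene5 = first(.data$g1), gene3 = first(.data$g2),
              n_methods = dplyr::n_distinct(.data$method),
              methods = paste(sort(unique(.data$method)), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_methods >= min_methods) |>
    select(-"class") |>
    arrange(.data$gene5, .data$gene3)
}

#' Sweep the proxy-truth grid
#'
#' Evaluates [build_proxy_truth()] over the standard grid of minimum
#' method counts and read-support thresholds, returning the truth-set
#' size for each cell (30 cells at the defaults).
#'
#' @inheritParams build_proxy_truth
#' @param min_reads_grid,min_methods_grid Grid axes.
#' @return Tibble `min_methods`, `min_reads`, `n_truth`.
#' @export
proxy_truth_grid <- function(preds_all, min_reads_grid = 1:10,
                             min_methods_grid = 2:4,
                             similarity = empty_similarity_map(),
                             overlap_pairs = NULL) {
  tidyr::expand_grid(min_methods = min_methods_grid,
                     min_reads = min_reads_grid) |>
    mutate(n_truth = purrr::map2_int(
      .data$min_methods, .data$min_reads,
      function(mm, mr) nrow(build_proxy_truth(preds_all, mr, mm,
                                              similarity, overlap_pairs))))
}

#' Remove nuisance fusions from a prediction table
#'
#' Drops fusions enriched for artifacts or irrelevant biology: partners
#' on the mitochondrial chromosome or in user-supplied mitochondrial /
#' HLA / immunoglobulin gene lists, pairs annotated as occurring in
#' normal samples, same-chromosome neighbors whose gene spans are within
#' `max_neighbor_gap` bases (cis-splicing territory; ties at the gap are
#' removed), and — when a cross-sample table is given — fusions
#' containing promiscuous genes, i.e. genes appearing in fusion calls of
#' at least `min_methods` methods across at least `min_samples` samples.
#'
#' @param preds Prediction tibble (`gene5`, `gene3`, ...).
#' @param gms A [gene_model_set()] for coordinates (genes absent from it
#'   skip the positional tests).
#' @param mito_genes,hla_genes,ig_genes Character vectors of gene ids.
#' @param normal_fusions Unordered pair list (`"A--B"` strings or
#'   two-column data frame) of fusions found in normals.
#' @param max_neighbor_gap Same-chromosome span gap threshold (bases).
#' @param cross_sample Optional tibble `method`, `sample`, `gene5`,
#'   `gene3` across the cohort, enabling the promiscuous-gene filter.
#' @param min_methods,min_samples Promiscuity thresholds.
#' @return The retained predictions.
#' @export
nuisance_filter <- function(preds, gms = NULL,
                            mito_genes = character(), hla_genes = character(),
                            ig_genes = character(), normal_fusions = NULL,
                            max_neighbor_gap = 100000L,
                            cross_sample = NULL, min_methods = 2L,
                            min_samples = 2L) {
  preds <- as_tibble(preds)
  if (nrow(preds) == 0) return(preds)
  bad_genes <- c(mito_genes, hla_genes, ig_genes)
  if (!is.null(gms)) {
    mito_chrom <- gms$genes |> filter(.data$chrom %in% c("chrM", "MT"))
    bad_genes <- c(bad_genes, mito_chrom$gene_id)
  }
  drop <- preds$gene5 %in% bad_genes | preds$gene3 %in% bad_genes
  if (!is.null(normal_fusions)) {
    drop <- drop | pair_key(preds$gene5, preds$gene3) %in%
      normalize_pair_list(normal_fusions)
  }
  if (!is.null(gms)) {
    g <- gms$genes
    i5 <- match(preds$gene5, g$gene_id); i3 <- match(preds$gene3, g$gene_id)
    known <- !is.na(i5) & !is.na(i3)
    same_chrom <- known & g$chrom[i5] == g$chrom[i3]
    gap <- pmax(g$span_start[i5], g$span_start[i3]) -
      pmin(g$span_end[i5], g$span_end[i3])
    drop <- drop | (same_chrom & !is.na(gap) & gap <= max_neighbor_gap)
  }
  if (!is.null(cross_sample)) {
    promiscuous <- as_tibble(cross_sample) |>
      tidyr::pivot_longer(c("gene5", "gene3"), values_to = "gene") |>
      group_by(.data$gene) |>
      summarise(n_methods = dplyr::n_distinct(.data$method),
                n_samples = dplyr::n_distinct(.data$sample), .groups = "drop") |>
      filter(.data$n_methods >= min_methods, .data$n_samples >= min_samples)
    drop <- drop | preds$gene5 %in% promiscuous$gene |
      preds$gene3 %in% promiscuous$gene
  }
  preds[!drop, , drop = FALSE]
}

#' Convert a fusion report to the benchmarking prediction dialect
#'
#' @param report A `fusion_report`.
#' @param method,sample Labels for the prediction table.
#' @param per_fusion Aggregate breakpoint rows to one row per fusion gene
#'   pair (summing reads, keeping the dominant breakpoint)? Default TRUE.
#' @return Prediction tibble: `method`, `sample`, `gene5`, `gene3`,
#'   `breakpoint5`, `breakpoint3`, `num_reads`.
#' @export
as_predictions <- function(report, method = "lrfuse", sample = "sample",
                           per_fusion = TRUE) {
  p <- as_tibble(report) |>
    mutate(method = method, sample = sample) |>
    select("method", "sample", gene5 = "LeftGene", gene3 = "RightGene",
           breakpoint5 = "LeftBreakpoint", breakpoint3 = "RightBreakpoint",
           num_reads = "NumLongReads")
  if (per_fusion) {
    p <- p |>
      group_by(.data$method, .data$sample, .data$gene5, .data$gene3) |>
      arrange(desc(.data$num_reads), .by_group = TRUE) |>
      summarise(breakpoint5 = first(.data$breakpoint5),
                breakpoint3 = first(.data$breakpoint3),
                num_reads = sum(.data$num_reads), .groups = "drop")
  }
  p
}
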