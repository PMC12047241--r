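#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a precision-recall result
#'
#' @param x A `fusion_pr` from [pr_curve_auc()].
#' @param ... Unused.
#' @return One row per read-support threshold with TP/FP/FN counts and
#'   precision, recall, F1.
#' @method tidy fusion_pr
#' @export
tidy.fusion_pr <- function(x, ...) x$points

#' @rdname tidy.fusion_pr
#' @return `glance`: a one-row tibble with `auc`, `best_f1`,
#'   `n_thresholds`.
#' @method glance fusion_pr
#' @export
glance.fusion_pr <- function(x, ...) {
  usable <- x$points |> filter(!.data$flagged)
  tibble(auc = x$auc,
         best_f1 = if (nrow(usable)) max(usable$f1) else 0,
         n_thresholds = nrow(x$points))
}

#' Summarise a fusion report
#'
#' @param x A `fusion_report`.
#' @param ... Unused.
#' @return A one-row tibble: fusion pair count, breakpoint (isoform)
#'   count, total supporting reads, consensus-splice fraction.
#' @method glance fusion_report
#' @export
glance.fusion_report <- function(x, ...) {
  tibble(
    n_fusions = dplyr::n_distinct(x$FusionName),
    n_breakpoints = nrow(x),
    n_supporting_reads = sum(x$NumLongReads),
    frac_consensus_splice = if (nrow(x)) mean(x$SpliceType == "ONLY_REF_SPLICE") else NA_real_
  )
}

#' Plot a precision-recall curve
#'
#' @param object A `fusion_pr`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fusion_pr
#' @export
autoplot.fusion_pr <- function(object, ...) {
  pts <- object$points |> filter(!.data$flagged) |> arrange(.data$recall)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(size = .data$threshold), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "min reads") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("Precision-recall (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot fusion read support
#'
#' One bar per reported breakpoint, grouped by fusion and coloured by
#' splice class.
#'
#' @param object A `fusion_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fusion_report
#' @export
autoplot.fusion_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(isoform = paste(.data$LeftBreakpoint, .data$RightBreakpoint,
                           sep = " | "))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$isoform, .data$NumLongReads),
    y = .data$NumLongReads, fill = .data$SpliceType)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$FusionName),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = "Supporting long reads", fill = "Splice") +
    ggplot2::theme_minimal()
}
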