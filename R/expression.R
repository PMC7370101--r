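#' Call expression from an FPKM matrix
#'
#' Implements the threshold rule used for the published organ heatmaps:
#' replicate FPKM values are aggregated per (gene, condition), log10
#' transformed, and a gene is called expressed in a condition iff its
#' logarithmic FPKM exceeds `threshold_log10` (strictly; mean FPKM exactly 1
#' is not expressed). A zero aggregate has no logarithm and is reported as
#' `NA` (display sentinel) and not expressed.
#'
#' @param x An `aqp_expression` object ([read_fpkm_matrix()],
#'   [new_aqp_expression()], [simulate_fpkm()]).
#' @param threshold_log10 Expression threshold on the log10 scale.
#' @param aggregate Replicate aggregation: arithmetic mean (default) or
#'   median of FPKM before the log transform.
#' @return A tibble of class `aqp_calls`: `gene_id`, `condition`,
#'   `mean_fpkm`, `log10_fpkm`, `expressed`.
#' @export
call_expression <- function(x, threshold_log10 = 0,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  stopifnot(inherits(x, "aqp_expression"))
  empty <- setdiff(unique(x$design$condition), x$design$condition)
  if (length(empty) > 0) {
    abort(sprintf("Condition(s) without samples: %s.",
                  paste(empty, collapse = ", ")),
          class = "aqpkit_design_error")
  }
  long <- x$fpkm %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample", values_to = "fpkm") %>%
    dplyr::inner_join(x$design, by = "sample")
  calls <- long %>%
    dplyr::group_by(.data$gene_id, .data$condition) %>%
    dplyr::summarise(mean_fpkm = agg_fun(.data$fpkm), .groups = "drop") %>%
    dplyr::mutate(
      log10_fpkm = ifelse(.data$mean_fpkm > 0, log10(.data$mean_fpkm), NA_real_),
      expressed = !is.na(.data$log10_fpkm) & .data$log10_fpkm > threshold_log10
    ) %>%
    dplyr::arrange(match(.data$gene_id, x$fpkm$gene_id),
                   match(.data$condition, unique(x$design$condition)))
  structure(calls, class = c("aqp_calls", class(calls)),
            conditions = unique(x$design$condition))
}

#' Per-condition expressed-gene counts
#'
#' @param calls An `aqp_calls` tibble from [call_expression()].
#' @return A tibble `condition`, `n_expressed`.
#' @export
expressed_counts <- function(calls) {
  calls %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(n_expressed = sum(.data$expressed), .groups = "drop")
}

#' Genes expressed in every named condition
#'
#' @param calls An `aqp_calls` tibble from [call_expression()].
#' @param conditions Conditions to intersect over (default: all present;
#'   at least two required).
#' @return Character vector of gene ids expressed in all the conditions.
#' @export
ubiquitous_genes <- function(calls, conditions = NULL) {
  present <- unique(calls$condition)
  if (is.null(conditions)) conditions <- present
  unknown <- setdiff(conditions, present)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(unknown, collapse = ", ")),
          class = "aqpkit_input_error")
  }
  if (length(conditions) < 2) {
    abort("At least two conditions are required.", class = "aqpkit_input_error")
  }
  calls %>%
    dplyr::filter(.data$condition %in% conditions) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(ubiq = all(.data$expressed), .groups = "drop") %>%
    dplyr::filter(.data$ubiq) %>%
    dplyr::pull("gene_id")
}

#' Genes expressed in no condition
#'
#' @inheritParams ubiquitous_genes
#' @return Character vector of gene ids not expressed anywhere.
#' @export
silent_genes <- function(calls) {
  calls %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(none = !any(.data$expressed), .groups = "drop") %>%
    dplyr::filter(.data$none) %>%
    dplyr::pull("gene_id")
}

#' Export a genes-by-conditions log10 FPKM matrix
#'
#' Wide matrix of log10 aggregated FPKM values with `NA` as the sentinel for
#' zero aggregates, suitable for heatmap rendering or TSV export (where the
#' sentinel serializes as "NA").
#'
#' @param calls An `aqp_calls` tibble from [call_expression()].
#' @param order `"input"` keeps the input gene order; `"subfamily"` orders
#'   genes by the bundled inventory's subfamily/group/isoform order (genes
#'   absent from the inventory keep input order at the end).
#' @param inventory Inventory used for `"subfamily"` ordering.
#' @param path Optional TSV output path.
#' @return The wide tibble (first column `gene_id`), invisibly when `path`
#'   is given.
#' @export
heatmap_matrix <- function(calls, order = c("input", "subfamily"),
                           inventory = NULL, path = NULL) {
  order <- match.arg(order)
  wide <- calls %>%
    dplyr::select("gene_id", "condition", "log10_fpkm") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "log10_fpkm")
  if (order == "subfamily") {
    if (is.null(inventory)) inventory <- load_gene_inventory()
    ord <- inventory %>%
      dplyr::arrange(match(.data$subfamily, AQP_SUBFAMILIES), .data$group,
                     .data$isoform) %>%
      dplyr::pull("locus") %>% unique()
    wide <- wide[order(match(wide$gene_id, ord), seq_len(nrow(wide))), ]
  }
  if (!is.null(path)) {
    readr::write_tsv(wide, path, progress = FALSE)
    return(invisible(wide))
  }
  wide
}

#' Heatmap of expression calls
#'
#' @param object An `aqp_calls` tibble from [call_expression()].
#' @param ... Unused.
#' @return A ggplot object: genes by conditions, filled by log10 FPKM (grey
#'   tiles mark the zero-FPKM sentinel).
#' @export
autoplot.aqp_calls <- function(object, ...) {
  df <- as_tibble(object)
  df$gene_id <- factor(df$gene_id, levels = rev(unique(df$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                   fill = .data$log10_fpkm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "khaki",
                                  high = "darkgreen", midpoint = 0.5,
                                  na.value = "grey85",
                                  name = "log10 FPKM") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname autoplot.aqp_calls
#' @param calls An `aqp_calls` tibble.
#' @export
plot_expression_heatmap <- function(calls, ...) autoplot.aqp_calls(calls, ...)
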