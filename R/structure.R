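#' Summarize intron/exon structure per transcript
#'
#' Introns are the gaps between consecutive exons; lengths come from the
#' 0-based half-open interval arithmetic, so `sum(exons) + sum(introns)`
#' equals the transcript span exactly.
#'
#' @param models Exon tibble (as from [read_gene_models()] or
#'   [simulate_gene_models()]).
#' @param long_threshold Intron length (bp) at or above which an intron is
#'   flagged long (default 10 kb).
#' @return A tibble per transcript: `transcript_id`, `gene_id`,
#'   `exon_count`, `intron_count`, `intron_lengths` (list column),
#'   `max_intron`, `n_long_introns`, `span`.
#' @export
summarize_structure <- function(models, long_threshold = 10000L) {
  validate_gene_models(models)
  models %>%
    dplyr::group_by(.data$transcript_id, .data$gene_id) %>%
    dplyr::arrange(.data$exon_start, .by_group = TRUE) %>%
    dplyr::summarise(
      exon_count = dplyr::n(),
      intron_lengths = list({
        s <- .data$exon_start; e <- .data$exon_end
        if (dplyr::n() > 1) as.integer(s[-1] - e[-dplyr::n()]) else integer(0)
      }),
      span = max(.data$exon_end) - min(.data$exon_start),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      intron_count = .data$exon_count - 1L,
      max_intron = purrr::map_int(.data$intron_lengths,
                                  ~ if (length(.x) == 0) 0L else max(.x)),
      n_long_introns = purrr::map_int(.data$intron_lengths,
                                      ~ sum(.x >= long_threshold))
    ) %>%
    dplyr::select("transcript_id", "gene_id", "exon_count", "intron_count",
                  "intron_lengths", "max_intron", "n_long_introns", "span")
}

#' Per-gene structure table and intron-count distribution
#'
#' Where a gene has several mRNAs, the transcript with the most exons
#' represents the gene (published structures report one per gene). The
#' intron-count histogram is attached as attribute `intron_histogram` and
#' also available via [intron_count_distribution()].
#'
#' @inheritParams summarize_structure
#' @return Per-gene tibble sorted by `gene_id` (columns as in
#'   [summarize_structure()]).
#' @export
structure_table <- function(models, long_threshold = 10000L) {
  per_tx <- summarize_structure(models, long_threshold = long_threshold)
  per_gene <- per_tx %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_max(.data$exon_count, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$gene_id)
  hist <- per_gene %>% dplyr::count(.data$intron_count, name = "n_genes")
  attr(per_gene, "intron_histogram") <- hist
  per_gene
}

#' @rdname structure_table
#' @param structures Output of [structure_table()] (or any structure summary
#'   tibble with an `intron_count` column).
#' @export
intron_count_distribution <- function(structures) {
  h <- attr(structures, "intron_histogram")
  if (!is.null(h)) return(h)
  structures %>% dplyr::count(.data$intron_count, name = "n_genes")
}

#' Exon-diagram plot of gene structures
#'
#' @param models Exon tibble.
#' @return A ggplot object: one horizontal track per transcript, exon
#'   rectangles joined by intron lines.
#' @export
plot_gene_structures <- function(models) {
  df <- models %>% dplyr::mutate(
    transcript_id = factor(.data$transcript_id,
                           levels = rev(unique(.data$transcript_id))))
  spans <- df %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(start = min(.data$exon_start), end = max(.data$exon_end),
                     .groups = "drop")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$transcript_id,
                                       yend = .data$transcript_id),
                          linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$exon_start,
                                    xmax = .data$exon_end,
                                    ymin = as.integer(.data$transcript_id) - 0.35,
                                    ymax = as.integer(.data$transcript_id) + 0.35),
                       fill = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
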