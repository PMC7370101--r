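#' Run the full aquaporin characterization pipeline
#'
#' Wires the stages in dependency order: completeness screen, subfamily
#' classification of the complete records, signature extraction, substrate
#' prediction, and — when the corresponding inputs are supplied — gene
#' structure summaries and expression calling. Deterministic given identical
#' inputs and configuration.
#'
#' @param proteins Tibble with columns `id`, `sequence` (e.g. from
#'   [read_aqp_fasta()]).
#' @param references Annotated reference set (default
#'   [aqp_reference_set()]).
#' @param gene_models Optional exon tibble (from [read_gene_models()] or
#'   [simulate_gene_models()]).
#' @param expression Optional `aqp_expression` object.
#' @param substrate_mode `"restricted"` or `"raw"` substrate calls.
#' @param screen_args,classify_args,expression_args Named lists of extra
#'   arguments forwarded to [screen_proteins()], [classify_proteins()] and
#'   [call_expression()].
#' @param out_dir Optional directory; when given, every stage table is also
#'   written as TSV.
#' @return An object of class `aqp_pipeline`: a list with elements `screen`,
#'   `classification`, `signatures`, `substrates`, `substrate_calls`,
#'   `structures` (or NULL), `expression_calls` (or NULL) and `summary`.
#' @export
run_aqp_pipeline <- function(proteins, references = aqp_reference_set(),
                             gene_models = NULL, expression = NULL,
                             substrate_mode = c("restricted", "raw"),
                             screen_args = list(), classify_args = list(),
                             expression_args = list(), out_dir = NULL) {
  substrate_mode <- match.arg(substrate_mode)
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) {
    abort("Duplicate protein ids.", class = "aqpkit_input_error")
  }

  screen <- do.call(screen_proteins, c(list(proteins), screen_args))
  complete <- proteins[proteins$id %in%
                         screen$id[screen$status == "complete"], ,
                       drop = FALSE]
  classification <- if (nrow(complete) > 0) {
    do.call(classify_proteins,
            c(list(complete, references = references), classify_args))
  } else NULL
  signatures <- if (nrow(complete) > 0) {
    extract_signatures(complete, references = references,
                       classification = classification)
  } else NULL
  substrates <- if (!is.null(signatures)) {
    predict_substrates(signatures, mode = substrate_mode)
  } else NULL
  substrate_calls <- if (!is.null(substrates)) {
    summarize_substrate_calls(substrates)
  } else NULL
  structures <- if (!is.null(gene_models)) structure_table(gene_models)
                else NULL
  expression_calls <- if (!is.null(expression)) {
    do.call(call_expression, c(list(expression), expression_args))
  } else NULL

  summary <- tibble(
    n_input = nrow(proteins),
    n_complete = sum(screen$status == "complete"),
    n_pseudogene_like = sum(screen$status == "pseudogene_like"),
    n_classified = if (is.null(classification)) 0L
                   else sum(classification$status == "classified"),
    n_genes_with_structure = if (is.null(structures)) NA_integer_
                             else nrow(structures),
    n_expression_conditions = if (is.null(expression_calls)) NA_integer_
                              else length(unique(expression_calls$condition))
  )

  result <- structure(
    list(screen = screen, classification = classification,
         signatures = signatures, substrates = substrates,
         substrate_calls = substrate_calls, structures = structures,
         expression_calls = expression_calls, summary = summary,
         substrate_mode = substrate_mode),
    class = "aqp_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

flatten_list_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(format(v), collapse = ";"), character(1))
  ))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(screen = result$screen, classification = result$classification,
               signatures = result$signatures,
               substrates = result$substrates,
               substrate_calls = result$substrate_calls,
               structures = result$structures,
               expression_calls = result$expression_calls,
               summary = result$summary)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      readr::write_tsv(flatten_list_cols(as_tibble(tabs[[nm]])),
                       file.path(out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.aqp_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<aqp_pipeline>\n")
  cat(sprintf("  proteins: %d input, %d complete, %d pseudogene-like\n",
              s$n_input, s$n_complete, s$n_pseudogene_like))
  cat(sprintf("  classified: %d (mode: %s substrate calls)\n",
              s$n_classified, x$substrate_mode))
  if (!is.na(s$n_genes_with_structure)) {
    cat(sprintf("  gene structures: %d genes\n", s$n_genes_with_structure))
  }
  if (!is.na(s$n_expression_conditions)) {
    cat(sprintf("  expression: %d conditions\n", s$n_expression_conditions))
  }
  invisible(x)
}

#' Tidy a pipeline result into one row per protein
#'
#' @param x An `aqp_pipeline` object.
#' @param ... Unused.
#' @return A tibble joining screen verdicts, classification, signature
#'   strings and the called substrates per protein.
#' @export
tidy.aqp_pipeline <- function(x, ...) {
  out <- x$screen %>%
    dplyr::mutate(reasons = vapply(.data$reasons, paste, character(1),
                                   collapse = ";"))
  if (!is.null(x$classification)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$classification, "id", "subfamily", "group",
                    "identity", class_status = "status"),
      by = "id")
  }
  if (!is.null(x$signatures)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$signatures, "id", "arR", "froger", "lb_region",
                    "le_region"),
      by = "id")
  }
  if (!is.null(x$substrate_calls)) {
    out <- dplyr::left_join(
      out,
      x$substrate_calls %>%
        dplyr::mutate(substrates = vapply(.data$calls, paste, character(1),
                                          collapse = ";")) %>%
        dplyr::select("id", "substrates"),
      by = "id")
  }
  out
}

#' One-row summary of a pipeline result
#'
#' @param x An `aqp_pipeline` object.
#' @param ... Unused.
#' @return The pipeline's one-row summary tibble.
#' @export
glance.aqp_pipeline <- function(x, ...) x$summary

#' Overview plot of a pipeline result
#'
#' @param object An `aqp_pipeline` object.
#' @param ... Unused.
#' @return A ggplot: expression heatmap when expression calls exist,
#'   otherwise subfamily counts of the classified proteins.
#' @export
autoplot.aqp_pipeline <- function(object, ...) {
  if (!is.null(object$expression_calls)) {
    return(autoplot.aqp_calls(object$expression_calls))
  }
  if (is.null(object$classification)) {
    abort("Nothing to plot: pipeline has no classification or expression.",
          class = "aqpkit_input_error")
  }
  df <- object$classification %>%
    dplyr::filter(.data$status == "classified") %>%
    dplyr::count(.data$subfamily)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subfamily, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "subfamily", y = "classified proteins") +
    ggplot2::theme_minimal(base_size = 10)
}
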