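#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features into a tidy exon table: one row per exon,
#' one gene model per mRNA. GFF3 coordinates (1-based, closed) are converted
#' at this boundary to the package-internal 0-based half-open convention, so
#' interval arithmetic downstream (intron lengths, spans) is subtraction-safe.
#'
#' @param path Path to a GFF3 file in which exon features carry `Parent`
#'   attributes pointing at mRNA features.
#' @return A tibble with columns `transcript_id`, `gene_id`, `strand`,
#'   `exon_start`, `exon_end` (0-based half-open), sorted by transcript and
#'   exon start.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GFF3 file '%s' does not exist.", path),
          class = "aqpkit_io_error")
  }
  gff <- as.data.frame(rtracklayer::readGFF(path))
  feat_type <- tolower(as.character(gff$type))
  mrna <- gff[feat_type %in% c("mrna", "transcript"), , drop = FALSE]
  exons <- gff[feat_type == "exon", , drop = FALSE]
  if (nrow(exons) == 0) {
    abort("GFF3 contains no exon features.", class = "aqpkit_parse_error")
  }
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x) == 0) NA_character_ else as.character(x[[1]]),
           character(1))
  }
  exon_parent <- first_parent(exons$Parent)
  mrna_id <- as.character(mrna$ID)
  mrna_gene <- first_parent(mrna$Parent)
  unresolved <- setdiff(unique(exon_parent), mrna_id)
  if (length(unresolved) > 0 || anyNA(exon_parent)) {
    abort(sprintf(
      "Exon(s) with unresolvable mRNA parent: %s.",
      paste(stats::na.omit(c(unresolved, if (anyNA(exon_parent)) "<missing Parent>")),
            collapse = ", ")
    ), class = "aqpkit_structure_error")
  }
  out <- tibble(
    transcript_id = unname(exon_parent),
    gene_id = unname(mrna_gene[match(exon_parent, mrna_id)]),
    strand = as.character(exons$strand),
    exon_start = as.integer(exons$start) - 1L,   # to 0-based half-open
    exon_end = as.integer(exons$end)
  )
  out$gene_id[is.na(out$gene_id)] <- out$transcript_id[is.na(out$gene_id)]
  out <- dplyr::arrange(out, .data$transcript_id, .data$exon_start)
  validate_gene_models(out)
  out
}

validate_gene_models <- function(models) {
  if (any(models$exon_end <= models$exon_start)) {
    abort("Exon with non-positive length.", class = "aqpkit_invariant_error")
  }
  bad <- models %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(
      overlap = any(.data$exon_start[-1] < .data$exon_end[-dplyr::n()]) &&
        dplyr::n() > 1,
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf("Overlapping exons within mRNA(s): %s.",
                  paste(bad$transcript_id, collapse = ", ")),
          class = "aqpkit_invariant_error")
  }
  invisible(models)
}

#' Convert internal exon coordinates back to GFF3 convention
#'
#' Inverse of the coordinate conversion done by [read_gene_models()]; used by
#' the writers and in round-trip checks.
#'
#' @param models Exon table as returned by [read_gene_models()].
#' @return The same tibble with `exon_start`/`exon_end` replaced by 1-based
#'   closed `start`/`end` columns.
#' @export
gene_models_to_gff_coords <- function(models) {
  models %>%
    dplyr::mutate(start = .data$exon_start + 1L, end = .data$exon_end) %>%
    dplyr::select(-"exon_start", -"exon_end")
}

#' Write gene models to a GFF3 file
#'
#' @param models Exon table (0-based half-open), as from [read_gene_models()]
#'   or [simulate_gene_models()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, source = "aqpkit") {
  lines <- c("##gff-version 3")
  for (tx in unique(models$transcript_id)) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    gene <- ex$gene_id[1]
    strand <- ex$strand[1]
    g_start <- min(ex$exon_start) + 1L
    g_end <- max(ex$exon_end)
    lines <- c(
      lines,
      paste(gene, source, "gene", g_start, g_end, ".", strand, ".",
            sprintf("ID=%s", gene), sep = "\t"),
      paste(gene, source, "mRNA", g_start, g_end, ".", strand, ".",
            sprintf("ID=%s;Parent=%s", tx, gene), sep = "\t"),
      paste(gene, source, "exon", ex$exon_start + 1L, ex$exon_end, ".",
            strand, ".", sprintf("ID=%s.exon%d;Parent=%s", tx,
                                 seq_len(nrow(ex)), tx), sep = "\t")
    )
  }
  writeLines(lines, path)
  invisible(path)
}
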