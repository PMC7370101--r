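#' Read an FPKM expression matrix with its replicate design
#'
#' Reads a genes-by-samples TSV of FPKM values plus a design table mapping
#' each sample to a condition label and replicate index, and enforces the
#' expression-matrix invariants: all values present and non-negative, every
#' sample column described exactly once in the design, every condition with
#' at least one replicate.
#'
#' @param path TSV whose first column holds gene ids and remaining numeric
#'   columns one sample each.
#' @param design_path TSV with columns `sample`, `condition`, `replicate`.
#' @return A list of class `aqp_expression` with elements `fpkm` (wide
#'   tibble, first column `gene_id`) and `design` (tibble).
#' @export
read_fpkm_matrix <- function(path, design_path) {
  fpkm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(fpkm)[1] <- "gene_id"
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "condition", "replicate") %in% names(design))) {
    abort("Design file must have columns sample, condition, replicate.",
          class = "aqpkit_design_error")
  }
  new_aqp_expression(fpkm, design)
}

#' Assemble an expression object from in-memory tables
#'
#' @param fpkm Wide tibble: first column `gene_id`, one numeric column per
#'   sample.
#' @param design Tibble with columns `sample`, `condition`, `replicate`.
#' @return A list of class `aqp_expression`.
#' @export
new_aqp_expression <- function(fpkm, design) {
  sample_ids <- setdiff(names(fpkm), "gene_id")
  vals <- as.matrix(fpkm[sample_ids])
  if (!is.numeric(vals)) {
    abort("All sample columns must be numeric FPKM values.",
          class = "aqpkit_domain_error")
  }
  if (anyNA(vals)) {
    abort("Missing FPKM values are not allowed.", class = "aqpkit_domain_error")
  }
  if (any(vals < 0)) {
    abort("Negative FPKM values are not allowed.", class = "aqpkit_domain_error")
  }
  if (anyDuplicated(design$sample)) {
    abort("Each sample may appear only once in the design.",
          class = "aqpkit_design_error")
  }
  missing <- setdiff(sample_ids, design$sample)
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) absent from design: %s.",
                  paste(missing, collapse = ", ")),
          class = "aqpkit_design_error")
  }
  if (anyDuplicated(fpkm$gene_id)) {
    abort("Duplicate gene ids in FPKM matrix.", class = "aqpkit_domain_error")
  }
  design <- dplyr::filter(design, .data$sample %in% sample_ids)
  structure(list(fpkm = as_tibble(fpkm), design = as_tibble(design)),
            class = "aqp_expression")
}

#' @export
print.aqp_expression <- function(x, ...) {
  cat(sprintf(
    "<aqp_expression> %d genes x %d samples (%d conditions)\n",
    nrow(x$fpkm), nrow(x$design), dplyr::n_distinct(x$design$condition)
  ))
  invisible(x)
}

#' Write an expression object to TSV files
#'
#' @param x An `aqp_expression` object.
#' @param path Output path for the FPKM matrix TSV.
#' @param design_path Output path for the design TSV.
#' @return `path`, invisibly.
#' @export
write_fpkm_matrix <- function(x, path, design_path) {
  readr::write_tsv(x$fpkm, path, progress = FALSE)
  readr::write_tsv(x$design, design_path, progress = FALSE)
  invisible(path)
}
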