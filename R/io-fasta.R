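#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid FASTA into the tabular protein-record representation used
#' throughout aqpkit: one row per entry with a unique `id` (first whitespace
#' token of the header) and an uppercase `sequence`. Trailing stop characters
#' (`*`) are stripped; duplicate ids and empty sequences are rejected.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `id`, `sequence` and `description` (the full
#'   FASTA header).
#' @seealso [write_aqp_fasta()]
#' @export
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">a demo", "MNPA"), faa)
#' read_aqp_fasta(faa)
read_aqp_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file '%s' does not exist.", path),
          class = "aqpkit_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("Failed to parse FASTA '%s': %s", path, conditionMessage(e)),
            class = "aqpkit_parse_error")
    }
  )
  if (length(set) == 0) {
    abort(sprintf("FASTA '%s' contains no records.", path),
          class = "aqpkit_parse_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(duplicated(ids))) {
    dups <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate record id(s): %s.", paste(dups, collapse = ", ")),
          class = "aqpkit_parse_error")
  }
  empty <- which(!nzchar(seqs) | !nzchar(ids))
  if (length(empty) > 0) {
    abort(sprintf("Empty id or sequence at FASTA entry %d.", empty[1]),
          class = "aqpkit_parse_error")
  }
  purrr::walk2(seqs, ids, assert_aa_sequence)
  tibble(id = unname(ids), sequence = unname(seqs), description = unname(headers))
}

#' Write protein records to a FASTA file
#'
#' @param proteins A tibble with columns `id` and `sequence` (as returned by
#'   [read_aqp_fasta()] or [simulate_family()]).
#' @param path Output file path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_aqp_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
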