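.aqpkit_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.aqpkit_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aqpkit_env$BLOSUM62 <- e$BLOSUM62
  }
  .aqpkit_env$BLOSUM62
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gaps
#' (opening 10, extension 1), via `Biostrings::pairwiseAlignment()`.
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_ext Affine gap penalties (positive costs).
#' @return A list with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `score`, and summary counts `matches`, `aligned_columns`
#'   (columns where both sequences have a residue) and `identity`
#'   (matches / aligned_columns).
#' @export
align_global <- function(a, b, gap_open = 10, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("Sequences must be non-empty.", class = "aqpkit_input_error")
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_stats(aligned_a, aligned_b)
  c(list(aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
         score = Biostrings::score(aln)), stats)
}

alignment_stats <- function(aligned_a, aligned_b) {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb)
  list(matches = matches, aligned_columns = sum(both),
       identity = if (sum(both) == 0) 0 else matches / sum(both))
}

# Identity of each query against one reference, vectorized over queries.
identities_to_reference <- function(sequences, reference,
                                    gap_open = 10, gap_ext = 1) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(sequences),
    subject = Biostrings::AAString(reference),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  purrr::map2(pa, sa, alignment_stats)
}

# Map 0-based indices in `b` (the template) to 0-based indices in `a` (the
# query) through a global alignment; positions aligned to a gap map to NA.
map_positions_through_alignment <- function(aligned_a, aligned_b, b_indices) {
  ca <- seq_chars(aligned_a)
  cb <- seq_chars(aligned_b)
  a_pos <- cumsum(ca != "-") - 1L   # 0-based index in a at each column
  b_pos <- cumsum(cb != "-") - 1L
  vapply(b_indices, function(bi) {
    col <- match(bi, b_pos)
    if (is.na(col) || cb[col] == "-" || ca[col] == "-") NA_integer_
    else a_pos[col]
  }, integer(1))
}
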