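# Selectivity-signature extraction: the ar/R filter (H2, H5, LE1, LE2),
# Froger's positions P1-P5, and the loop-B/loop-E NPA-region strings.
#
# Offsets are anchored on the N of each NPA motif. In the canonical PIP
# exemplar strings the N sits at offset 5 of the 10-mer loop-B region
# ("SGGHINPAVT") and at offset 4 of the 11-mer loop-E region
# ("GTGINPARSLG"), which fixes the windows LB = [NPA1-5, NPA1+5) and
# LE = [NPA2-4, NPA2+7), and the filter positions LE1 = NPA2-3,
# LE2 = NPA2+3 (the T and R of the exemplar). H2, H5 and P1-P5 have no
# sequence-local rule and are transferred from an annotated template through
# a global alignment.

substr0 <- function(sequence, start0, len) {
  substr(sequence, start0 + 1L, start0 + len)
}

#' Extract the loop-B and loop-E NPA-region strings
#'
#' @param sequence Amino-acid string.
#' @param anchors Two-row anchor tibble from [find_npa_anchors()].
#' @return A list with `lb_region` (10-mer), `le_region` (11-mer) and
#'   `flags` (character vector naming unresolved regions when a window falls
#'   outside the sequence).
#' @export
extract_npa_regions <- function(sequence, anchors) {
  n <- nchar(sequence)
  npa1 <- anchors$n_index[anchors$loop == "B"]
  npa2 <- anchors$n_index[anchors$loop == "E"]
  flags <- character(0)
  lb <- NA_character_; le <- NA_character_
  if (npa1 - 5L >= 0 && npa1 + 5L <= n) {
    lb <- substr0(sequence, npa1 - 5L, 10L)
  } else {
    flags <- c(flags, "position_unresolved:lb_region")
  }
  if (npa2 - 4L >= 0 && npa2 + 7L <= n) {
    le <- substr0(sequence, npa2 - 4L, 11L)
  } else {
    flags <- c(flags, "position_unresolved:le_region")
  }
  list(lb_region = lb, le_region = le, flags = flags)
}

#' Transfer annotated template positions onto a record
#'
#' Globally aligns the record to an annotated reference template and maps
#' each annotated template index to the record residue aligned to that
#' column. Positions aligned to a gap come back `NA`.
#'
#' @param sequence Record amino-acid string.
#' @param template One-row template tibble (see [build_template()]).
#' @return Named integer vector of 0-based record indices (NA = unresolved).
#' @export
transfer_positions <- function(sequence, template) {
  aln <- align_global(sequence, template$sequence[[1]])
  pos <- template$positions[[1]]
  out <- map_positions_through_alignment(aln$aligned_a, aln$aligned_b,
                                         unname(pos))
  names(out) <- names(pos)
  out
}

#' Extract the full selectivity signature of one protein
#'
#' Assembles the ar/R filter, Froger positions and NPA-region strings.
#' LE1/LE2 come from the NPA-relative rule (authoritative, since the region
#' definitions are NPA-anchored); when the template transfer also resolves
#' them and disagrees, the conflict is reported as a warning and the
#' NPA-relative residues win. H2, H5 and P1-P5 come from template transfer
#' only.
#'
#' @param sequence Amino-acid string.
#' @param anchors Anchor tibble from [find_npa_anchors()].
#' @param template Annotated template of the record's subfamily/group.
#' @param id Record identifier carried into the output.
#' @return One-row tibble: `id`, `arR`, `froger`, `lb_region`, `le_region`,
#'   `coords` (named 0-based indices), `flags` (list of
#'   `position_unresolved:<name>` markers; empty for a clean signature).
#' @export
extract_signature <- function(sequence, anchors, template, id = "record") {
  n <- nchar(sequence)
  chars <- seq_chars(sequence)
  npa1 <- anchors$n_index[anchors$loop == "B"]
  npa2 <- anchors$n_index[anchors$loop == "E"]
  regions <- extract_npa_regions(sequence, anchors)
  flags <- regions$flags

  transferred <- transfer_positions(sequence, template)
  res_at <- function(i) if (!is.na(i) && i >= 0 && i < n) chars[i + 1L] else NA_character_

  coords <- c(NPA1_N = npa1, NPA2_N = npa2,
              LE1 = npa2 - 3L, LE2 = npa2 + 3L,
              transferred[c("H2", "H5", "P1", "P2", "P3", "P4", "P5")])

  # NPA-relative LE1/LE2 vs template transfer: NPA-relative is authoritative
  for (nm in c("LE1", "LE2")) {
    tr <- transferred[[nm]]
    if (!is.na(tr) && !is.na(coords[[nm]]) && tr != coords[[nm]]) {
      warn(sprintf(
        "%s: transferred %s (index %d) disagrees with NPA-relative rule (index %d); keeping NPA-relative.",
        id, nm, tr, coords[[nm]]))
    }
  }

  sig_res <- vapply(coords, res_at, character(1))
  for (nm in c("H2", "H5", "LE1", "LE2", "P1", "P2", "P3", "P4", "P5")) {
    if (is.na(sig_res[[nm]])) flags <- c(flags, paste0("position_unresolved:", nm))
  }
  arR <- if (any(is.na(sig_res[c("H2", "H5", "LE1", "LE2")]))) NA_character_
         else paste(sig_res[c("H2", "H5", "LE1", "LE2")], collapse = "")
  froger <- if (any(is.na(sig_res[paste0("P", 1:5)]))) NA_character_
            else paste(sig_res[paste0("P", 1:5)], collapse = "")
  tibble(
    id = id, arR = arR, froger = froger,
    lb_region = regions$lb_region, le_region = regions$le_region,
    coords = list(coords), flags = list(unique(flags))
  )
}

#' Extract signatures for a set of proteins
#'
#' Convenience pipeline stage: runs TM segmentation, NPA anchoring,
#' classification (unless supplied) and signature extraction for every
#' record. Records whose anchors cannot be resolved come back fully flagged.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param references Annotated reference set (see [aqp_reference_set()]).
#' @param classification Optional precomputed output of
#'   [classify_proteins()]; computed when missing.
#' @return Signature tibble (one row per record, columns as in
#'   [extract_signature()] plus `subfamily` and `group` from classification).
#' @export
extract_signatures <- function(proteins, references = aqp_reference_set(),
                               classification = NULL) {
  if (is.null(classification)) {
    classification <- classify_proteins(proteins, references)
  }
  rows <- purrr::pmap(
    list(proteins$id, proteins$sequence), function(id, sequence) {
      cls <- classification[classification$id == id, , drop = FALSE]
      template <- references[references$id == cls$best_reference[1], ,
                             drop = FALSE]
      tm <- tryCatch(predict_tm_segments(sequence),
                     aqpkit_input_error = function(e)
                       tibble(start = integer(0), end = integer(0),
                              length = integer(0)))
      anchors <- tryCatch(find_npa_anchors(sequence, tm = tm),
                          aqpkit_anchor_error = function(e) NULL)
      if (is.null(anchors)) {
        return(tibble(
          id = id, arR = NA_character_, froger = NA_character_,
          lb_region = NA_character_, le_region = NA_character_,
          coords = list(NULL), flags = list("position_unresolved:anchors")
        ))
      }
      extract_signature(sequence, anchors, template, id = id)
    })
  dplyr::bind_rows(rows) %>%
    dplyr::left_join(
      dplyr::select(classification, "id", "subfamily", "group"),
      by = "id")
}

#' Partition records by identical signature component
#'
#' @param signatures Signature tibble (from [extract_signatures()] or
#'   [extract_signature()] rows).
#' @param component `"arR"` or `"froger"`.
#' @return A tibble of groups ordered by size (desc) then lexicographically:
#'   `group_id`, `value` (the shared string, `"unresolved"` for flagged
#'   signatures), `n`, `ids` (list column).
#' @export
group_by_signature <- function(signatures, component = c("arR", "froger")) {
  component <- match.arg(component)
  if (nrow(signatures) == 0) {
    return(tibble(group_id = integer(0), value = character(0), n = integer(0),
                  ids = list()))
  }
  flagged <- lengths(signatures$flags) > 0 | is.na(signatures[[component]])
  vals <- ifelse(flagged, "unresolved", signatures[[component]])
  out <- tibble(value = vals, id = signatures$id) %>%
    dplyr::group_by(.data$value) %>%
    dplyr::summarise(n = dplyr::n(), ids = list(.data$id), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$value) %>%
    dplyr::mutate(group_id = dplyr::row_number()) %>%
    dplyr::select("group_id", "value", "n", "ids")
  out
}
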