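#' Screen candidate aquaporin proteins for completeness
#'
#' Codifies the manual pseudogene screen as explicit rules: a candidate is
#' `complete` only if its length lies within `[min_len, max_len]`, its
#' hydropathy segmentation yields at least `min_tm` TM segments, and both NPA
#' anchors (loops B and E) are found. Failures are verdicts, not errors: each
#' failed rule is listed in `reasons` and the record is `pseudogene_like`.
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param min_len,max_len Allowed protein length range (residues).
#' @param min_tm Minimum number of TM segments.
#' @param window,threshold Passed to [predict_tm_segments()].
#' @return A tibble with one row per protein: `id`, `status` (`complete` or
#'   `pseudogene_like`), `reasons` (list of failed rule ids among `length`,
#'   `tm_count`, `npa_anchors`), `length`, `tm_count`, `npa_b`, `npa_e`
#'   (anchor tripeptides or `NA`), `mw_kda`, `pi`.
#' @export
screen_proteins <- function(proteins, min_len = 200L, max_len = 400L,
                            min_tm = 5L, window = 19L, threshold = 1.6) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  rows <- purrr::map2(proteins$id, proteins$sequence, function(id, sequence) {
    len <- nchar(sequence)
    tm <- tryCatch(
      predict_tm_segments(sequence, window = window, threshold = threshold),
      aqpkit_input_error = function(e) tibble(start = integer(0),
                                             end = integer(0),
                                             length = integer(0))
    )
    anchors <- tryCatch(find_npa_anchors(sequence, tm = tm),
                        aqpkit_anchor_error = function(e) NULL)
    reasons <- character(0)
    if (len < min_len || len > max_len) reasons <- c(reasons, "length")
    if (nrow(tm) < min_tm) reasons <- c(reasons, "tm_count")
    if (is.null(anchors)) reasons <- c(reasons, "npa_anchors")
    tibble(
      id = id,
      status = if (length(reasons) == 0) "complete" else "pseudogene_like",
      reasons = list(reasons),
      length = len,
      tm_count = nrow(tm),
      npa_b = if (is.null(anchors)) NA_character_ else anchors$tripeptide[1],
      npa_e = if (is.null(anchors)) NA_character_ else anchors$tripeptide[2],
      mw_kda = as.numeric(compute_mw(sequence)),
      pi = compute_pi(sequence)
    )
  })
  dplyr::bind_rows(rows)
}
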