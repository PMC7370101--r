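# Third-residue tolerance set for N-P-X tripeptides: covers the canonical A
# plus the naturally occurring variants (T in SIP1, L in SIP2, V in XIP and
# NIP5/6 loops) and conservative neighbors.
NPA_TOLERATED <- c("A", "T", "L", "V", "S", "C", "G", "I", "M")

npa_preference <- function(third) {
  dplyr::case_when(
    third == "A" ~ 3L,
    third %in% c("T", "V", "L", "S") ~ 2L,
    TRUE ~ 1L
  )
}

npa_candidates <- function(sequence, tolerated = NPA_TOLERATED) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < 3) return(tibble(n_index = integer(0), tripeptide = character(0)))
  idx <- which(chars[-c(n - 1, n)] == "N" &
                 chars[2:(n - 1)] == "P" &
                 chars[3:n] %in% tolerated) - 1L   # 0-based
  tibble(
    n_index = idx,
    tripeptide = vapply(idx, function(i) paste(chars[i + 1:3], collapse = ""),
                        character(1)),
    preference = npa_preference(substr(vapply(idx, function(i)
      paste(chars[i + 1:3], collapse = ""), character(1)), 3, 3))
  )
}

#' Locate the loop-B and loop-E NPA anchors of an aquaporin sequence
#'
#' Scans for N-P-X tripeptides with a tolerated third residue and returns the
#' pair anchoring loops B and E. When a six-segment TM segmentation is
#' supplied, the loop-B anchor is sought between TM2 and TM3 and the loop-E
#' anchor between TM5 and TM6; otherwise (or when either region lacks a
#' candidate) a fallback selects the candidate pair separated by
#' `sep_range` residues whose third residues score highest under the
#' preference A > T,V,L,S > others, breaking ties toward the N-terminus.
#'
#' @param sequence Amino-acid string.
#' @param tm Optional TM segmentation tibble from [predict_tm_segments()].
#' @param tolerated Tolerated third residues of the tripeptide.
#' @param sep_range Allowed loop-B to loop-E spacing (residues) in fallback
#'   mode; the default 80-160 covers typical MIP architecture and rejects
#'   spurious N-terminal dipeptides.
#' @return A two-row tibble (`loop` = "B", "E") with 0-based `n_index` and
#'   `tripeptide`. Raises an `aqpkit_anchor_error` when no valid pair exists.
#' @export
find_npa_anchors <- function(sequence, tm = NULL, tolerated = NPA_TOLERATED,
                             sep_range = c(80L, 160L)) {
  cand <- npa_candidates(sequence, tolerated)
  if (nrow(cand) < 2) {
    abort("Fewer than two N-P-X anchor candidates found.",
          class = "aqpkit_anchor_error")
  }
  pick_region <- function(lo, hi) {
    inr <- cand[cand$n_index >= lo & cand$n_index < hi, , drop = FALSE]
    if (nrow(inr) == 0) return(NULL)
    inr <- inr[order(-inr$preference, inr$n_index), , drop = FALSE]
    inr[1, , drop = FALSE]
  }
  b <- e <- NULL
  if (!is.null(tm) && nrow(tm) == 6) {
    b <- pick_region(tm$end[2], tm$start[3])
    e <- pick_region(tm$end[5], tm$start[6])
    if (!is.null(b) && !is.null(e) && b$n_index >= e$n_index) b <- e <- NULL
  }
  if (is.null(b) || is.null(e)) {
    # fallback: best-scoring pair at plausible loop-B -> loop-E spacing
    best <- NULL
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        sep <- cand$n_index[j] - cand$n_index[i]
        if (sep < sep_range[1] || sep > sep_range[2]) next
        sc <- cand$preference[i] + cand$preference[j]
        if (is.null(best) || sc > best$sc) {
          best <- list(i = i, j = j, sc = sc)
        }
      }
    }
    if (is.null(best)) {
      abort("No candidate tripeptide pair with plausible loop-B/loop-E spacing.",
            class = "aqpkit_anchor_error")
    }
    b <- cand[best$i, , drop = FALSE]
    e <- cand[best$j, , drop = FALSE]
  }
  tibble(
    loop = c("B", "E"),
    n_index = c(b$n_index, e$n_index),
    tripeptide = c(b$tripeptide, e$tripeptide)
  )
}
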