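#' Kyte-Doolittle hydropathy profile
#'
#' Window-centered mean hydropathy for each residue where a full window fits.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width.
#' @return A tibble with `index` (0-based residue index of the window center)
#'   and `hydropathy` (window mean).
#' @export
hydropathy_profile <- function(sequence, window = 19L) {
  if (window %% 2 == 0 || window < 3) {
    abort("Window must be an odd integer >= 3.", class = "aqpkit_input_error")
  }
  chars <- seq_chars(sequence)
  n <- length(chars)
  if (n < window) {
    abort(sprintf("Sequence length %d is shorter than window %d.", n, window),
          class = "aqpkit_input_error")
  }
  kd <- unname(KD_SCALE[chars])
  cs <- c(0, cumsum(kd))
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half, n - half - 1L)            # 0-based
  means <- (cs[centers + half + 2L] - cs[centers - half + 1L]) / window
  tibble(index = centers, hydropathy = means)
}

#' Predict transmembrane segments by hydropathy segmentation
#'
#' Reimplements TM-helix calling as Kyte-Doolittle sliding-window
#' segmentation: maximal runs of residues whose window-centered mean
#' hydropathy reaches the threshold become candidate segments; runs separated
#' by fewer than `min_gap` residues are merged and segments shorter than
#' `min_length` are dropped. Canonical aquaporins yield the six TM helices
#' (TM1-TM6) under the defaults.
#'
#' @param sequence Amino-acid string (length >= `window`).
#' @param window Odd sliding-window width (default 19, a TM-helix span).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @param min_length Minimum reported segment length in residues.
#' @param min_gap Minimum separation below which adjacent runs merge.
#' @return A tibble of segments with 0-based half-open `start`, `end` and
#'   `length`, sorted by `start`.
#' @export
predict_tm_segments <- function(sequence, window = 19L, threshold = 1.6,
                                min_length = 12L, min_gap = 3L) {
  prof <- hydropathy_profile(sequence, window = window)
  hot <- prof$index[prof$hydropathy >= threshold]
  if (length(hot) == 0) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0)))
  }
  breaks <- which(diff(hot) > 1)
  run_start <- hot[c(1, breaks + 1)]
  run_end <- hot[c(breaks, length(hot))] + 1L        # half-open
  # merge runs separated by < min_gap residues
  keep_start <- run_start[1]
  starts <- integer(0); ends <- integer(0)
  cur_end <- run_end[1]
  if (length(run_start) > 1) {
    for (k in 2:length(run_start)) {
      if (run_start[k] - cur_end < min_gap) {
        cur_end <- run_end[k]
      } else {
        starts <- c(starts, keep_start); ends <- c(ends, cur_end)
        keep_start <- run_start[k]; cur_end <- run_end[k]
      }
    }
  }
  starts <- c(starts, keep_start); ends <- c(ends, cur_end)
  seg <- tibble(start = starts, end = ends, length = ends - starts)
  dplyr::filter(seg, .data$length >= min_length)
}
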