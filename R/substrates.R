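#' Predict transported substrates from selectivity signatures
#'
#' Matches each signature against the eight SDP rows of the bundled table.
#' `raw` mode reports every substrate whose four component patterns (ar/R,
#' loop-B region, loop-E region, Froger positions) all match. The raw
#' patterns over-call by construction, so `restricted` mode additionally
#' applies configurable subfamily gates that reconstruct the published
#' rosters (e.g. CO2 only in PIPs, Si only in NIPs with an exact GSGR ar/R
#' filter); restricted calls are always a subset of raw calls. Flagged
#' (incomplete) signatures match nothing.
#'
#' @param signatures Signature tibble from [extract_signatures()]; for
#'   restricted mode it must carry `subfamily` (and ideally `group`) columns.
#' @param table SDP pattern table from [load_sdp_table()].
#' @param mode `"restricted"` (default) or `"raw"` — selects which match
#'   column is reported as `call`.
#' @param gates Gate configuration from [load_substrate_gates()].
#' @return A long tibble, one row per (record, substrate): `id`,
#'   `substrate`, component booleans `arR_ok`, `lb_ok`, `le_ok`, `fp_ok`,
#'   `first_fail` (name of the first failing component, `NA` on a raw
#'   match), `raw_match`, `gate_ok`, `restricted_match`, and `call` (the
#'   mode-selected verdict).
#' @export
predict_substrates <- function(signatures, table = load_sdp_table(),
                               mode = c("restricted", "raw"),
                               gates = load_substrate_gates()) {
  mode <- match.arg(mode)
  has_subfamily <- "subfamily" %in% names(signatures)
  rows <- purrr::map(seq_len(nrow(signatures)), function(i) {
    sig <- signatures[i, ]
    flagged <- length(sig$flags[[1]]) > 0 ||
      anyNA(c(sig$arR, sig$lb_region, sig$le_region, sig$froger))
    comp <- function(res, classes) {
      if (flagged) return(FALSE)
      match_component(res, classes)$match
    }
    purrr::map_dfr(seq_len(nrow(table)), function(s) {
      arR_ok <- comp(sig$arR, table$arR_classes[[s]])
      lb_ok <- comp(sig$lb_region, table$lb_classes[[s]])
      le_ok <- comp(sig$le_region, table$le_classes[[s]])
      fp_ok <- comp(sig$froger, table$fp_classes[[s]])
      raw <- arR_ok && lb_ok && le_ok && fp_ok
      fails <- c("arR", "lb", "le", "fp")[!c(arR_ok, lb_ok, le_ok, fp_ok)]
      gate_ok <- substrate_gate_ok(
        gates[[table$substrate[s]]],
        subfamily = if (has_subfamily) sig$subfamily else NA_character_,
        group = if ("group" %in% names(signatures)) sig$group else NA_integer_,
        arR = sig$arR
      )
      tibble(
        id = sig$id, substrate = table$substrate[s],
        arR_ok = arR_ok, lb_ok = lb_ok, le_ok = le_ok, fp_ok = fp_ok,
        first_fail = if (length(fails) == 0) NA_character_ else fails[1],
        raw_match = raw, gate_ok = gate_ok,
        restricted_match = raw && gate_ok
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$call <- if (mode == "raw") out$raw_match else out$restricted_match
  out
}

# Evaluate one gate entry against a record's subfamily/group/arR. A missing
# or empty gate (H2O2) passes everything.
substrate_gate_ok <- function(gate, subfamily, group, arR) {
  if (is.null(gate) || length(gate) == 0) return(TRUE)
  if (!is.null(gate$subfamilies)) {
    if (is.na(subfamily) || !(subfamily %in% unlist(gate$subfamilies))) {
      return(FALSE)
    }
    if (!is.null(gate$groups) && subfamily %in% names(gate$groups)) {
      if (is.na(group) || !(group %in% unlist(gate$groups[[subfamily]]))) {
        return(FALSE)
      }
    }
  }
  if (!is.null(gate$arR)) {
    if (is.na(arR) || arR != gate$arR) return(FALSE)
  }
  TRUE
}

#' Aggregate substrate calls per record
#'
#' @param detail Long tibble from [predict_substrates()].
#' @return One row per record: `id`, `raw_matches` and `restricted_matches`
#'   (list columns of substrate names), `calls` (the mode-selected set).
#' @export
summarize_substrate_calls <- function(detail) {
  detail %>%
    dplyr::group_by(.data$id) %>%
    dplyr::summarise(
      raw_matches = list(.data$substrate[.data$raw_match]),
      restricted_matches = list(.data$substrate[.data$restricted_match]),
      calls = list(.data$substrate[.data$call]),
      .groups = "drop"
    )
}

#' Expand a printed transporter roster
#'
#' Roster tokens follow the printed notation `Name<group>;<i>` or
#' `Name<group>;<i>–<j>` (en-dash or hyphen), e.g. `"NtPIP1;4–8"` expands to
#' the five isoforms NtPIP1;4 ... NtPIP1;8. Input order is preserved.
#'
#' @param roster Character vector of tokens, or a single comma-separated
#'   roster string.
#' @return Character vector of isoform names.
#' @export
expand_roster <- function(roster) {
  if (length(roster) == 1 && grepl(",", roster)) {
    roster <- trimws(strsplit(roster, ",")[[1]])
  }
  roster <- roster[nzchar(roster)]
  out <- purrr::map(roster, function(tok) {
    m <- regexec("^([A-Za-z]+[0-9]+;)([0-9]+)(?:[–-]([0-9]+))?$", tok)
    g <- regmatches(tok, m)[[1]]
    if (length(g) == 0) {
      abort(sprintf("Unparseable roster token '%s'.", tok),
            class = "aqpkit_parse_error")
    }
    i <- as.integer(g[3])
    j <- if (is.na(g[4]) || !nzchar(g[4])) i else as.integer(g[4])
    if (j < i) {
      abort(sprintf("Descending range in roster token '%s'.", tok),
            class = "aqpkit_range_error")
    }
    paste0(g[2], seq.int(i, j))
  })
  unlist(out, use.names = FALSE)
}

#' Summarize the printed transporter rosters by substrate and subfamily
#'
#' Expands every printed roster of the SDP table and counts isoform names,
#' total and per subfamily.
#'
#' @param table SDP table from [load_sdp_table()].
#' @return A tibble: `substrate`, `n_total`, one count column per subfamily
#'   (`PIP`, `TIP`, `NIP`, `SIP`, `XIP`), and `names` (list column of the
#'   expanded isoform names).
#' @export
roster_summary <- function(table = load_sdp_table()) {
  purrr::map_dfr(seq_len(nrow(table)), function(i) {
    names_i <- if (length(table$roster[[i]]) == 0) character(0)
               else expand_roster(table$roster[[i]])
    counts <- stats::setNames(integer(length(AQP_SUBFAMILIES)),
                              AQP_SUBFAMILIES)
    if (length(names_i) > 0) {
      sub <- parse_aqp_name(names_i)$subfamily
      tab <- table(factor(sub, levels = AQP_SUBFAMILIES))
      counts[names(tab)] <- as.integer(tab)
    }
    dplyr::bind_cols(
      tibble(substrate = table$substrate[i], n_total = length(names_i)),
      as_tibble(as.list(counts)),
      tibble(names = list(names_i))
    )
  })
}
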