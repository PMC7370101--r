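#' Parse aquaporin gene names into subfamily, group, isoform and variant
#'
#' Names follow the common plant-AQP convention
#' `<species prefix><subfamily><group>;<isoform><variant>`, e.g. `NtPIP2;14`
#' or `NtXIP1;1α` (a splice variant).
#'
#' @param gene_name Character vector of gene names.
#' @return A tibble with columns `gene_name`, `prefix`, `subfamily`, `group`,
#'   `isoform`, `variant` (`NA` when absent) and `locus` (the name with any
#'   splice-variant suffix stripped).
#' @export
parse_aqp_name <- function(gene_name) {
  pattern <- "^([A-Za-z]*?)(PIP|TIP|NIP|SIP|XIP)([0-9]+);([0-9]+)(\\S?)$"
  m <- regmatches(gene_name, regexec(pattern, gene_name))
  bad <- gene_name[vapply(m, length, integer(1)) == 0]
  if (length(bad) > 0) {
    abort(sprintf("Unparseable gene name(s): %s.", paste(bad, collapse = ", ")),
          class = "aqpkit_table_error")
  }
  tibble(
    gene_name = gene_name,
    prefix = vapply(m, `[`, character(1), 2),
    subfamily = vapply(m, `[`, character(1), 3),
    group = as.integer(vapply(m, `[`, character(1), 4)),
    isoform = as.integer(vapply(m, `[`, character(1), 5)),
    variant = dplyr::na_if(vapply(m, `[`, character(1), 6), "")
  ) %>%
    dplyr::mutate(locus = sprintf("%s%s%d;%d", .data$prefix, .data$subfamily,
                                  .data$group, .data$isoform))
}

#' Load the bundled tobacco aquaporin gene inventory
#'
#' Machine-readable transcription of the published *Nicotiana tabacum* AQP
#' inventory: 90 full-length proteins from 88 gene loci (two XIP loci each
#' contribute α/β splice variants), with accession, isoelectric
#' point, molecular weight, length, and predicted subcellular localization.
#' Structural assertions (row count, name parsing) run at load time so a
#' transcription defect fails fast.
#'
#' @param path Optional path to an alternative inventory TSV with the same
#'   columns; defaults to the bundled file.
#' @return A tibble with one row per protein: `gene_name`, `accession`, `pi`,
#'   `mw_kda`, `aa_count`, `localization` (list of labels among PM, C, V),
#'   plus parsed `subfamily`, `group`, `isoform`, `variant`, `locus`.
#' @export
load_gene_inventory <- function(path = extdata_path("gene_inventory.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  parsed <- parse_aqp_name(raw$gene_name)
  if (any(raw$aa_count <= 0)) {
    abort("Inventory aa_count must be positive.", class = "aqpkit_table_error")
  }
  out <- dplyr::bind_cols(
    raw %>% dplyr::mutate(localization = strsplit(.data$localization, ",",
                                                  fixed = TRUE)),
    parsed %>% dplyr::select(-"gene_name")
  )
  bad_loc <- setdiff(unlist(out$localization), c("PM", "C", "V"))
  if (length(bad_loc) > 0) {
    abort(sprintf("Unknown localization label(s): %s.",
                  paste(bad_loc, collapse = ", ")),
          class = "aqpkit_table_error")
  }
  out
}

#' Load the bundled substrate-specificity (SDP) pattern table
#'
#' Machine-readable transcription of the published SDP table: for each of the
#' eight substrates (Bo, CO2, H2O2, NH3, Si, U, As, Sb) a position-wise
#' residue-class pattern for the ar/R filter (4 positions), the loop-B NPA
#' region (10), the loop-E NPA region (11) and Froger's positions (5), plus
#' the printed transporter roster (empty for Sb). Patterns are compiled to
#' residue-class sets at load time and their fixed lengths asserted.
#'
#' @param path Optional path to an alternative pattern TSV; defaults to the
#'   bundled transcription.
#' @return A tibble with one row per substrate: `substrate`, the four raw
#'   pattern strings (`arR`, `lb`, `le`, `fp`), compiled class lists
#'   (`arR_classes`, `lb_classes`, `le_classes`, `fp_classes`), and `roster`
#'   (list of printed roster tokens; empty character vector for "-").
#' @export
load_sdp_table <- function(path = extdata_path("sdp_patterns.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  expected <- c("Bo", "CO2", "H2O2", "NH3", "Si", "U", "As", "Sb")
  if (!setequal(raw$substrate, expected) || nrow(raw) != 8) {
    abort("SDP table must contain exactly the 8 known substrate rows.",
          class = "aqpkit_table_error")
  }
  out <- raw %>%
    dplyr::mutate(
      arR_classes = purrr::map(.data$arR, compile_pattern),
      lb_classes = purrr::map(.data$lb, compile_pattern),
      le_classes = purrr::map(.data$le, compile_pattern),
      fp_classes = purrr::map(.data$fp, compile_pattern),
      roster = purrr::map(.data$roster, function(r) {
        if (is.na(r) || trimws(r) %in% c("-", "")) character(0)
        else trimws(strsplit(r, ",")[[1]])
      })
    )
  lens <- c(arR_classes = 4L, lb_classes = 10L, le_classes = 11L,
            fp_classes = 5L)
  for (col in names(lens)) {
    got <- lengths(out[[col]])
    if (any(got != lens[[col]])) {
      abort(sprintf(
        "SDP component '%s' compiled to wrong length for substrate(s): %s.",
        sub("_classes$", "", col),
        paste(out$substrate[got != lens[[col]]], collapse = ", ")
      ), class = "aqpkit_table_error")
    }
  }
  out
}

#' Load substrate restriction gates
#'
#' The raw SDP patterns over-call: several rows are satisfied simultaneously
#' by the same signature. The published rosters embed subfamily priors; these
#' gates reconstruct them (e.g. CO2 calls only in PIPs, Si only in NIPs with
#' an exact GSGR ar/R filter). They live in a JSON config, not in code, and
#' can be replaced by the user.
#'
#' @param path Optional path to a gate JSON; defaults to the bundled config.
#' @return Named list, one element per substrate, each with optional fields
#'   `subfamilies`, `groups`, `arR`.
#' @export
load_substrate_gates <- function(path = extdata_path("substrate_gates.json")) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
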