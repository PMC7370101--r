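# Deterministic generators of aquaporin-like test worlds: subfamily-group
# templates with planted anchors and selectivity signatures, mutated
# families, gene models, and FPKM matrices, each with a ground-truth
# manifest.

# Planted signature strings per subfamily-group. Each string is a fixed
# representative of the corresponding residue-class pattern of the bundled
# SDP table; the le string is chosen so that its positions NPA2-3 and NPA2+3
# equal the 3rd and 4th ar/R residues (LE1/LE2), keeping the planted ar/R
# internally consistent with the NPA-relative extraction rule. Loop-B NPA
# variants follow the family biology: NPT in SIP1, NPL in SIP2, NPV in XIPs;
# NIP5/6 carry the loop-E NPV variant.
GROUP_SIGNATURES <- tibble::tribble(
  ~subfamily, ~group, ~arR,   ~lb,          ~le,           ~fp,
  "PIP",      1L,     "FHTR", "SGGHINPAVT", "GTGINPARSLG", "MSAFW",
  "PIP",      2L,     "FHTR", "SGGHINPAVT", "GTGINPARSLG", "QSAFW",
  "TIP",      1L,     "HIAR", "SGGHVNPAVT", "GASMNPARSFG", "TSAYW",
  "TIP",      2L,     "HIAR", "SGGHVNPAVT", "GASMNPARSFG", "TSAYW",
  "TIP",      3L,     "HIAR", "SGGHVNPAVT", "GASMNPARSFG", "TSAYW",
  "TIP",      4L,     "HIAR", "SGGHVNPAVT", "GASMNPARSFG", "TSAYW",
  "TIP",      5L,     "HIAR", "SGGHVNPAVT", "GASMNPARSFG", "TSAYW",
  "NIP",      1L,     "WVGR", "SGAHLNPAVT", "GGSMNPARSLG", "LTAYF",
  "NIP",      2L,     "GSGR", "SGAHMNPAVT", "GGSMNPARTLG", "LTAYF",
  "NIP",      3L,     "WSGR", "SGAHLNPAVT", "GGSMNPARSLG", "LTAYF",
  "NIP",      4L,     "WAGR", "SGAHLNPAVT", "GGSMNPARSLG", "LTAYF",
  "NIP",      5L,     "AIGR", "SGGHLNPAVT", "GGSMNPVRTLG", "FTAYF",
  "NIP",      6L,     "GIGR", "SGGHLNPAVT", "GGSMNPVRTLG", "VTAYF",
  "NIP",      7L,     "TAGR", "SGAHLNPAVT", "GGSMNPARTLG", "FTAYL",
  "NIP",      8L,     "AIAR", "SGAHLNPAVT", "GASMNPARTLG", "YTAYM",
  "SIP",      1L,     "YSAR", "STGHLNPTVT", "GASLNPARSLG", "VAAYW",
  "SIP",      2L,     "YGAR", "STGHLNPLVT", "GASLNPARSLG", "IAAYW",
  "XIP",      1L,     "IVAR", "SGGHINPVVT", "GASMNPARSLG", "FCAYW",
  "XIP",      2L,     "IVGR", "SGGHINPVLT", "GGSMNPARSLG", "VTAYW"
)

# Scaffold layout (0-based, total 280 residues): six 23-residue hydrophobic
# blocks separated by polar loops; loop B holds the 10-mer NPA region, loop E
# the 11-mer.
TEMPLATE_LAYOUT <- local({
  tm_len <- 23L
  starts <- c(nterm = 0L, tm1 = 20L, loopA = 43L, tm2 = 59L, loopB = 82L,
              tm3 = 102L, loopC = 125L, tm4 = 143L, loopD = 166L, tm5 = 180L,
              loopE = 203L, tm6 = 227L, cterm = 250L)
  list(
    total = 280L,
    tm = tibble(start = unname(starts[c("tm1", "tm2", "tm3", "tm4", "tm5",
                                        "tm6")]),
                end = unname(starts[c("tm1", "tm2", "tm3", "tm4", "tm5",
                                      "tm6")]) + tm_len),
    regions = starts,
    lb_start = 87L,    # loop B offset 5 -> NPA1_N = 92
    le_start = 207L,   # loop E offset 4 -> NPA2_N = 211
    positions = c(H2 = 76L, H5 = 197L, LE1 = 208L, LE2 = 214L,
                  P1 = 134L, P2 = 220L, P3 = 222L, P4 = 255L, P5 = 258L,
                  NPA1_N = 92L, NPA2_N = 211L)
  )
})

TM_AA <- c("I", "L", "V", "F", "A", "M")
TM_W <- c(5, 5, 4, 2, 1, 1)
LOOP_AA <- c("S", "T", "G", "Q", "H")
LOOP_W <- c(4, 4, 4, 1, 1)
PAD_AA <- c("S", "T", "G")
PAD_WIDTH <- 5L

# Mutation alphabet: the 20 residues minus N and P, so substitutions can
# never create a new N-P-X tripeptide near (or away from) the anchors.
MUTATION_AA <- c("A", "R", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "S", "T", "W", "Y", "V")

#' Build a deterministic annotated reference template
#'
#' Constructs an aquaporin-like sequence of 280 residues for one
#' subfamily-group: six strongly hydrophobic 23-residue blocks separated by
#' polar loops, the subfamily's loop-B 10-mer and loop-E 11-mer NPA regions,
#' and planted ar/R and Froger residues consistent with the bundled SDP
#' patterns. The builder is a pure function of (subfamily, group): repeated
#' calls return byte-identical templates.
#'
#' @param subfamily One of PIP, TIP, NIP, SIP, XIP.
#' @param group Group index within the subfamily (e.g. 2 for PIP2).
#' @return A one-row tibble: `id`, `subfamily`, `group`, `sequence`,
#'   `positions` (named 0-based indices for H2, H5, LE1, LE2, P1-P5, NPA1_N,
#'   NPA2_N), planted `arR`, `lb`, `le`, `fp` strings, and `tm` (tibble of
#'   planted TM intervals).
#' @export
build_template <- function(subfamily, group) {
  sig <- GROUP_SIGNATURES[GROUP_SIGNATURES$subfamily == subfamily &
                            GROUP_SIGNATURES$group == group, , drop = FALSE]
  if (nrow(sig) != 1) {
    abort(sprintf("No template defined for %s group %d.", subfamily, group),
          class = "aqpkit_input_error")
  }
  lay <- TEMPLATE_LAYOUT
  chars <- with_local_seed(string_seed(paste0(subfamily, group)), {
    x <- character(lay$total)
    region_of <- function(name) {
      starts <- lay$regions
      s <- starts[[name]]
      nxt <- c(starts[-1], lay$total)
      names(nxt) <- names(starts)
      seq.int(s, nxt[[name]] - 1L)
    }
    tm_names <- c("tm1", "tm2", "tm3", "tm4", "tm5", "tm6")
    loop_names <- c("nterm", "loopA", "loopB", "loopC", "loopD", "loopE",
                    "cterm")
    for (nm in tm_names) {
      idx <- region_of(nm)
      x[idx + 1L] <- sample(TM_AA, length(idx), replace = TRUE, prob = TM_W)
    }
    for (nm in loop_names) {
      idx <- region_of(nm)
      x[idx + 1L] <- sample(LOOP_AA, length(idx), replace = TRUE,
                            prob = LOOP_W)
      # mild pads at the loop/TM boundaries keep hydropathy edges clean
      edge <- c(utils::head(idx, PAD_WIDTH), utils::tail(idx, PAD_WIDTH))
      x[edge + 1L] <- sample(PAD_AA, length(edge), replace = TRUE)
    }
    x
  })
  chars[1] <- "M"
  plant <- function(chars, start0, str) {
    s <- seq_chars(str)
    chars[start0 + seq_along(s)] <- s
    chars
  }
  chars <- plant(chars, lay$lb_start, sig$lb)
  chars <- plant(chars, lay$le_start, sig$le)
  arr <- seq_chars(sig$arR)
  fps <- seq_chars(sig$fp)
  pos <- lay$positions
  chars[pos[["H2"]] + 1L] <- arr[1]
  chars[pos[["H5"]] + 1L] <- arr[2]
  for (k in 1:5) chars[pos[[paste0("P", k)]] + 1L] <- fps[k]
  sequence <- paste(chars, collapse = "")
  stopifnot(substr(sequence, pos[["NPA1_N"]] + 1L, pos[["NPA1_N"]] + 1L) == "N",
            substr(sequence, pos[["NPA2_N"]] + 1L, pos[["NPA2_N"]] + 1L) == "N")
  tibble(
    id = sprintf("ref_%s%d", subfamily, group),
    subfamily = subfamily, group = group,
    sequence = sequence,
    positions = list(pos),
    arR = sig$arR, lb = sig$lb, le = sig$le, fp = sig$fp,
    tm = list(lay$tm)
  )
}

#' Packaged annotated reference set
#'
#' One deterministic template per subfamily-group (PIP1-2, TIP1-5, NIP1-8,
#' SIP1-2, XIP1-2; 19 references). Users analyzing real data may substitute
#' their own annotated references with the same columns.
#'
#' @return A tibble of templates, one row per reference (see
#'   [build_template()]).
#' @export
aqp_reference_set <- function() {
  if (is.null(.aqpkit_env$reference_set)) {
    .aqpkit_env$reference_set <- dplyr::bind_rows(
      purrr::map2(GROUP_SIGNATURES$subfamily, GROUP_SIGNATURES$group,
                  build_template)
    )
  }
  .aqpkit_env$reference_set
}

# 0-based indices that mutation must not touch: the 11 annotated positions
# plus the full loop-B and loop-E NPA windows.
protected_positions <- function() {
  lay <- TEMPLATE_LAYOUT
  sort(unique(c(
    unname(lay$positions),
    seq.int(lay$positions[["NPA1_N"]] - 5L, lay$positions[["NPA1_N"]] + 4L),
    seq.int(lay$positions[["NPA2_N"]] - 4L, lay$positions[["NPA2_N"]] + 6L)
  )))
}

#' Simulate a mutated aquaporin family with ground truth
#'
#' Each record is its subfamily-group template with i.i.d. substitutions at
#' unprotected positions (protected: the annotated signature positions and
#' the two NPA windows) at the requested per-residue rate. Substitutions draw
#' from the 18-letter alphabet excluding N and P, so no spurious NPA
#' candidates can arise. Pure function of (spec, seed): regeneration is
#' byte-identical.
#'
#' @param spec Tibble with columns `subfamily`, `group`, `n` (records per
#'   group). Defaults to 10 records for the first group of each subfamily.
#' @param divergence Per-residue substitution probability in [0, 0.5].
#' @param seed Integer seed.
#' @return A list with `proteins` (tibble `id`, `sequence`, `subfamily`,
#'   `group`) and `manifest` (per record: planted signature strings, the
#'   planted TM intervals, and `raw_substrates` computed from the bundled SDP
#'   table at generation time).
#' @export
simulate_family <- function(spec = NULL, divergence = 0.1, seed = 1L) {
  if (is.null(spec)) {
    spec <- tibble(subfamily = AQP_SUBFAMILIES, group = 1L, n = 10L)
  }
  if (divergence < 0 || divergence > 0.5) {
    abort("divergence must be in [0, 0.5].", class = "aqpkit_input_error")
  }
  sdp <- load_sdp_table()
  prot <- protected_positions()
  rows <- list()
  man <- list()
  for (r in seq_len(nrow(spec))) {
    tpl <- build_template(spec$subfamily[r], spec$group[r])
    tpl_chars <- seq_chars(tpl$sequence)
    free <- setdiff(seq_along(tpl_chars) - 1L, prot)
    raw_sub <- raw_substrates_for(tpl$arR, tpl$lb, tpl$le, tpl$fp, sdp)
    for (k in seq_len(spec$n[r])) {
      id <- sprintf("sim_%s%d_%03d", spec$subfamily[r], spec$group[r], k)
      chars <- tpl_chars
      mutate_mask <- with_local_seed(
        string_seed(id, base = as.numeric(seed) * 7919),
        {
          hit <- free[stats::runif(length(free)) < divergence]
          repl <- vapply(chars[hit + 1L], function(cur) {
            sample(setdiff(MUTATION_AA, cur), 1L)
          }, character(1))
          list(hit = hit, repl = repl)
        }
      )
      chars[mutate_mask$hit + 1L] <- mutate_mask$repl
      rows[[length(rows) + 1]] <- tibble(
        id = id, sequence = paste(chars, collapse = ""),
        subfamily = spec$subfamily[r], group = spec$group[r]
      )
      man[[length(man) + 1]] <- tibble(
        id = id, subfamily = spec$subfamily[r], group = spec$group[r],
        arR = tpl$arR, lb = tpl$lb, le = tpl$le, fp = tpl$fp,
        froger = tpl$fp,
        positions = tpl$positions,
        tm = tpl$tm,
        n_mutations = length(mutate_mask$hit),
        raw_substrates = list(raw_sub)
      )
    }
  }
  list(proteins = dplyr::bind_rows(rows), manifest = dplyr::bind_rows(man))
}

# Substrates whose four compiled patterns all match the given component
# strings (generation-time ground truth).
raw_substrates_for <- function(arR, lb, le, fp, sdp = load_sdp_table()) {
  hit <- vapply(seq_len(nrow(sdp)), function(i) {
    match_component(arR, sdp$arR_classes[[i]])$match &&
      match_component(lb, sdp$lb_classes[[i]])$match &&
      match_component(le, sdp$le_classes[[i]])$match &&
      match_component(fp, sdp$fp_classes[[i]])$match
  }, logical(1))
  sdp$substrate[hit]
}

#' Simulate gene models with known intron structure
#'
#' Builds one gene model per requested gene on its own coordinate system:
#' exon lengths drawn uniformly from `exon_bp`, intron lengths from
#' `intron_bp`, with an optional planted long intron per selected gene.
#' Deterministic under `seed`.
#'
#' @param intron_counts Named integer vector: gene id -> number of introns.
#' @param seed Integer seed.
#' @param exon_bp,intron_bp Length ranges (bp).
#' @param long_intron_genes Gene ids that receive one planted long intron.
#' @param long_intron_bp Length of the planted long intron.
#' @return A list with `models` (exon tibble as from [read_gene_models()])
#'   and `manifest` (per gene: `gene_id`, `n_introns`, `intron_lengths` list,
#'   `has_long_intron`).
#' @export
simulate_gene_models <- function(intron_counts, seed = 1L,
                                 exon_bp = c(50L, 300L),
                                 intron_bp = c(80L, 2000L),
                                 long_intron_genes = character(0),
                                 long_intron_bp = 12000L) {
  if (any(intron_counts < 0)) {
    abort("Intron counts must be non-negative.", class = "aqpkit_input_error")
  }
  if (is.null(names(intron_counts))) {
    names(intron_counts) <- sprintf("gene%03d", seq_along(intron_counts))
  }
  rows <- list(); man <- list()
  for (g in names(intron_counts)) {
    n_introns <- intron_counts[[g]]
    n_exons <- n_introns + 1L
    lens <- with_local_seed(string_seed(g, base = as.numeric(seed) * 104729), {
      ex <- sample(seq.int(exon_bp[1], exon_bp[2]), n_exons, replace = TRUE)
      intr <- if (n_introns > 0) {
        sample(seq.int(intron_bp[1], intron_bp[2]), n_introns, replace = TRUE)
      } else integer(0)
      if (g %in% long_intron_genes && n_introns > 0) {
        intr[sample.int(n_introns, 1)] <- long_intron_bp
      }
      strand <- sample(c("+", "-"), 1)
      list(ex = ex, intr = intr, strand = strand)
    })
    starts <- integer(n_exons); ends <- integer(n_exons)
    at <- 0L
    for (i in seq_len(n_exons)) {
      starts[i] <- at
      ends[i] <- at + lens$ex[i]
      at <- ends[i] + if (i <= n_introns) lens$intr[i] else 0L
    }
    rows[[g]] <- tibble(
      transcript_id = paste0(g, ".t1"), gene_id = g, strand = lens$strand,
      exon_start = starts, exon_end = ends
    )
    man[[g]] <- tibble(
      gene_id = g, n_introns = n_introns,
      intron_lengths = list(as.integer(lens$intr)),
      has_long_intron = any(lens$intr >= long_intron_bp)
    )
  }
  list(models = dplyr::bind_rows(rows), manifest = dplyr::bind_rows(man))
}

#' Intron-count catalogue for the bundled tobacco inventory
#'
#' Encodes the published per-subfamily intron architecture of the 88 tobacco
#' AQP loci: PIPs with two or three introns (exceptions: PIP2;3 one; PIP1;5,
#' PIP1;7, PIP1;11, PIP2;8 none), TIPs with two (TIP1;2-4 and TIP1;8-9 one,
#' TIP1;1 none), NIPs with four (NIP5;1 three; NIP3s and NIP6;1 five; NIP8;2
#' six, one intron of which is ~10 kb), SIPs with two (SIP2;1 none), XIPs
#' with two (XIP2;1 one). PIP2;2 carries a ~15 kb intron.
#'
#' @param inventory Gene inventory tibble, as from [load_gene_inventory()].
#' @return Named integer vector of intron counts per locus (88 entries), with
#'   attribute `long_intron_genes` naming loci with a planted long intron.
#' @export
inventory_intron_counts <- function(inventory = load_gene_inventory()) {
  loci <- dplyr::distinct(inventory, .data$locus, .data$subfamily,
                          .data$group, .data$isoform)
  n <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    key <- sprintf("%s%d;%d", l$subfamily, l$group, l$isoform)
    n[i] <- switch(
      key,
      "PIP2;3" = 1L, "PIP1;5" = 0L, "PIP1;7" = 0L, "PIP1;11" = 0L,
      "PIP2;8" = 0L,
      "TIP1;1" = 0L, "TIP1;2" = 1L, "TIP1;3" = 1L, "TIP1;4" = 1L,
      "TIP1;8" = 1L, "TIP1;9" = 1L,
      "NIP5;1" = 3L, "NIP3;1" = 5L, "NIP3;2" = 5L, "NIP6;1" = 5L,
      "NIP8;2" = 6L,
      "SIP2;1" = 0L,
      "XIP2;1" = 1L,
      switch(l$subfamily,
             PIP = if (l$group == 1) 3L else 2L,
             TIP = 2L, NIP = 4L, SIP = 2L, XIP = 2L)
    )
  }
  names(n) <- loci$locus
  attr(n, "long_intron_genes") <- c("NtPIP2;2", "NtNIP8;2")
  n
}

#' Simulate an FPKM matrix with a planted expressed/not-expressed partition
#'
#' Expressed (gene, condition) cells draw a log10-normal base level (mean 1,
#' sd 0.5; mean FPKM around 10); non-expressed cells draw uniformly from
#' [0, 0.8]. Replicates add multiplicative log-normal noise (sd 0.1 log10
#' units). Draws are clamped away from the FPKM = 1 decision boundary
#' (expressed replicates >= 1.25, non-expressed <= 0.95) so the planted
#' labels are exactly recoverable by the threshold rule.
#'
#' @param n_genes Number of genes (ignored when `gene_ids` given).
#' @param conditions Character vector of condition labels.
#' @param replicates Replicates per condition.
#' @param expressed_fraction Probability that a (gene, condition) cell is
#'   expressed (ignored for conditions named in `n_expressed`).
#' @param n_expressed Optional named integer vector: condition -> exact
#'   number of expressed genes to plant.
#' @param gene_ids Optional gene id vector.
#' @param seed Integer seed.
#' @return A list with `expression` (an `aqp_expression` object) and
#'   `manifest` (tibble `gene_id`, `condition`, `expressed`).
#' @export
simulate_fpkm <- function(n_genes = 88L,
                          conditions = c("root", "leaf", "flower"),
                          replicates = 3L, expressed_fraction = 0.8,
                          n_expressed = NULL, gene_ids = NULL, seed = 1L) {
  if (expressed_fraction < 0 || expressed_fraction > 1) {
    abort("expressed_fraction must be in [0, 1].", class = "aqpkit_input_error")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  n_genes <- length(gene_ids)
  with_local_seed(seed, {
    labels <- list(); cols <- list()
    design <- tibble(
      sample = sprintf("%s_r%d", rep(conditions, each = replicates),
                       rep(seq_len(replicates), length(conditions))),
      condition = rep(conditions, each = replicates),
      replicate = rep(seq_len(replicates), length(conditions))
    )
    fpkm <- tibble(gene_id = gene_ids)
    for (cond in conditions) {
      expressed <- if (!is.null(n_expressed) && cond %in% names(n_expressed)) {
        k <- n_expressed[[cond]]
        stopifnot(k >= 0, k <= n_genes)
        seq_len(n_genes) %in% sample.int(n_genes, k)
      } else {
        stats::runif(n_genes) < expressed_fraction
      }
      base <- ifelse(expressed,
                     pmax(10^stats::rnorm(n_genes, 1, 0.5), 1.3),
                     stats::runif(n_genes, 0, 0.8))
      for (r in seq_len(replicates)) {
        vals <- base * 10^stats::rnorm(n_genes, 0, 0.1)
        vals <- ifelse(expressed, pmax(vals, 1.25), pmin(vals, 0.95))
        fpkm[[sprintf("%s_r%d", cond, r)]] <- vals
      }
      labels[[cond]] <- tibble(gene_id = gene_ids, condition = cond,
                               expressed = expressed)
    }
    list(expression = new_aqp_expression(fpkm, design),
         manifest = dplyr::bind_rows(labels))
  })
}
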