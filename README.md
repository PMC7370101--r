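# aqpkit

Characterization of plant **aquaporin (AQP / MIP) families** from protein
sequences, gene models, and expression tables. Aquaporins are six-helix
membrane channels whose transport selectivity is encoded in a handful of
sequence positions: the two conserved **NPA motifs** in loops B and E, the
four-residue **ar/R selectivity filter** (H2, H5, LE1, LE2), and the five
**Froger positions** (P1–P5). aqpkit is written for researchers who have a
set of candidate AQP protein sequences — for example from a genome screen —
and want a reproducible path from raw FASTA to per-isoform subfamily calls,
selectivity signatures, predicted substrates, gene structures, and
organ-level expression calls.

The package bundles machine-readable transcriptions of a published tobacco
(*Nicotiana tabacum*) AQP gene inventory (90 proteins from 88 loci) and the
matching substrate-specificity (SDP) pattern table, plus a deterministic
synthetic-data generator with ground-truth manifests so every pipeline
stage is testable offline.

## What it computes

* **Completeness screen** — Kyte–Doolittle TM segmentation (window 19,
  threshold 1.6), tolerant NPA anchoring (N-P-X with
  X ∈ {A,T,L,V,S,C,G,I,M}), and rule-based verdicts
  (length ∈ [200, 400], ≥ 5 TM segments, both anchors) separating
  full-length proteins from pseudogene-like fragments; molecular weight and
  isoelectric point (Bjellqvist pKa, bisection).
* **Classification** — nearest-annotated-reference assignment to subfamily
  (PIP/TIP/NIP/SIP/XIP) and group by normalized alignment identity
  (Needleman–Wunsch, BLOSUM62, affine 10/1; classified iff identity ≥ 0.35
  over ≥ 150 columns), plus a neighbor-joining tree on p-distances.
* **Signatures** — ar/R filter and Froger positions via NPA-relative rules
  (LB = [NPA1−5, NPA1+5), LE = [NPA2−4, NPA2+7), LE1 = NPA2−3,
  LE2 = NPA2+3) combined with annotated-template position transfer.
* **Substrate prediction** — position-wise residue-class matching against
  the eight SDP rows (B, CO2, H2O2, NH3, Si, urea, As, Sb), in `raw` mode
  (patterns only) or `restricted` mode (subfamily gates reconstructing the
  published rosters), plus printed-roster expansion
  (`NtPIP1;4–8` → five names).
* **Gene structure** — intron/exon summaries on 0-based half-open
  coordinates from GFF3, with ≥ 10 kb introns flagged.
* **Expression calling** — mean FPKM per (gene, condition); expressed iff
  log10(mean FPKM) > 0, strictly; ubiquitous/silent sets and heatmap
  export.

## Worked example

```r
library(aqpkit)

# a small synthetic world with known truth: two PIP groups and NIP2
fam <- simulate_family(
  spec = tibble::tibble(subfamily = c("PIP", "PIP", "NIP"),
                        group = c(1L, 2L, 2L), n = 2L),
  divergence = 0.1, seed = 7)
expr <- simulate_fpkm(gene_ids = fam$proteins$id, seed = 7)

res <- run_aqp_pipeline(fam$proteins, expression = expr$expression)
res
#> <aqp_pipeline>
#>   proteins: 6 input, 6 complete, 0 pseudogene-like
#>   classified: 6 (mode: restricted substrate calls)
#>   expression: 3 conditions

tidy(res)[, c("id", "subfamily", "group", "arR", "froger", "substrates")]
#>             id subfamily group  arR froger substrates
#> 1 sim_PIP1_001       PIP     1 FHTR  MSAFW        CO2
#> 2 sim_PIP1_002       PIP     1 FHTR  MSAFW        CO2
#> 3 sim_PIP2_001       PIP     2 FHTR  QSAFW   CO2;H2O2
#> 4 sim_PIP2_002       PIP     2 FHTR  QSAFW   CO2;H2O2
#> 5 sim_NIP2_001       NIP     2 GSGR  LTAYF   Si;As;Sb
#> 6 sim_NIP2_002       NIP     2 GSGR  LTAYF   Si;As;Sb

expressed_counts(res$expression_calls)
#>   condition n_expressed
#> 1    flower           5
#> 2      leaf           6
#> 3      root           5
```

Reading the output: every record passed the completeness screen; both PIP
groups carry the invariant PIP filter F-H-T-R but split at Froger P1 (M in
group 1, Q in group 2), which is exactly what gates CO2 vs H2O2 calls; the
NIP2 records show the G-S-G-R filter of silicon channels. With real data,
start from `read_aqp_fasta("candidates.faa")` and, if available,
`read_gene_models("genes.gff3")` and
`read_fpkm_matrix("fpkm.tsv", "design.tsv")`; `autoplot(res)` renders the
expression heatmap.

The bundled tables are available directly: `load_gene_inventory()` (90
protein rows, 88 loci: 34 PIP, 27 TIP, 20 NIP, 3 SIP, 4 XIP),
`load_sdp_table()` and `roster_summary()` (e.g. 12 PIP names in the CO2
roster, 10 NIP names for arsenic).

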