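---
title: "Methods: aquaporin family annotation and substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaporin family annotation and substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpkit)
```

## Scope and model

Aquaporins (AQPs, major intrinsic proteins) are small channel proteins with
six transmembrane helices (TM1–TM6), five connecting loops (A–E), and two
conserved Asn-Pro-Ala (NPA) motifs in loops B and E. Two sequence-level
determinants of transport selectivity are well established: the
aromatic/arginine (ar/R) constriction, formed by four residues contributed
by TM2 (H2), TM5 (H5), and loop E (LE1, LE2); and Froger's positions P1–P5.
Vascular-plant AQPs fall into five subfamilies — PIP, TIP, NIP, SIP, XIP —
each with characteristic group structure (PIP1/PIP2, TIP1–5, NIP1–8,
SIP1–2, XIP1–2 in tobacco).

aqpkit turns the corresponding annotation workflow into composable, testable
stages:

1. **Screen** — hydropathy-based TM segmentation, NPA anchoring, and a
   rule-based completeness verdict separating full-length candidates from
   pseudogene-like fragments.
2. **Classify** — nearest-annotated-reference subfamily/group assignment,
   with an optional neighbor-joining tree.
3. **Signatures** — extraction of the ar/R filter, Froger positions, and
   the loop-B/loop-E NPA-region strings.
4. **Substrates** — matching signatures against position-wise residue-class
   patterns (SDPs) for eight substrates: boron, CO2, H2O2, ammonia,
   silicon, urea, arsenic, antimony.
5. **Structure / expression** — intron–exon summaries from gene models, and
   FPKM-threshold expression calling.

A deterministic synthetic-data generator with ground-truth manifests makes
every stage verifiable without downloads. The bundled data are
machine-readable transcriptions of a published tobacco AQP gene inventory
(90 proteins, 88 loci) and the corresponding SDP pattern table.

## TM segmentation

`predict_tm_segments()` computes a Kyte–Doolittle window-centered mean
hydropathy profile (window 19 residues, an α-helical membrane span) and
reports maximal runs of residues whose window mean reaches the threshold
(default 1.6), merging runs separated by fewer than 3 residues and dropping
segments shorter than 12. The window and threshold were chosen so that
canonical six-helix templates are segmented into exactly six TM blocks;
both are exposed as arguments. This is a hydropathy reimplementation of the
dedicated TM predictors used interactively in this field; it is deliberately
simple and deterministic.

## NPA anchoring

`find_npa_anchors()` scans for N-P-X tripeptides with X in
{A, T, L, V, S, C, G, I, M}. The canonical third residue is alanine;
naturally occurring variants motivate the tolerance set: threonine (SIP1),
leucine (SIP2), and valine (XIP loop B, NIP5/6 loop E). When the
segmentation yields exactly six TM blocks, the loop-B anchor is sought
between TM2 and TM3 and the loop-E anchor between TM5 and TM6. Otherwise a
fallback picks the candidate pair separated by 80–160 residues (typical
loop-B→loop-E spacing in MIPs) whose third residues score best under the
preference A > {T, V, L, S} > others, ties resolved toward the N-terminus.
The spacing window exists to stop spurious N-terminal NP dipeptides from
anchoring.

## Completeness screen

A candidate is `complete` only if all of: length within [200, 400]
residues, at least 5 TM segments, and both NPA anchors found. Anything else
is `pseudogene_like`, with each failed rule listed. The thresholds are
configurable; the defaults bracket the observed full-length range
(238–347 aa in the bundled inventory) with margin. This codifies a screen
that is usually performed by manual inspection; the exact manual criteria
behind the published discard count are not recoverable, so that count is
not a package claim.

## Physicochemical calculators

`compute_mw()` sums average residue masses plus one water (kDa); sequences
containing X are flagged approximate. `compute_pi()` finds the zero of the
Henderson–Hasselbalch net charge by bisection on pH 0–14 (tolerance 0.01),
using the Bjellqvist pKa set (N-terminus 7.5, C-terminus 3.55; K 10.0,
R 12.0, H 5.98, D 4.05, E 4.45, C 9.0, Y 10.0). The tool behind the
inventory's printed pI/MW columns is unknown, so agreement with those
columns is diagnostic (±0.3 pH, ±0.5 kDa) rather than exact.

## Classification

`classify_proteins()` aligns each query globally (Needleman–Wunsch,
BLOSUM62, affine gap open 10 / extend 1, via Biostrings) to every annotated
reference and copies subfamily and group from the best reference by
normalized identity (matches over aligned non-gap columns). A call requires
identity ≥ 0.35 over ≥ 150 aligned columns — a conservative family-level
recognition threshold; anything below is `unclassified`. The packaged
reference set is one deterministic template per subfamily-group (19
references) built by the generator, so tests need no downloads; users with
real data should supply references built from curated sequences.

Full phylogenetic inference (ML with bootstraps) is out of scope by design:
trees are used here only to assign subfamilies, which nearest-reference
scoring reproduces. `build_nj_tree()` provides a neighbor-joining tree on
alignment p-distances for visual grouping, with negative branch lengths
clamped to zero.

## Signature extraction

The loop-B and loop-E region strings are windows anchored on the N of each
NPA motif: LB = [NPA1−5, NPA1+5) (10-mer) and LE = [NPA2−4, NPA2+7)
(11-mer). The offsets are fixed by locating the N inside the canonical PIP
exemplar strings: "SGGHINPAVT" has its N at offset 5, "GTGINPARSLG" at
offset 4. The same exemplars fix LE1 = NPA2−3 and LE2 = NPA2+3 (the T and R
of the PIP filter F-H-T-R). H2, H5, and P1–P5 have no reliable
sequence-local rule, so they transfer from the annotated template through
the global alignment; positions aligned to a gap come back flagged
`position_unresolved`. When both routes resolve LE1/LE2 and disagree, the
NPA-relative rule wins (the region definitions are NPA-anchored) and the
conflict is surfaced as a warning. Flagged signatures are excluded from
substrate matching and form their own bin in `group_by_signature()`.

## Substrate prediction

`compile_pattern()` compiles the SDP table's bracket syntax into one
residue-class set per position (4/10/11/5 positions for ar/R, LB, LE, FP);
`match_component()` is exact positionwise membership. A substrate is a
**raw** match when all four components match. The raw patterns over-call by
construction — the silicon-consistent NIP signature also satisfies the
arsenic, antimony and urea classes — while the published rosters embed
subfamily priors. **Restricted** mode therefore applies gates that live in
`inst/extdata/substrate_gates.json`, not in code: CO2 → PIP; NH3 → TIP;
Si → NIP with ar/R exactly GSGR; As, Sb → NIP; B → NIP group 5 or XIP;
urea → TIP or XIP; H2O2 ungated. Restricted calls are provably a subset of
raw calls. The gates are a reconstruction of the published outcome, not a
published algorithm; edge cases (e.g. which NIP groups the published As
roster excludes) cannot be resolved at subfamily granularity and are
documented rather than forced. The antimony row has patterns but an empty
printed roster; it is still evaluated and reported in raw mode.

`expand_roster()` implements the printed range notation (`NtPIP1;4–8`,
en-dash or hyphen) and `roster_summary()` reproduces the published roster
arithmetic: 12 PIP names for CO2, 10 NIP names for As, one NIP for Si, none
for Sb. One internal inconsistency of the source tables is carried as-is:
the H2O2 roster lists 15 PIP names while the accompanying narrative says
thirteen; no package result depends on it.

## Gene structure and expression

Coordinates are 0-based half-open internally; GFF3 conversion happens only
at the I/O boundary, which makes intron lengths and spans pure subtraction
and gives exact `sum(exons) + sum(introns) == span` invariants. Introns at
or above 10 kb are flagged long (the inventory's structural catalogue
highlights a ~10 kb and a ~15 kb intron). Where a gene has several mRNAs,
the most exon-rich transcript represents the gene.

Expression calling aggregates replicate FPKM per (gene, condition) by
arithmetic mean (configurable to median — the published analysis does not
state its aggregation), then applies the strict rule: expressed iff
log10(aggregate) > 0, i.e. mean FPKM > 1. A gene at exactly FPKM 1 is not
expressed. A zero aggregate has no logarithm; it is reported as `NA` (the
heatmap sentinel, serialized as "NA" in TSV) and not expressed.

## The synthetic generator

`build_template()` emits, per subfamily-group, a 280-residue sequence with
six 23-residue hydrophobic blocks (drawn from I/L/V/F/A/M, weighted toward
the strong hydropathy residues) separated by polar loops (S/T/G/Q/H, with
5-residue mild S/T/G pads at every block boundary so hydropathy edges stay
clean). Loop B embeds the subfamily's 10-mer NPA region and loop E its
11-mer; the ar/R and Froger residues are planted at fixed annotated
coordinates. Every planted string is a fixed representative of the
corresponding SDP residue-class pattern, so each template's intended
substrate is a raw match by construction. Templates are pure functions of
(subfamily, group).

`simulate_family()` mutates unprotected positions i.i.d. at the requested
divergence, drawing from the 18-letter alphabet without N and P — no
substitution can create a spurious NPA candidate. Protected positions are
the 11 annotated coordinates plus both NPA windows. The generator does not
model indels, rate heterogeneity, or codon structure; recovery results on
it therefore demonstrate correctness of the extraction machinery under
substitution noise, not robustness to the full variability of real
sequences (real-data use relies on the alignment-transfer route and the
flag system).

`simulate_fpkm()` draws expressed cells log10-normal (mean 1, sd 0.5) and
non-expressed cells uniform on [0, 0.8], with multiplicative replicate
noise (log10 sd 0.1). Draws are clamped away from the FPKM = 1 boundary
(expressed replicates ≥ 1.25, non-expressed ≤ 0.95) so planted labels are
exactly recoverable — count-recovery tests are exact rather than
probabilistic by design. `simulate_gene_models()` draws exon lengths from
50–300 bp and intron lengths from 80–2000 bp, with optional planted ≥ 10 kb
introns; `inventory_intron_counts()` encodes the published per-locus intron
catalogue for the 88 tobacco loci (PIP1s are assigned three introns and
PIP2s two among the "two or three" stated for PIPs; the named exceptions
are exact).

## Problem sizes and verification

The test suite verifies, among others: exact recovery of all planted
signature strings at 15% divergence and 100% subfamily/group classification
at 15% (≥ 95% at 25%), on 250 records (50 per subfamily, fixed seed);
equality of the SDP matcher with a brute-force Cartesian-product oracle on
every table component; alignment scores against an independent affine-gap
DP oracle on short peptides; pI against a 0.001-step grid-scan oracle; and
exact recovery of planted expression counts over 100 seeds of an 88-gene,
3-condition, 3-replicate world. `scripts/acceptance.R` recomputes these
quantities from scratch with a caller-supplied seed.

## Known limitations

* Genome-wide identification itself (BLAST screening of assemblies) is out
  of scope; the screen operates on user-supplied FASTA.
* The published organ expression counts (73/75/71 expressed, 68 ubiquitous;
  53 in BY-2 cells) derive from external RNA-seq datasets and are not
  reproducible from bundled data; the package reproduces the calling rule
  and verifies it on synthetic worlds instead.
* Subcellular localization is carried as inventory annotation only.
* The packaged references are synthetic templates; per-isoform signature
  values for real tobacco proteins require the user to supply the actual
  sequences.
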