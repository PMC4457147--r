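---
title: "Models and methods behind defensescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind defensescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defensescan)
library(dplyr)
```

defensescan analyses the three genome-defense layers of a fungal genome —
repeat-induced point mutation (RIP), cytosine methylation, and small-RNA
mediated silencing — and integrates them into a per-transposable-element
(TE) silencing classification.  This vignette is the package's own account
of the models it implements, the parameters that matter, and the choices
made where the design was genuinely open.

## RIP detection

RIP converts cytosines to thymines in duplicated sequence during the
sexual cycle, leaving a strand-symmetric C:G→T:A excess in repeat
families.  Detection is alignment-based: the copies of a family are
aligned, an ancestral (pre-RIP) state is inferred per column, and every
copy that carries T where the ancestor had C (or A where it had G — the
same event on the other strand) is one RIP event.

**Pre-RIP model.**  The default ancestral state is the per-column
majority base with ties broken toward C/G over T/A.  The tie-break
encodes the direction of the process: RIP only ever moves C→T, so when a
column is evenly split the GC-richer state is the ancestral one.  A gap
is emitted only on a strict gap majority.  As an alternative,
`build_consensus(model = "highest-gc")` uses the copy with the highest
ungapped GC fraction as the reference — useful when one copy has escaped
RIP while the rest decayed.

**Family inclusion.**  Only copies at least 400 bp long are used, and a
family is analysed only when its mean pairwise identity is at least 0.80
(`extract_repeat_families()`).  Copies are read 5'→3' on their own
strand, so RIP on a minus-strand copy is evaluated in the orientation it
occurred in.

**Per-event counting.**  A column in which three copies carry the derived
T yields three events, and `mutation_spectrum()` classifies *every*
consensus-versus-copy substitution (not only RIP-like ones) into the six
strand-symmetric classes.  This per-mutation-event convention matches how
spectra are usually tabulated; a per-variant-column variant would simply
deduplicate events per column and is easy to derive from the site table.

**Aligner.**  Copies of equal length (no indels) pass through unchanged;
otherwise a center-star progressive alignment is built from
`Biostrings::pairwiseAlignment()` runs against the longest copy
(match +1, mismatch −1, gap open −5, gap extend −1).  On families at the
≥ 80 % identity floor the called sites are insensitive to the exact
aligner; pre-aligned input is accepted to bypass it entirely.

## RIP indices and the composite RIP index

For a sequence window, with `f(XpY)` the overlapping dinucleotide count:

* product index = `f(TpA) / f(ApT)` — accumulates as RIP deposits TpA;
* substrate index = `(f(CpA) + f(TpG)) / (f(ApC) + f(GpT))` — decays as
  RIP consumes its preferred substrate;
* CRI = product − substrate.

A zero denominator leaves the corresponding index — and hence the CRI —
undefined (`NA`).  No pseudocounts are added: inventing counts would
fabricate signal in low-complexity windows, and downstream consumers
(window tracks, region detection) treat `NA` as "no evidence".

One property worth knowing: the CRI is tuned to *TpA-generating* RIP.
When RIP prefers CpA, each event adds product (TpA) and removes substrate
(CpA), so CRI rises monotonically with dose.  When RIP prefers CpG — as
in this genome's regime — each event creates TpG, which *inflates* the
substrate numerator, and the window CRI can fall with dose.  The
dosage-monotonicity property test therefore runs under CpA-preferring
weights, where the index's response is well defined; on CpG-preferring
data the CRI remains a useful enrichment flag (RIP'd repeats still sit
above background) but not a dose meter.

Window tracks (`windowed_tracks()`) use 500 bp windows advancing by
100 bp by default, the classic moving-window scan; a truncated tail
window is available behind a flag and off by default so that all windows
are directly comparable.

## Methylome scoring

Contexts follow the standard CpG / CHG / CHH classification (H = A, C or
T), always re-derived from the genome on the cytosine's own strand.
Cytosines within 2 bp of the strand's 3' chromosome end that cannot be
fully classified are reported CHH and flagged `context_truncated`.

A cytosine is *methylated* iff coverage ≥ `min_cov` (default 4) and
methylated fraction ≥ `min_frac` (default 0.5), both inclusive.  These
are explicit configuration: published site counts rarely state their
calling rule, so the rule here is visible and changeable rather than
inferred.

Feature-level methylation is a site count per kilobase
(`feature_methylation()`), strand-agnostic, with TE / gene / exon /
intron types aggregated by `feature_methylation_summary()`.  Two
CpG-related summaries deliberately differ: for per-kb levels the two
strands of a symmetric CpG are two sites, while
`cpg_site_methylation_fraction()` counts each CpG *dinucleotide* once,
methylated if either strand carries a call — they answer different
questions (how much methylation per bp, versus what fraction of CpG
positions is touched).

## Small-RNA loci

Strand-specific alignments (BED6; name = read id, score = collapsed copy
count) are merged into candidate loci when reads on either strand lie
within `max_gap = 50` bp of each other.  Candidates must reach
`min_density` reads/kb over the merged interval — 60 for the disiRNA
screen, with milRNA candidates re-thresholded at > 270 — and carry at
least `min_reads = 10` (weighted) reads.  The read floor exists because a
pure density threshold is scale-free: two chance-overlapping background
reads span ~30 bp and already exceed 60 reads/kb, so some minimum
support is needed for "locus" to mean anything.  Multi-mapped reads
contribute 1/hits each by default (`multimap = "fractional"`), keeping
repeat-derived loci visible without double-counting; `"all"` and
`"unique"` are available.

milRNA classification applies four criteria in order: (1) strand bias
≥ 10-fold (an empty minority strand counts as infinite bias, i.e.
passes); (2) density > 270 reads/kb; (3 — evaluated last) the mature
candidate lies on the hairpin stem; (4) precursor MFE ≤ −20 kcal/mol and
MFEI > 0.8.  The precursor is the locus extended by `flank = 80` bp on
each side on the dominant strand; the flank length is a package default
(structure callers need enough context to close the hairpin, and 80 bp
accommodates arms around a 40–100 bp mature region).  The mature
candidate is the most abundant 18–25 nt read in the locus, and
"on the stem" means every mature base is paired or sits in unpaired
interruptions of ≤ 2 nt.

The MFEI is the standard index from the miRNA-prediction literature:
`MFEI = (|MFE| / precursor length × 100) / GC%`.

disiRNA loci require similar abundance from both strands and density
≥ 60 reads/kb.  "Similar" is qualitative in the literature; it is
operationalised as strand ratio ≤ `balance_max = 2`, exposed as
configuration.  A locus already classified milRNA is never re-labelled.

**Folding backend.**  `fold_rna()` defaults to a bundled
stacking-weighted maximum-pairing model (Rcpp): pair weights −2.0 (GC),
−1.1 (AU), −0.6 (GU) kcal/mol, −1.0 per stacked pair, minimum loop 3 nt.
It is not a nearest-neighbour thermodynamic model: it over-pairs random
sequence relative to ViennaRNA and its absolute energies are calibrated,
not measured — genuine inverted repeats (arms ≥ ~20 nt at ≥ 80 %
complementarity) score well below −20 kcal/mol while short or sparse
complementarity does not.  Its virtues are determinism and zero external
dependencies, which is why it is the default and the backend all
energy-dependent tests run against; `backend = "rnafold"` uses `RNAfold`
when present for thermodynamically meaningful energies.

## Integration

A TE is *RIP-affected* with ≥ 1 called RIP site in its interval and
*methylated* with ≥ 1 methylated cytosine (`min_rip`, `min_mc`
configurable; no per-TE minimum is standard, so the floor of one keeps
the flags interpretable as "any evidence").  Expression requires ≥ 1
read surviving the filters: ≤ 2 mismatches and a unique genomic hit.
Mate-pair concordance is an alignment-time property not representable in
BED6+2 and is assumed enforced upstream.

`crosstab()` reproduces the classic silencing table: evidence sets
{Total, RIP, Non-RIP, 5mC, Non-5mC, RIP & 5mC, Non-RIP & non-5mC} ×
expression status, with cells as percentages of the grand total.
Percentages are held at full precision internally — so the partition
identities (RIP + Non-RIP = Total, cell-wise) are exact — and rounded
half-up to two decimals only at formatting time.

`detect_defense_regions()` flags windows satisfying all four hallmarks
(low GC, CRI ≥ `cri_min`, RIP-site and methylated-cytosine enrichment)
and merges runs of ≥ `min_windows = 5` qualifying windows.  The default
thresholds are declared data-derived conventions: GC ≤ mean − 1 SD of
window GC, CRI ≥ 0, counts ≥ the 90th percentile of nonzero window
counts.  A caveat at small scale: on a desk-sized synthetic genome where
one planted cluster contains a large share of all RIP, the cluster
itself supplies the upper percentiles, and the self-referential default
under-calls it.  The recovery scenario in the test-suite therefore
declares explicit thresholds (GC ≤ 0.5, CRI ≥ 0, ≥ 5 RIP sites and ≥ 8
methylated cytosines per window) as part of the scenario; on a
genome-sized input, where candidate regions are a vanishing fraction of
windows, the percentile defaults behave as intended.

## The synthetic-data generator

`generate_genome()` plus `simulate_methylome()`, `simulate_smrna()` and
`simulate_rnaseq()` produce a genome in which every downstream answer is
known.  Its defaults are the study conditions under which the analyses
are exercised:

| parameter | default | what it encodes |
|---|---|---|
| `gc_background` | 0.55 | GC-rich fungal genome background |
| family `unit_length` / `target_identity` | ≥ 400 bp / ≥ 0.80 | the repeat inclusion rule |
| `rip_rate` | 0.10 | per-site C→T probability at the preferred context |
| `rip_context_weights` | CpG 0.55, CpA 0.25, CpC 0.10, CpT 0.10 | CpG-preferring RIP with CpA second |
| `meth_rate_te` | 0.09 | ≈ ⅓ of TE CpG dinucleotides methylated |
| `meth_rate_genic` | 0.008 | sets the genome-wide mC rate near 1.8 % at ~12 % TE content |
| `meth_context_weights` | CpG 0.987, CHG 0.008, CHH 0.005 | CpG-dominated methylome |
| `bs_coverage` / `bs_meth_level` / `bs_error` | 30 / 0.95 / 0.005 | deep bisulfite libraries, small failed-conversion rate |
| milRNA locus | 40 bp window, 60:1 strand bias, hairpin arms 60 nt | strand-biased hairpin pileup |
| disiRNA locus | 400 bp, 45:40 reads | strand-balanced double-stranded locus |
| `background_read_rate` | 2 reads/kb | uniform small-RNA background |

Mechanically: the background genome is drawn i.i.d. per base (no
higher-order composition — sufficient for window statistics, not for
motif work); repeat copies diverge from a common ancestor by random
substitutions to the target identity, then `apply_rip()` mutates
eligible sites at `rip_rate × w(context)/max(w)`; CpG methylation is
planted symmetrically (both strands of a dinucleotide together, as
maintenance methyltransferases work); milRNA hairpins are inverted
repeats whose arms are redrawn until the bundled folder scores the
precursor ≤ −20 kcal/mol.

One deliberate constraint: `apply_rip()` caps the number of mutated
copies per alignment column at ⌊n/2⌋.  Without it, a column can lose its
ancestral C in a majority of copies, after which *no* alignment method
could recover the planted state — the truth would be unidentifiable, not
merely hard.  The cap keeps "the called sites equal the planted sites"
a meaningful exactness test.  Per-copy site counts remain binomial to
within the tested 3σ bands at the rates used (≤ 0.3).

What the generator does **not** emulate: indels and nested/truncated
repeat copies, sequencing error and quality scores, PCR duplicates,
diploidy, transcription-coupled methylation patterns, and expression
levels beyond a binary planted flag.  Passing recovery tests therefore
demonstrate correctness of the inference logic under clean conditions,
not robustness to alignment artefacts in real libraries.

## Numerical and interface choices

* Internal coordinates are 1-based inclusive throughout — the
  R/Bioconductor convention shared by GFF3, `IRanges` and `Biostrings` —
  with BED (0-based half-open) and CX positions converted only at the
  I/O boundary.  Conversions are involutive (read→write→read identity).
* All randomness flows through explicit seeds; a configuration
  (including its seed) reproduces every output byte-for-byte, and the
  GFF3 writer strips the volatile `##date` header for that reason.
* Degenerate inputs return typed empties or `NA` rather than zero-filled
  placeholders: empty spectra have undefined fractions, regions without
  CpG an undefined methylation fraction, windows with zero denominators
  an undefined CRI.
* Reported percentages round half-up (not half-even) to 2 decimals,
  the convention under which published partition percentages reproduce
  exactly.

## Problem sizes

The test-suite exercises recovery at sizes chosen to finish in minutes
while leaving 3σ statistics meaningful: 20-seed suites for RIP-site
exactness and locus calling, a 500 kb genome for methylome rate
recovery, 1,000 random 500-mers for the index oracle, and a 200 kb
two-chromosome fixture (`inst/extdata/demo-config.yaml`) for the
byte-reproducible end-to-end run.

## Known limitations

* The bundled folder's energies are calibrated, not thermodynamic; MFEI
  values from it should be compared against its own −20/0.8 thresholds,
  not against ViennaRNA outputs.
* `scan_loci()` merges across strands before classification, so a
  milRNA locus inside a larger double-stranded transcription unit can be
  absorbed into a balanced locus.
* Defense-region defaults are enrichment conventions; biological
  interpretation of a region still requires inspecting its tracks.
* The RIP caller presumes substitutions-only divergence within a family;
  heavily indel-fragmented families should be pre-aligned with a
  dedicated MSA tool and supplied as gapped input.
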