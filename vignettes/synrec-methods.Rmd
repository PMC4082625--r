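---
title: "Methods: synteny blocks, breakpoint regions and recombination in synrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny blocks, breakpoint regions and recombination in synrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synrec)
library(dplyr)
```

synrec re-implements, as a tested pipeline over plain tables, a
comparative-genomics workflow for primate-scale genome pairs: detect
homologous synteny blocks (HSBs) and the evolutionary breakpoint regions
(EBRs) between them from orthologous gene coordinates, filter and classify
the underlying rearrangements, relate breakpoint regions to tandem-repeat and
gene-density landscapes, test for functional-term enrichment near breakpoints
and inside inversions, and quantify how inversions reshape meiotic
recombination measured as MLH1 foci on synaptonemal complexes (SCs). Because
the original inputs (public ortholog downloads, spermatocyte image
measurements) are out of scope, a first-class synthetic-data module generates
every input with known ground truth.

All genomic coordinates are 0-based half-open internally (BED semantics);
`to_report_coords()` converts to 1-based inclusive for human-readable tables.

## Synteny blocks and breakpoint regions

`detect_hsbs()` chains markers sorted by reference coordinate. A block grows
while the next marker keeps the chromosome pair, continues the block's
monotone target order, keeps the strand relation, and stays within
`max_marker_gap_bp` of its predecessor on both genomes. The orientation of a
block is fixed by its first two markers (`same`: target ascending, strands
equal; `inverted`: descending, strands opposite); a contradiction closes the
block. Markers carrying NA target coordinates — reference genes with no
target ortholog, the encoding used for deleted sequence — close the open
chain, which is what makes small insertions/deletions visible to a
marker-order detector at all.

Defaults are declared, not inferred: `min_markers = 2` (a single out-of-order
marker cannot found a block) and `max_marker_gap_bp = 4` Mbp, deliberately
aligned with the gap rule below so one knob carries one semantic. Singleton
markers interrupting a chain are not tolerated (strict chaining); an optional
pre-filter drops isolated strand-discordant singletons for noisy tables.

`derive_ebrs()` emits the interval between consecutive blocks per
chromosome. Candidates larger than 4 Mbp are labelled `gap` and excluded —
at that size the signal is assembly discontinuity, not a breakpoint.
Intervals between a chromosome end and the outermost blocks are terminal
segments, not EBRs. `narrow_ebrs()` tightens bounds to the innermost
flanking markers and never widens (for chain-derived EBRs this is a fixed
point; it matters for externally supplied or merged sets). The sequence-level
breakpoint refinement performed by alignment-based tools is explicitly not
reproduced: narrowing here is marker-bounded only.

`dual_reference_run()` runs detect–derive–narrow twice, once per genome as
reference, so each genome's EBR coordinates are native. `merge_ebr_sets()`
reconciles two detector profiles; overlapping calls become one record whose
bounds are the **intersection** (the narrower consensus — the reconciliation
rule is a design choice here, with union available via `rule = "union"`).
Masks from `build_region_masks()` label the 2 Mbp at each chromosome end
telomeric and the 2 Mbp flanking every N-run centromeric; any overlap with a
mask (or `gap` status) excludes an EBR, a deliberately conservative rule.

`classify_rearrangements()` types each retained EBR through its flanking
blocks: opposite orientations on one target chromosome give an inversion
(the two EBRs bounding the inverted block are grouped, the inverted span is
the rearranged region); a chromosome-pair switch gives fusion/fission when
genome-wide chromosome counts differ (polarized with the pipeline reference
treated as ancestral) or translocation otherwise; same pair and orientation
with a target-side gap at most half the reference-side gap gives an indel
(the target gap is ordinary intergenic distance when sequence was deleted —
the 0.5 ratio is a declared tie-break, robust for deletions a few times
larger than marker spacing); anything else is complex. Rearranged regions
larger than 1.4 Mbp are macro-rearrangements, the rest micro; exactly
1.4 Mbp goes to micro because the published convention is strict on both
sides.

## Tandem repeats and window landscapes

`find_tandem_repeats()` reports perfect tandem repeats with unit sizes
2–100 bp and at least two complete copies, trimmed so that span = period x
copies. Mismatch-tolerant repeats are a documented limitation: the classical
scanners accept mismatches under a score threshold that the workflow being
reproduced does not state, so exact matching is the deterministic choice.
Homopolymers are reported at the smallest admissible period; overlapping
calls across periods resolve to the longest span, then the smallest period,
then the leftmost start; the motif is the lexicographically least rotation.
The scanner is validated against a brute-force oracle — exhaustively on all
binary strings up to length 10 and on randomized strings up to 30 bp —
rather than on spot examples.

`window_scan()` tiles chromosomes into non-overlapping 100-Kbp windows (the
trailing short window is kept and length-normalized via `tr_bp_norm`),
accumulating repeat bp clipped to the window and gene counts by any-overlap
(a boundary-spanning gene counts in both windows: presence/absence, not
base-pair coverage). `label_windows()` assigns one label per window with
precedence telomere > centromere > EBR > HSB. `compare_window_groups()` uses
the Kruskal–Wallis test for more than two labels and the Mann–Whitney U for
two, through the base R implementations.

## Enrichment statistics

`ease_pvalue()` implements the conservative one-sided Fisher variant: one
term-positive gene is removed from the foreground, giving the upper-tail
hypergeometric probability P[X ≥ k−1] for n−1 draws from N genes of which K
carry the term; k = 0 gives 1. It always bounds the exact Fisher p from
above, and it is checked against direct hypergeometric summation on an
exhaustive grid of all margins with N ≤ 25 plus larger margins to N = 200.
`cluster_terms()` greedily agglomerates individually significant terms
(EASE p ≤ 0.05) when Cohen's kappa over the foreground universe reaches 0.35
with at least half of a cluster's members — both thresholds follow the
established annotation-clustering tool's defaults, since the workflow being
reproduced does not state them — keeps clusters with 10–3000 member genes,
and scores each cluster as −log10 of the geometric mean of member EASE
p-values, flagging scores ≥ 1.5. The score threshold is only coherent on the
−log10 scale, which is therefore the scale used. No multiple-testing
correction is applied beyond these thresholds, matching the workflow.
Degenerate kappa tables follow a documented convention: identical
memberships give 1, a vanishing chance-corrected denominator gives 0.

## Recombination statistics

Every SC is a row: length (μm), centromere position, sorted MLH1 focus
positions, named BAC-marker positions. `relative_positions()` returns two
conventions side by side — signed percent of total SC length from the
centromere (used for the 10% binning and cumulative maps, matching the
percentage-of-SC convention) and signed percent of the containing arm
(q-telomere = +100). A focus exactly at the centromere goes to the q arm.

`co_density()` pools foci over cells: Σ foci in the region / Σ region
lengths, with per-cell densities retained for the rank tests (both
aggregations are reported because the source workflow is silent on which it
used). Intervals are closed on the left, open on the right, so inside +
outside decompose the whole SC exactly — a conservation identity asserted in
the tests. `delimit_inversion()` resolves a region from the centromere
and/or BAC markers per cell, excluding cells with a missing marker listwise
from inversion estimates only. `simulated_inversion_control()` maps a
proportional span onto a collinear chromosome's SCs — the control isolating
positional effects (e.g. centromeric suppression) from inversion effects.
`pericentromeric_density()` covers the region extending 30% of each arm from
the centromere. `genetic_length()` converts the mean total foci per cell at
50 map units per crossover. One MLH1 focus = one crossover throughout.

## The synthetic-data generator

The generator defines the study conditions; its defaults are not tuned.

**Genome pairs.** `simulate_genome_pair()` builds an ancestral genome
(default two 30-Mbp chromosomes, 400 genes placed uniformly or in clusters,
a 500-Kbp centromeric N-run at 40% of each chromosome so the masking stage
has real signal) and applies a script of inversions, indels, fissions,
fusions and translocations expressed in ancestral coordinates. Derived
chromosomes are ordered lists of oriented ancestral segments, so coordinates
and strands propagate exactly through any event composition; genes split by
a breakpoint or deleted carry NA target coordinates. Ground-truth EBRs are
recorded in both genomes as the interval between the innermost retained
orthologs flanking each breakpoint — the resolution limit of any
marker-based detector, which is why detector recovery can be asserted
exactly. Overlapping events are rejected rather than reordered.

**Window landscapes.** `simulate_window_landscape()` draws per-window repeat
bp (negative binomial, dispersion 5, clipped to the window) and gene counts
(Poisson) at label-specific rates. Default gene rates plant 1.48 genes per
100-Kbp window in EBRs against 0.73 in HSBs — the gene-density regime the
pipeline is meant to detect — and repeat rates elevate telomeric/centromeric
windows (5000/6000 bp per window) over HSB/EBR windows (1500/1600 bp),
with EBR ≈ HSB so that the repeat comparison is null, matching the
qualitative landscape the analysis operates in.

**Annotations.** `simulate_annotations()` assigns uniform background terms
and planted terms whose members are sampled with weight `fold` for genes
inside a chosen region; fold 1 is exactly the null.

**Meiosis.** `simulate_meiotic_cells()` draws per-SC crossover counts from a
Poisson whose rate is calibrated by root-finding so the *delivered* mean
equals `per_sc_expected_co` — under the obligate crossover the count is
zero-truncated, and naively using the target mean as the rate would inflate
the delivered mean by the truncation. Positions are sampled uniformly
subject to a hard-core minimum spacing (default 20% of SC length) using the
exact order-statistics construction on the slack interval, which avoids the
positional bias a forced-insertion scheme would introduce; suppression
intervals thin both the count (by the lost intensity mass) and the positions
(whole-configuration accept/reject against the suppression weights).
Interference is a hard-core spacing rather than a gamma renewal process
because it is the simplest mechanism reproducing the observed at-most-three
crossovers on large bivalents; the spacing is a free parameter, not an
inferred one, since the source data do not report interference strength.
`meiosis_config_study()` encodes the reference regime: 258 cells, 20
autosomal bivalents with lengths declining 18 to 5 μm and expectations
increasing linearly in length (floor 1.1) to total 35.24 foci per cell.

What the generator does **not** emulate: nucleotide substitution,
segmental duplications, assembly errors, measurement noise on SC lengths,
inter-cell correlation of crossover counts, and the empirical overdispersion
of real foci counts (the simulated per-cell SD is Poisson-like). Passing
tests therefore demonstrate correctness of the algorithms under a clean
generative model, not robustness to the artefacts of real assemblies or
image measurements.

## Numerical choices and degenerate inputs

* Interval ties: any-overlap (≥ 1 bp) triggers masking, labelling and
  merging; zero-width touching does not, under half-open coordinates.
* A focus on a region boundary counts inside (closed-left).
* The hard-core interference interacts with suppression avoidance: with
  interference on, density inside a large central suppressed interval sits
  slightly above `suppression_factor` times the outside density (packing
  forces mass inward). The consistency property (inside/outside ratio →
  factor) is exact for the pure thinned process and is tested with
  interference off.
* One global seed; subsystem seeds derive by fixed offsets
  (reproducible partial reruns), all below 2^31.
* Empty inputs return empty tibbles; invalid configurations abort with
  informative messages (overlapping events, out-of-bounds intervals,
  suppression factors outside [0, 1], empty comparison groups are all
  rejected, never silently repaired).

## Problem sizes used in the tests

Simulations are sized for a single CPU: oracle equivalence runs on ≤ 10
markers, strings ≤ 30 bp, and EASE margins ≤ 200; recovery and
classification use 400–900 genes on 30–60 Mbp chromosomes over several
seeds; power and calibration loops use 40–200 replicate seeds at the
reference cell counts (85–87 cells for suppression, 258 for calibration).
These sizes give binomial standard errors comfortably inside the asserted
margins while keeping the default suite fast.

## Worked example

```{r example, eval = FALSE}
cfg <- genome_config(
  n_chromosomes = 2, chrom_length_bp = c(60e6, 40e6), n_genes = 900,
  rearrangements = dplyr::bind_rows(
    rearrangement("inversion", "chrA1", 10e6, 14e6),
    rearrangement("inversion", "chrA2", 8e6, 8.8e6)),
  seed = 51)
mei <- meiosis_config_study(seed = 51)
out <- run_pipeline(cfg, mei)
summarise_ebrs(out$ebrs)
out$classified
genetic_length(out$cells)
```

## Known limitations

Exact-match tandem repeats only; marker-resolution breakpoints (no sequence
alignment refinement); fusion/fission polarity requires treating the
reference genome as ancestral; enrichment results depend on the supplied
annotation table, not on any hosted ontology; recombination statistics assume
one focus = one crossover and ignore sex-chromosome bivalents.
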