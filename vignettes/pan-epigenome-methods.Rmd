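---
title: "Methods: mapping bacterial methylomes onto motifs, regions and replicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping bacterial methylomes onto motifs, regions and replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panepi)
```

## The problem

Single-molecule sequencing calls base modifications (N6-methyladenine,
N4-methylcytosine, C5-methylcytosine) per base and per strand. Methylation in
bacteria is deposited by methyltransferases (MTases) at short, often
degenerate recognition motifs, and across a panel of strains of one species
the *set* of methylated motifs varies: some motifs are methylated in every
strain (a core epigenome, typically deposited by conserved MTases such as
the cell-cycle regulator CcrM at GANTC), others only in a subset (a shell
epigenome, tracking mobile or strain-specific MTases and
restriction–modification systems). `panepi` turns per-base modification
calls, genome sequences and gene annotations for a multi-strain,
multi-replicon panel into:

1. motif occurrence sets on both strands (IUPAC-degenerate, exhaustive
   naive matching);
2. methylated/unmethylated flags per occurrence, by exact position, strand
   and modification-type matching against the calls;
3. a strand-aware partition of every replicon into CDS, nCDS, tIG and US
   region classes, and the region class of each occurrence's modified base;
4. methylation frequencies per strain × motif × region × replicon class,
   the core/shell classification, and the comparative statistics: NRMSD,
   PCA variable contributions, Kruskal–Wallis + Dunn tests, complete-linkage
   dendrograms with cophenetic correlations, and donor × recipient
   log10 fold changes of plasmid-transfer ratios.

## Coordinates, scanning and assignment

All coordinates are 1-based inclusive (GFF3-native) everywhere in the
package; the single exception is BED export, which is 0-based half-open as
the format requires. Keeping one convention end to end avoids off-by-one
drift between the three GFF3/FASTA inputs and the TSV outputs.

Motif scanning is exhaustive: every window matching the IUPAC pattern on the
plus strand yields a `+` occurrence and every window whose reverse
complement matches yields a `-` occurrence reported at its leftmost
plus-strand coordinate. Overlapping occurrences are all retained (no greedy
masking), and palindromic motifs yield paired `+`/`-` occurrences at the
same start — two methylatable sites per locus, matching the strand-specific
nature of the calls. `N` in the genome never matches any motif position,
including `N` in the motif: unsequenced gap characters should not inflate
occurrence totals. Internally a window matches when the 4-bit base sets of
motif and sequence intersect at every position, which the tests verify
against a brute-force oracle that expands each motif into all concrete
words.

An occurrence is flagged methylated when a call exists with the same
replicon, strand, *exact* modified-base position and a compatible
modification type. Generic `modified_base` calls (present in some
base-modification GFF3 dialects) are accepted for any motif type by default
(`allow_generic`); strict typing is a flag. A single call can flag several
overlapping occurrences — distinct motifs of the same modification type can
frame the same methylated base, and position matching cannot (and should
not) disambiguate them.

### Modified-base offsets

Published motif tables rarely print which base in the motif carries the
mark. The packaged table (`sm_motifs()`) therefore curates the offsets: the
canonical base where established (the A of GANTC; the GATC-context adenine
in CGATCG and RGATCY), and otherwise a compatible position chosen so that
distinct same-type motifs never share a modified genome position in any
sequence context. Two exceptions are unavoidable: every A-compatible choice
for ACGGAG and CTCGAG shares its adenine with a GANTC context (ACGGAGTC,
CTCGAGTC). Both motifs are core, like GANTC itself, so the overlap cannot
change a core/shell label; its effect on frequencies is modeled exactly in
the synthetic ground truth (below). If a motif file omits the offset, the
first compatible base is used with a warning.

### Collapsing motif lists

Motif-prediction software often reports a core recognition sequence plus
extended variants. `collapse_motifs()` maps motif A onto motif B when B (or
its reverse complement) occurs as a contiguous sub-motif of A, with each of
A's IUPAC sets a subset of B's aligned set and the modified base aligned
(through the mirror position in the reverse-complement orientation). The
shorter, more general motif is retained, mappings resolve transitively, and
pairs that would collapse but disagree on modification type are both kept
with a warning. This subset-containment rule is one defensible
formalization of "shared core sequence" collapsing; it is deliberately
conservative (exact containment, no mismatches).

## The four region classes

Per strand, every position of a replicon belongs to exactly one class:

* **CDS** — inside an annotated gene on the accordant strand;
* **nCDS** — inside a gene on the discordant strand (antisense);
* **US** — within `us_length` bp upstream (5′, strand-aware) of a gene
  start on the accordant strand;
* **tIG** — true intergenic: everything else.

Precedence CDS > nCDS > US > tIG is applied per strand, so a base inside a
gene is never US even when it also lies upstream of a neighbor; this makes
the four classes a true partition, which the downstream frequency
statistics require (region totals must sum to the genome-wide total). The
nCDS definition — antisense within a gene — is a design decision: with CDS
and US defined strand-accordantly and tIG as between-gene space, the
antisense gene body is the only remaining positional class in a
four-class scheme. `us_length` defaults to 300 bp, a conventional bacterial
promoter-proximal window; it is configurable, and US windows truncate at
replicon boundaries unless the replicon is declared circular. Replicons are
linear by default because draft assemblies are contigs; circularity is
metadata the user must assert.

## Frequencies and the core/shell classification

The methylation frequency of a motif in a group is the number of times it
was found methylated over the total number of times it was found there.
Groups with zero occurrences are reported as missing, never as frequency 0
— absence of the motif is not evidence of absent methylation. A motif
counts as *present* in a strain when it has at least one methylated
occurrence genome-wide (a minimum-frequency threshold is available, because
very low frequencies — 0.02 in the packaged table — still count as
presence). A motif methylated in every strain is **core**, in exactly one
**exclusive**, otherwise **shell**; motifs methylated nowhere are labeled
absent and excluded from those counts.

## Comparative statistics

**NRMSD.** Strain-to-strain variability of a motif's frequency in a region
is summarized as `sqrt(mean((x - mean(x))^2)) / mean(x)` — the
coefficient-of-variation form. The normalizer is a design choice the source
statistic leaves open; mean-normalization keeps a high-frequency,
low-spread motif (GANTC) near zero while distinguishing magnitudes, which
range-normalization would not. Range-normalization is available as a
config alternative, and the choice is recorded in the output metadata.
NRMSD of a constant vector is 0; a zero mean with spread is undefined
(missing). Heatmap-style matrices can be z-scored row-wise (per motif) or
column-wise (per region) with `scale_matrix()`; zero-variance rows map to
zeros with a warning rather than NaN.

**PCA.** `pca_contributions()` decomposes the strain × region frequency
matrix (centered and scaled by default, since frequencies differ in
magnitude across motifs) and reports the percentage contribution of each
variable to each component, `100 · loading² / Σ loadings²`, summing to 100
per PC. Missing cells are imputed to column means, with a message.

**Dunn's test.** Group differences in frequency across regions or replicon
classes are tested with Kruskal–Wallis followed by Dunn's pairwise z with
tie correction `T = Σ(t³ − t)/(12(N−1))`, two-sided normal p-values and
Holm adjustment by default (Bonferroni/BH selectable — the adjustment is
not dictated by the source description). The rank-based pair is used
because Dunn's statistic is defined on the joint ranking; a classical ANOVA
on the same layout is available through base R if wanted. The significance
flag in the output tables is `p_adjusted < 0.001`, the threshold used for
replicon comparisons in this literature.

**Clustering and cophenetic correlation.** Strains are clustered on
frequency or presence/absence profiles by Euclidean distance and complete
linkage (`stats::hclust`); leaves are label-sorted before agglomeration so
exact ties break deterministically toward the smallest labels (tie order
changes dendrogram shape, and reference implementations leave it opaque).
The cophenetic distance of two leaves is the height of their lowest common
merge; agreement between two trees is the Pearson correlation of their
aligned upper-triangle cophenetic vectors (Spearman behind a flag). A
precomputed phylogeny in Newick format can stand in for one of the trees
via its patristic distances — tree building itself is out of scope.

**Transfer fold changes.** For a donor × recipient table of plasmid
acquisition ratios, `log10_fold_change()` reports
`log10(ratio(d, r) / ratio(r, r))`; the diagonal is 0, a zero nonself ratio
(no transformants) is −Inf and serialized as the literal token `"-Inf"`,
and the result is invariant to rescaling all ratios of a recipient by a
common factor. Ratios are taken as given; no variance model is fitted
because only point values are reported upstream.

## The synthetic panel generator

`generate_panel()` emits a complete panel — FASTA, annotation GFF3,
methylation GFF3, replicon-class manifest, motif table — plus a ground
truth of every occurrence with its true region and flag. It emulates the
structure of a 21-strain panel of a multipartite-genome alphaproteobacterium
at desk scale:

* three replicon classes per strain — chromosome 100 kb, chromid (pSymB)
  50 kb, megaplasmid (pSymA) 40 kb, roughly 35× smaller than the real
  replicons — and an extra 15 kb plasmid on every third strain (3–4
  replicons per strain);
* i.i.d. background sequence, uniform base composition by default with a GC
  knob (GC-rich genomes change motif densities);
* non-overlapping genes of 300–900 bp separated by 200–700 bp gaps on
  random strands, so all four region classes are well populated;
* a presence design: 10 core motifs active in all strains, 6 shell motifs
  in nested leading subsets of 2–19 strains (the shell occupancy range
  reported for the real panel); nesting gives the shell epigenome a planted
  strain structure that clustering should recover;
* Bernoulli methylation per occurrence, independent across occurrences,
  with probabilities that differ by motif (GANTC flat at 0.99; other
  baselines spread over 0.3–0.9), by region (regulatory windows slightly
  above antisense gene bodies) and by replicon class (plasmids markedly
  hypomethylated) — so region- and replicon-wise contrasts exist by
  construction;
* guaranteed statistical power: at least `n_min` occurrences (default 8)
  of every motif are planted into every region class of every replicon,
  by writing a random concrete expansion of the motif into a free segment
  of the right class and strand.

Because same-type motifs can frame the same methylated base, the ground
truth records for each occurrence the exact probability that it ends up
flagged: `1 − Π(1 − p)` over all co-located occurrences.
`expected_frequency()` aggregates these into the exact expectation and
standard deviation of any group frequency (occurrences sharing a site are
perfectly correlated, distinct sites independent), so recovery tests can
use honest 99% intervals instead of a naive binomial that ignores the
overlap.

Everything is deterministic given the seed (byte-identical reruns; the
global RNG state is restored on exit). What the generator does *not*
emulate: kinetic signal strength and coverage (calls are exact), sequence
evolution along the planted tree (backgrounds are independent across
strains), operon structure, and spatially correlated methylation. Passing
recovery tests therefore validate the bookkeeping and the statistics — not
robustness to noisy, partially detected calls in real data.

## Problem sizes and numerical choices

The shipped tests exercise: oracle-equivalent scanning on 100 random
sequences up to 5 kb for all 16 curated motifs; the region partition on
1,000 random gene layouts including nested and overlapping genes; a full
21-strain panel (≈4.4 Mb of sequence, ≈700k occurrences) for frequency and
label recovery; 10,000 null simulations for the Dunn type-I error
(0.05 ± 0.01 at α = 0.05); and exact recovery of planted transfer fold
changes including −Inf cells. These sizes keep the whole suite around two
minutes on one CPU while leaving each check statistically meaningful.

Numerical conventions worth knowing: frequencies of empty groups are NA,
never 0; `nrmsd` errors on vectors shorter than 2 and returns NA for a
zero mean; Dunn's z is 0 (p = 1) when the pooled variance collapses under
total ties; cophenetic correlation of trees with fewer than 3 leaves, or
with zero-variance cophenetic vectors (star trees), is NA with a warning;
PCA refuses constant columns under scaling and names the offending column.

## Known limitations

* The collapse rule is exact containment; motifs related by a single
  mismatch or by partial overlap are not merged.
* The nCDS (antisense) reading of the four-class scheme is an assumption;
  alternative schemes (e.g. operon-aware upstream windows) are not
  implemented.
* Region assignment uses the annotation as given; unannotated pseudogenes
  become tIG/US.
* The transfer module computes point fold changes only — no replicate
  variance model.
* The Dunn tables test each motif separately; no cross-motif multiplicity
  correction is applied beyond the per-motif pairwise adjustment.
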