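# panepi — pan-epigenome analysis of multipartite bacterial genomes

`panepi` is an R package for comparative bacterial methylome analysis
across a panel of strains. It is aimed at microbial genomicists who have,
per strain, a (draft) genome assembly, a gene annotation, and per-base,
strand-specific DNA modification calls (6mA / 4mC / 5mC, e.g. from SMRT
kinetic analysis exported as GFF3), plus a list of recognition motifs, and
who want to know how methylation is organized **across strains, across
replicons and across genomic regions**.

## What it computes

For each strain the package scans every replicon on both strands for each
IUPAC-degenerate motif (exhaustive naive matching; overlapping occurrences
kept; `N` never matches), flags an occurrence as methylated when a call
matches its modified base exactly (same replicon, strand, position and a
compatible modification type), and assigns each occurrence's modified base
to one of four strand-aware region classes — CDS (sense gene body), nCDS
(antisense gene body), tIG (true intergenic) and US (≤ 300 bp upstream of a
gene start, strand-accordant) — with precedence CDS > nCDS > US > tIG so
the classes partition the genome.

On top of the per-strain layer it computes the comparative layer:

* **Methylation frequency** per group: `f = m / n`, methylated occurrences
  over total occurrences, at strain × motif × region × replicon-class
  granularity (empty groups are missing, never 0).
* **Pan-epigenome classification**: a motif methylated in all strains is
  *core*, in exactly one *exclusive*, otherwise *shell*.
* **NRMSD**, the strain-to-strain variability of a frequency vector:
  `NRMSD(x) = sqrt(mean((x − x̄)²)) / x̄` (coefficient-of-variation form;
  range normalization optional), with row/column z-scaling for heatmaps.
* **PCA variable contributions**: `100 · loading² / Σ loadings²` per
  component, from `prcomp` on the strain × region frequency matrix.
* **Kruskal–Wallis + Dunn's post hoc z** with tie correction
  `T = Σ(t³ − t)/(12(N−1))` and Holm-adjusted two-sided p-values, for
  region-wise and replicon-wise frequency contrasts.
* **Complete-linkage dendrograms** (Euclidean distance) of strains on
  core/shell epigenome profiles, **cophenetic distance matrices** and the
  **Pearson cophenetic correlation** between tree pairs (external Newick
  phylogenies can be compared via patristic distances).
* **Transfer fold changes**: `log10(ratio(d, r) / ratio(r, r))` for
  donor × recipient plasmid-acquisition tables, with `-Inf` marking
  zero-transformant pairs.

A seeded synthetic-panel generator (`generate_panel()`) emits the exact
input formats with planted ground truth (occurrences, regions, Bernoulli
methylation probabilities per motif × region × replicon), so the whole
pipeline is testable end to end without any downloads. A curated table of
the 16 methylated motifs observed across a 21-strain *Sinorhizobium
meliloti* panel ships in `inst/extdata/sm_motifs.tsv` (`sm_motifs()`).

## Worked example

```r
library(panepi)

## a synthetic 6-strain panel: chromosome + chromid + megaplasmid
## (+ a plasmid on every third strain), 16 motifs, planted core/shell design
cfg   <- panel_config(n_strains = 6, seed = 42)
panel <- generate_panel(cfg)          # or generate_panel(cfg, out_dir = "panel/")
res   <- analyze_panel(panel$genomes, panel$genes, panel$calls, cfg$motifs)
print(res)
#> <pan_epigenome> 6 strains, 16 motifs, 76121 occurrences
#> <pan_epigenome_classification> 16 motifs across 6 strains:
#>   core: 10  shell: 6  exclusive: 0  absent: 0
#>   No strain-exclusive methylated motif was found.
```

The classification recovers the planted design exactly: 10 motifs
methylated in every strain (core), 6 in proper subsets (shell). Genome-wide
frequencies behave like their design probabilities — GANTC, the cell-cycle
motif planted at p = 0.99 everywhere, is nearly fully methylated:

```r
subset(res$frequency, region == "ALL" & replicon_class == "ALL" &
       strain_id == "S01" & motif_label %in% c("GANTC", "RGATCY"))
#>  strain_id motif_label region replicon_class methylated total frequency
#>        S01       GANTC    ALL            ALL       1673  1686 0.9922894
#>        S01      RGATCY    ALL            ALL        477   642 0.7429907
```

Replicon-wise contrasts show the planted plasmid hypomethylation, e.g. for
TCGWCGA in strain S03 (0.84 on the chromosome vs 0.40 on the plasmid), and
the Dunn table ranks chromosome-vs-plasmid as the strongest pair
(z = 2.90); GANTC has the lowest strain-to-strain NRMSD of all motifs
(0.004), exactly as designed:

```r
res$dunn_replicon[res$dunn_replicon$motif_label == "TCGWCGA",
                  c("group_i", "group_j", "z", "p_adjusted")]
#>     group_i group_j      z p_adjusted
#>  chromosome plasmid  2.899     0.0224
#>  chromosome   pSymA  2.148     0.1587
#>  ...
round(rowMeans(res$nrmsd$region_raw, na.rm = TRUE)["GANTC"], 3)
#> GANTC
#> 0.004
```

For file-based runs, `run_pipeline("config.yaml")` reads per-strain
FASTA/GFF3 paths, a replicon-class manifest and a motif TSV, and writes the
full report bundle (occurrence dump, frequency tables, classification,
NRMSD matrices raw and scaled, PCA contributions, Dunn tables, Newick
dendrograms, cophenetic correlations, run manifest). A thin CLI wrapper
lives at `inst/cli/panepi.R` (`simulate` and `run-all` subcommands).

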