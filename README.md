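# circstress

Characterization of a plant circular RNA (circRNA) landscape under
multiple abiotic stresses, built as a reusable R package plus an analysis
workflow over synthetic data with planted ground truth.

## The problem

Back-splicing joins a downstream splice donor to an upstream acceptor,
producing covalently closed circRNAs that RNase R digestion enriches
before sequencing. Calling circRNAs from back-splice junction (BSJ)
candidates is noisy: low-credibility candidates are dominated by
intergenic junctions, and a single locus can emit several circular
isoforms. Downstream questions — which gene features favor
circularization, whether splice sites are conserved across species,
whether circRNA abundance tracks its host gene, whether circRNAs sponge
miRNAs, and what the chloroplast contributes — each need their own
statistics. `circstress` implements that whole chain for a cotton-like
multi-stress design (control, cold, heat, salt, UV-B; RNase R-treated
and control libraries):

- **Filtering** — per-library reliability-score retention (score > 0.1
  for RNase R libraries, > 0.9 for controls, strict inequalities),
  ultra-long span exclusion, intragenic/intergenic stratification,
  merging to unique circRNAs keyed by (contig, acceptor, donor, strand),
  condition-overlap partitions, and circular-to-linear ratios
  CLR = c/(c+l) contrasted between library types (Fisher exact and
  rank-sum).
- **Classification** — multi-exonic / single-exonic / intronic circles by
  exon-boundary matching against gene models; spliced lengths;
  chromosomal distribution.
- **Biogenesis** — flanking / circle-internal / genome-wide intron length
  classes; host-gene exon and isoform propensity with exact and
  rank-based tests; inverted complementary sequence (ICS) detection by
  Smith–Waterman local alignment of a flanking intron against the
  reverse complement of its partner; a k-mer repeat-density proxy.
- **Conservation** — host-ortholog overlap by the hypergeometric upper
  tail; splice sites projected through pairwise alignment and circles
  classified Accordant / Half-accordant / Unaccordant at a 10 nt
  tolerance.
- **Expression coupling** — RPM/RPKM normalization, per-pair Pearson
  correlation on log2(RPM+1), a self-contained exact conditional
  binomial DE test with BH correction, and Reversed / Coordinated
  pattern calls per stress.
- **ceRNA network** — a seed-weighted plant-style miRNA target scorer
  (mismatch 1, G:U wobble 0.5, gap 2, doubled at miRNA positions 2–13)
  evaluated under three stringency profiles whose consensus stands in
  for the intersection of independent predictors; tripartite
  circRNA–miRNA–mRNA network, hub ranking, sponge-consistency
  signatures.
- **Chloroplast** — read and junction share of the chloroplast, and a
  permutation test for clustering of BSJ endpoints in the 3'-terminal
  window of a psbA-like gene.

Because the profiled libraries behind such studies are not reproducible
at desk scale, the package ships a synthetic-data generator
(`generate_synthetic_study()`) that emulates every input with planted
truth — 60 true circRNAs of the three types, score-stratified artifacts,
a configurable circRNA–host correlation, planted miRNA sites, orthologs
with known conservation labels, and a chloroplast locus with
3'-clustered junctions — so the full pipeline is testable end to end.
See `vignettes/circstress-methods.Rmd` for the model choices and their
rationale.

## Worked example

```r
library(circstress)

bundle <- generate_synthetic_study(generator_config(seed = 2026))
report <- run_pipeline(bundle)
writeLines(report$log)
```

```
filtering: 849 candidates retained, 60 unique nuclear circRNAs
classification: intronic=20, multi-exonic=20, single-exonic=20
conservation: 15 ortholog circRNA pairs classified
coupling: median r = 0.344
network: 56 consensus interactions
organellar: chloroplast read fraction 0.779
```

The retention kept exactly the 60 planted circRNAs (the 40 low-score
artifacts and 5 ultra-long artifacts were removed) and classified all of
them correctly; the 15 ortholog circle pairs split 5/5/5 into
Accordant / Half-accordant / Unaccordant exactly as planted; the median
circRNA–host Pearson correlation of 0.34 equals the latent correlation
the generator was asked for, i.e. host-decoupled expression; and ~80% of
BSJ reads come from the chloroplast, where junction endpoints concentrate
in the psbA-like 3' window (permutation p ≈ 5e-4).

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (`Rscript analysis/01_simulate.R`, then `02`–`08` in any
order), writing their tables under `results/analysis/` and the bulky
regenerable bundle under `scratch/`. For example, `04_biogenesis.R`
prints:

```
Median intron length (bp): circ_internal=733, flanking=723, genome_wide=191
Host genes: mean 11.9 exons vs 3.9 in non-hosts (rank p = 3.5e-35); 2.9 vs 1.0 isoforms (p = 2.7e-79)
circRNA production propensity by exon bin: [2,6):0, [6,10):0.17, [10,14):1, [14,18]:1
```

— the planted biogenesis propensities: circle-producing genes have more
exons, more isoforms, and far longer introns than non-hosts.

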