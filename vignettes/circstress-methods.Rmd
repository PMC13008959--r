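---
title: "Methods: characterizing a plant circRNAome under abiotic stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a plant circRNAome under abiotic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`circstress` re-implements, as a tested pipeline over synthetic data with
planted ground truth, the characterization of a cotton-like circular RNA
(circRNA) landscape profiled under multiple abiotic stresses (control plus
cold, heat, salt and UV-B) with RNase R-enriched sequencing. The pipeline
consumes back-splice junction (BSJ) candidate tables with per-candidate
reliability scores — the upstream caller is out of scope and is emulated by
the generator — plus a genome, gene models, linear-read counts, expression
matrices, miRNA sequences, and an ortholog table, and produces the
downstream characterization: credibility filtering, structural
classification, biogenesis statistics, cross-species splice-site
conservation, circRNA–host expression decoupling, a ceRNA network, and
chloroplast locus analysis.

All internal coordinates are 0-based half-open; GFF3 I/O converts to and
from the 1-based closed dialect at the boundary, BED output stays 0-based.

# BSJ filtering

A candidate junction is **intragenic** iff at least one gene span contains
both its endpoints; a junction bridging two distinct genes is not a
canonical back-splice and counts as intergenic. Retention uses strictly
exclusive dual score thresholds per library type — score > 0.1 for
RNase R libraries, score > 0.9 for untreated controls — matching the
"greater than" wording of the emulated protocol, and excludes ultra-long
circularization artifacts. The span cutoff behind "ultra-long" is not
defined by the protocol; we use a configurable default of 100 kb, large
enough to keep any realistic gene-scale circle. The retained sets from the
two library types are unioned (an intersection mode exists); retained
candidates merge into unique circRNAs keyed by (contig, acceptor, donor,
strand), with per-condition read support and a low-support flag for
junctions seen as a single read in a single sample.

Two descriptive contrasts mirror the emulated study's quality checks: the
score-stratified intergenic fraction per 0.1-wide score bin
(left-closed bins, score 1.0 in the last bin), and the circular-to-linear
ratio CLR = c/(c+l) per junction site and library type (0 when both counts
are 0). The library contrast is assessed both by Fisher's exact test on
the 2x2 of library type against CLR above/below 0.5 — the emulated study
names Fisher's exact test but not its contingency construction, so this
one is ours — and by a rank-sum test on the CLR values.

Condition overlap (the Venn partition) counts a circRNA as detected in a
condition when at least one retained candidate supports it there; a
minimum-read option exists but defaults off. The partition is computed
over the four stress conditions.

# Structural classification

A circle is **multi-exonic** when its acceptor matches an exon start and
its donor a later exon end of one transcript (2 or more exons spanned),
**single-exonic** when both boundaries match one exon, **intronic** when
the junction lies entirely inside one intron (boundary-exact matching of
intron ends is not required: containment is used), and unclassified
otherwise. Boundary matching tolerance defaults to 0 nt (configurable to a
few nt for noisy junctions). When several transcripts match, the
transcript minimizing the number of exons in the circle wins, ties broken
by transcript id, so assignment is deterministic. Spliced length is the
sum of contained exon lengths (exonic) or the genomic span (intronic).
Per-gene "exon number" is the maximum over isoforms and "isoform number"
the transcript count — the emulated analysis reports one number per gene
without defining the reduction; the maximum is stable under partial
annotations.

# Biogenesis features

Flanking introns are the introns immediately bordering the circularized
exon block; internal introns lie between its exons; the genome-wide class
is every distinct annotated intron. Host/non-host comparisons of exon and
isoform counts use two-sided rank-sum tests (without continuity
correction, so self-comparisons return exactly 1); per-bin circRNA
production propensity is hosts-in-bin over genes-in-bin, with empty bins
undefined rather than zero. The emulated study's figure legend attributes
Fisher's exact test to all panels including continuous length
comparisons; we apply Fisher's exact test to proportion panels and
rank-sum tests to distribution panels.

Inverted complementary sequence (ICS) detection is not specified by the
emulated protocol; we use Smith–Waterman local alignment of the upstream
intron against the reverse complement of the downstream intron
(match +1, mismatch −1, linear gap −2; compiled in C++), reporting the
best match when it reaches 10 alignment columns at 80% identity.
Repetitive-sequence abundance is proxied by k-mer coverage: the fraction
of positions covered by a 13-mer occurring at least twice within the
sequence — a self-contained proxy, not a repeat-family annotation. The
control comparison samples internal exons (flanked on both sides) of
non-host transcripts without replacement under a fixed seed; first and
last exons are excluded for comparability with circularizable exons.
Because non-host introns are much shorter than host introns in the
generator (and in real genomes host introns are long), chance ICS length
partly reflects intron length; the comparison is therefore reported with
group medians alongside p-values.

# Cross-species conservation

Host-gene ortholog overlap is tested with the upper hypergeometric tail
P(X ≥ overlap) over the ortholog-pair universe. Splice sites are
projected between orthologous genes by sequence alignment; the emulated
study does not state a method, so we align a ±200 nt window around each
site to the full orthologous gene sequence (match +1, mismatch −1, gap
opening 5, extension 1) and project the site through the alignment — a
site aligned to a gap is unmappable. A full global coordinate map is also
provided for short genes. A site is conserved when its projected position
is within 10 nt (the default tolerance; the emulated study's "identical
genomic coordinates" examples suggest exactness, but no tolerance is
printed) of the partner circle's site; circles are **Accordant** (both
sites conserved), **Half-accordant** (one), or **Unaccordant** (none,
including unmappable). With several circles per ortholog pair, all pairs
are scored and the most conserved category per species-A circle is kept.

# Expression coupling

Counts are normalized to RPM (and RPKM with feature lengths). Pearson
correlations between each circRNA and its host are computed across
samples on log2(RPM + 1). On the raw count scale the generator's
lognormal–Poisson construction attenuates negative correlations well
beyond the recovery tolerance (the correlation of exponentiated normals
is not the latent correlation), while on the log scale the latent
correlation is recovered essentially unbiased; log-scale correlation is
also the field's standard practice. A raw-RPM mode is provided.

Differential expression uses a self-contained exact conditional test: the
pooled treatment count of a feature is tested against a binomial with
library-size-proportional success probability (two-sided, minimum-
likelihood convention), with BH correction; a feature is up/down when
q < 0.05 and |log2FC| ≥ 1 (log2FC on group RPM means with a 1-RPM
pseudocount; the emulated study prints none of these thresholds). The
test is dispersion-free and therefore anti-conservative under biological
overdispersion — visible in the synthetic study, where replicate-level
lognormal variation produces DE calls beyond the planted ones; a
configurable count-deflation factor is provided. The circRNA/host pattern
per condition is **Reversed** (opposite DE directions), **Coordinated**
(same), HostStable / CircStable (only one side DE), or NS.

# ceRNA network

The three external target predictors of the emulated protocol are
replaced by one plant-style scorer evaluated under three stringency
profiles (penalty cutoffs 0 / 2.5 / 5.0); the consensus filter keeps
interactions found under every profile, preserving the
intersection-of-predictors logic while staying self-contained. The scorer
aligns each target window against the reverse complement of the miRNA
with penalties mismatch 1, G:U wobble 0.5, gap 2, doubled at miRNA
positions 2–13 (the widely used plant expectation convention; the
protocol names no scheme), and free-energy filtering is approximated by
the penalty cutoff. circRNA target sequences are the spliced circle
extended by its own first L−1 bases so junction-spanning sites are
scannable. Overlapping sites resolve greedily by ascending penalty,
leftmost first. The network is tripartite (circRNA–miRNA–mRNA) with DE
attributes on nodes; hubs are ranked by circRNA-partner and DE-mRNA
target counts, and the sponge signature of a miRNA is the fraction of its
circRNA partners up and mRNA targets down.

# Chloroplast analysis

The chloroplast share of the BSJ pool is tallied both as reads and as
unique junctions (the emulated study's ">80% of the pool" does not say
which; both are emitted; the generator's read tally is the dominating
one). 3'-terminus clustering at the psbA-like gene uses a permutation
test: the observed fraction of junction endpoints (both acceptor and
donor by default) inside the 3'-terminal window — 20% of the gene length
by default, strand-aware — is compared against endpoints placed uniformly
within the gene, p = (1 + #{null ≥ observed}) / (n_perm + 1) with 2000
permutations, never zero, reproducible under the seed. Chloroplast genes
are intronless in the toy model and chloroplast circles bypass the
nuclear classifier.

# The synthetic study

The generator emulates the study's data products, not its reads:
no FASTQ, no error model, no RNase R efficiency beyond score separation.
Defaults encode the study conditions: 5 conditions × 2 replicates per
library type (replicate count is not printed in the emulated study; 2 is
the implied minimum), 60 true circRNAs (20 per type, one per host gene),
40 low-score artifacts (half intergenic) plus 5 credible-score ultra-long
artifacts, and a chloroplast whose read mass dominates the pool at
roughly the 80% level. Host genes draw 8–16 exons, 2–4 isoforms and
500–1000 bp introns versus 2–6 exons, 1 isoform and 50–200 bp introns for
the 300 non-hosts, so host/non-host contrasts (exons ≈ 12 vs 4, isoforms
≈ 3 vs 1) and the intron-length ordering are planted by construction.
Reliability scores are Beta-distributed and truncated to the credible
side of the retention thresholds (true: concentrated near 1; artifacts:
near 0) — the upstream caller's score model is out of scope, and only the
ordering against the thresholds matters downstream. Expression counts are
Poisson draws from latent bivariate lognormal means (sdlog 0.5, mean 200
counts per circRNA) with latent correlation 0.34 per circ–host pair — the
decoupling level reported by the emulated study, used purely as a
generator parameter — plus planted condition effects (|log2FC| = 2.5)
realizing 6 Reversed, 4 Coordinated, 4 HostStable and 2 CircStable pairs.
miRNA binding sites are planted as exact reverse complements at recorded
offsets, on the transcript the classifier deterministically matches;
orthologs are sequence copies with splice sites shifted by 0 (Accordant)
or 50 nt (beyond the 10 nt tolerance) at one or both ends, a third of the
Accordant copies carrying a 10 nt insertion to exercise alignment-based
projection. No ICS is planted by default, matching the emulated study's
negative ICS finding; a planting mode provides the detector's positive
control.

What passing on this generator does **not** show about real data:
alignment and scoring noise at junction boundaries (tolerance 0 suffices
here), overdispersed replicate counts (the DE test is anti-conservative
on real data), repeat families and structured intergenic sequence,
incomplete or wrong gene models, and miRNA sites with bulges or imperfect
seeds.

# Numerical and design choices

- Exact tests: two-sided Fisher p sums hypergeometric point
  probabilities ≤ the observed one with a 1e-7 relative tie slack (the
  standard convention); hypergeometric tails via the exact distribution
  functions. Verified against factorial-form enumeration to 1e-12 over
  all tables with total ≤ 40.
- Local alignment ties break toward the smallest end cell and
  diagonal-first traceback, giving a deterministic left-most match.
- Zero-length introns (abutting exons) are dropped as annotation
  artifacts; gene-overlap queries are strand-agnostic by default (the
  emulated study never states strandedness of BSJ–gene assignment), with
  a strand-matched mode.
- Degenerate inputs: CLR of 0/0 is 0; Pearson r with zero variance or
  n < 3 is missing (never 0); empty propensity bins are undefined;
  permutation p is never 0 by add-one smoothing.
- Problem sizes used by the validation suite (chosen to make the checks
  sharp at interactive scale): correlation recovery at 500 samples per
  pair; DE null calibration on 10,000 features at ~500 counts per group,
  where the discrete exact test's attained size sits within [0.04, 0.06];
  clustering calibration over 100 uniform replicates at 499 permutations;
  alignment oracles at 200 random pairs up to 40 nt plus exhaustive
  substring-pair enumeration up to 9 nt.

# Known limitations

The DE test ignores overdispersion (by design, to stay closed-form and
dependency-free); the repeat proxy is not a repeat annotation; the ICS
control comparison inherits intron-length confounding; rolling-circle
internal structure and circRNA isoform collapsing are out of scope, as is
any read-level processing.
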