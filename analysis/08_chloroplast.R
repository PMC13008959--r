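#!/usr/bin/env Rscript
# Chloroplast circRNAs: fraction of the BSJ read pool per library type and
# the permutation test for 3'-terminus clustering at the psbA-like locus.
source(file.path("analysis", "00_common.R"))

b <- study_bundle()
frac <- organelle_fraction(b$bsj, b$config$cp_contig)
retained <- apply_retention(b$bsj)
circ <- merge_unique(retained)
cp <- circ[circ$contig == b$config$cp_contig, ]
gene <- b$annotation$genes[b$annotation$genes$contig == b$config$cp_contig, ][1, ]
clust <- clustering_enrichment(cp, gene$start, gene$end, gene$strand,
                               n_perm = 2000, seed = 1)
tsv(frac$per_library, "chloroplast_fraction.tsv")
jsonlite::write_json(clust, file.path(OUT, "psba_clustering.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Chloroplast share of BSJ reads: %.0f%% overall; per library: %s\n",
            100 * frac$overall$fraction_reads,
            paste(frac$per_library$library,
                  sprintf("%.0f%%", 100 * frac$per_library$fraction_reads),
                  collapse = ", ")))
cat(sprintf("psbA-like 3' terminus: %.0f%% of junction endpoints in the terminal 20%% window (permutation p = %.2e, %d junctions)\n",
            100 * clust$observed_fraction, clust$permutation_p, nrow(cp)))
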