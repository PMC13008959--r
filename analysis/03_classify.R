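#!/usr/bin/env Rscript
# Structural classification of the retained circRNAs (multi-exonic /
# single-exonic / intronic), spliced lengths, and chromosomal distribution.
source(file.path("analysis", "00_common.R"))

b <- study_bundle()
retained <- apply_retention(classify_context(b$bsj, b$annotation))
nuclear <- merge_unique(retained)
nuclear <- nuclear[nuclear$contig != b$config$cp_contig, ]
cls <- classify_circs(nuclear, b$annotation)
tsv(cls, "classification.tsv")

tab <- table(cls$circ_type)
acc <- mean(cls$circ_type ==
              b$truth$circ$circ_type[match(cls$circ_id, b$truth$circ$circ_id)])
med_len <- tapply(cls$spliced_length, cls$circ_type, median)
chrom <- chromosome_distribution(nuclear)
tsv(chrom$per_contig, "chromosome_distribution.tsv")

cat("Type counts:", paste(names(tab), tab, sep = "=", collapse = ", "),
    sprintf("| planted-type recovery %.0f%%\n", 100 * acc))
cat("Median spliced length (nt):",
    paste(names(med_len), round(med_len), sep = "=", collapse = ", "), "\n")
cat("Per-chromosome circRNA counts:",
    paste(chrom$per_contig$contig, chrom$per_contig$n_circ,
          sep = "=", collapse = ", "), "\n")
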