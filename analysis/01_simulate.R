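#!/usr/bin/env Rscript
# Generate the synthetic multi-stress circRNA study (genome, annotation,
# BSJ candidates from RNase R and control libraries, linear reads,
# expression matrices, miRNAs, orthologs, chloroplast locus) and write it
# to plain-text files for inspection.
source(file.path("analysis", "00_common.R"))

b <- study_bundle()
# full bundle files are bulky and fully regenerable: keep them out of
# the results tree
dir <- file.path("scratch", "synthetic_study")
write_synthetic_bundle(b, dir)

cat("Synthetic study written to", dir, "\n")
cat("  genome:", length(b$genome$contigs), "contigs,",
    sum(b$genome$lengths), "bp\n")
cat("  genes:", nrow(b$annotation$genes),
    "| planted circRNAs:", nrow(b$truth$circ),
    "| artifact BSJs:", sum(b$origins$origin == "artifact"),
    "| ultra-long artifacts:", sum(b$origins$origin == "ultralong"), "\n")
cat("  BSJ candidate rows:", nrow(b$bsj),
    "| chloroplast junctions:", nrow(b$truth$cp), "\n")
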