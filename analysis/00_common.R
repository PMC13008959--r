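# Shared setup for the analysis scripts: the study configuration and paths.
# Every script regenerates the synthetic study deterministically from this
# seed, so the scripts can be run independently and in any order.
suppressPackageStartupMessages(library(circstress))

STUDY_SEED <- 2026
OUT <- file.path("results", "analysis")
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

study_bundle <- function() generate_synthetic_study(generator_config(seed = STUDY_SEED))
tsv <- function(df, name) {
  utils::write.table(df, file.path(OUT, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(name)
}
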