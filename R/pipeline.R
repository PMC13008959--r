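## Pipeline orchestration: runs every analysis stage in dependency order on
## a study bundle (synthetic or file-loaded), collects stage tables, and
## produces a machine-readable summary whose every number is recomputable
## from the tables.

#' Pipeline parameters
#'
#' @param retention A [retention_config()].
#' @param classify_tolerance Splice-boundary tolerance for type
#'   classification (nt).
#' @param conservation_tolerance Splice-site conservation tolerance (nt).
#' @param de_alpha,de_fc_floor Differential-expression thresholds.
#' @param profiles Target-scoring stringency cutoffs.
#' @param cp_window_frac 3'-terminal window fraction for the chloroplast
#'   clustering test.
#' @param n_perm Permutations for the clustering test.
#' @param seed Seed for the pipeline's own stochastic stages (control
#'   sampling, permutation test).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(retention = retention_config(),
                            classify_tolerance = 0,
                            conservation_tolerance = 10,
                            de_alpha = 0.05, de_fc_floor = 1,
                            profiles = stringency_profiles(),
                            cp_window_frac = 0.2, n_perm = 2000,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full circRNA characterization pipeline
#'
#' Stages in dependency order: BSJ filtering -> structural classification
#' -> biogenesis features -> conservation -> expression coupling -> ceRNA
#' network -> chloroplast analysis. Optional stages without inputs
#' (orthologs, miRNAs, expression) are skipped with a logged note.
#' Deterministic for fixed bundle and parameters.
#'
#' @param bundle A [generate_synthetic_study()] bundle (or an equivalently
#'   shaped list loaded from files).
#' @param params A [pipeline_params()].
#' @return A `pipeline_report` list: `tables` (per-stage results),
#'   `summary` (headline numbers), `params`, `log` (character vector).
#' @export
run_pipeline <- function(bundle, params = pipeline_params()) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  tables <- list()
  cp_contig <- bundle$config$cp_contig %||% "ChrC"

  ## 1. filtering ----------------------------------------------------------
  bsj <- classify_context(bundle$bsj, bundle$annotation)
  strat <- score_stratification(bsj)
  retained <- apply_retention(bsj, params$retention)
  circ_all <- merge_unique(retained)
  nuclear <- circ_all[circ_all$contig != cp_contig, , drop = FALSE]
  overlap <- condition_overlap(condition_sets(
    retained[retained$contig != cp_contig, , drop = FALSE]))
  site_stats <- bsj_site_stats(retained, bundle$linear)
  clr <- clr_library_contrast(site_stats)
  tables$filtering <- list(stratification = strat, circ = circ_all,
                           nuclear = nuclear, overlap = overlap,
                           site_stats = site_stats, clr_contrast = clr)
  note("filtering: ", nrow(retained), " candidates retained, ",
       nrow(nuclear), " unique nuclear circRNAs")

  ## 2. classification -----------------------------------------------------
  classification <- classify_circs(nuclear, bundle$annotation,
                                   params$classify_tolerance)
  chrom <- chromosome_distribution(nuclear)
  tables$classification <- list(classification = classification,
                                chromosomes = chrom)
  note("classification: ",
       paste(names(table(classification$circ_type)),
             table(classification$circ_type), sep = "=", collapse = ", "))

  ## 3. biogenesis features -------------------------------------------------
  host_ids <- unique(unlist(strsplit(nuclear$host_genes, ",")))
  host_ids <- host_ids[nzchar(host_ids)]
  nuclear_genes <- bundle$annotation$genes$gene_id[
    bundle$annotation$genes$contig != cp_contig]
  ann_nuc <- bundle$annotation
  introns <- intron_length_classes(classification, bundle$annotation)
  hf <- host_feature_comparison(
    subset_annotation_features(ann_nuc, nuclear_genes), host_ids)
  prop <- propensity_by_bin(subset_annotation_features(ann_nuc, nuclear_genes),
                            host_ids, "exons")
  ics <- tryCatch(
    ics_control_comparison(classification, bundle$annotation, bundle$genome,
                           host_ids, seed = params$seed),
    error = function(e) { note("ics comparison skipped: ", conditionMessage(e)); NULL })
  tables$biogenesis <- list(intron_classes = introns, host_features = hf,
                            propensity = prop, ics = ics)

  ## 4. conservation --------------------------------------------------------
  if (!is.null(bundle$orthologs)) {
    orth <- bundle$orthologs
    circ_a <- data.frame(circ_id = classification$circ_id,
                         gene_id = vapply(strsplit(nuclear$host_genes, ","),
                                          function(x) if (length(x)) x[1] else NA_character_,
                                          character(1)),
                         acceptor = nuclear$acceptor, donor = nuclear$donor,
                         stringsAsFactors = FALSE)
    circ_a <- circ_a[!is.na(circ_a$gene_id), , drop = FALSE]
    ov <- ortholog_overlap_test(host_ids, orth$hosts_b, orth$ortholog_map)
    calls <- conservation_calls(circ_a, orth$circ_b, orth$ortholog_map,
                                bundle$annotation, orth$annotation_b,
                                bundle$genome, orth$genome_b,
                                params$conservation_tolerance)
    tables$conservation <- list(overlap_test = ov, calls = calls,
                                summary = conservation_summary(calls))
    note("conservation: ", nrow(calls), " ortholog circRNA pairs classified")
  } else {
    note("conservation skipped: no ortholog input")
  }

  ## 5. expression coupling -------------------------------------------------
  if (!is.null(bundle$expr)) {
    host_map <- bundle$expr$pairs[, c("circ_id", "gene_id")]
    coup <- coupling_analysis(bundle$expr$circ_counts, bundle$expr$gene_counts,
                              host_map, bundle$expr$samples,
                              control = bundle$config$conditions[1],
                              alpha = params$de_alpha,
                              fc_floor = params$de_fc_floor)
    tables$coupling <- coup
    note("coupling: median r = ", round(coup$median_r, 3))
  } else {
    note("coupling skipped: no expression input")
  }

  ## 6. ceRNA network -------------------------------------------------------
  if (!is.null(bundle$mirnas) && !is.null(tables$coupling)) {
    circ_targets <- do.call(rbind, lapply(seq_len(nrow(classification)), function(i) {
      cl <- classification[i, ]
      if (cl$circ_type == "unclassified") return(NULL)
      data.frame(target_id = cl$circ_id,
                 sequence = circ_target_seq(
                   circ_sequence(cl, bundle$annotation, bundle$genome),
                   max(nchar(bundle$mirnas$sequence))),
                 target_kind = "circRNA", stringsAsFactors = FALSE)
    }))
    mrna_ids <- unique(bundle$mirna_sites$target_id[
      bundle$mirna_sites$target_kind == "mRNA"])
    mrna_targets <- do.call(rbind, lapply(mrna_ids, function(tid) {
      ex <- transcript_exons(bundle$annotation, tid)
      s <- paste(vapply(seq_len(nrow(ex)), function(e) {
        genome_subseq(bundle$genome, ex$contig[e], ex$start[e], ex$end[e])
      }, character(1)), collapse = "")
      data.frame(target_id = tid, sequence = s, target_kind = "mRNA",
                 stringsAsFactors = FALSE)
    }))
    targets <- rbind(circ_targets, mrna_targets)
    sites <- scan_all_targets(bundle$mirnas, targets, params$profiles)
    interactions <- consensus_filter(sites)
    # node DE states from the first stress condition's contrast
    st_cond <- names(tables$coupling$de_circ)[1]
    node_states <- rbind(
      data.frame(id = tables$coupling$de_circ[[st_cond]]$feature,
                 log2fc = tables$coupling$de_circ[[st_cond]]$log2fc,
                 state = tables$coupling$de_circ[[st_cond]]$state,
                 stringsAsFactors = FALSE),
      data.frame(id = tables$coupling$de_gene[[st_cond]]$feature,
                 log2fc = tables$coupling$de_gene[[st_cond]]$log2fc,
                 state = tables$coupling$de_gene[[st_cond]]$state,
                 stringsAsFactors = FALSE))
    # mRNA interaction targets are transcripts; inherit the gene's DE state
    tx2gene <- bundle$annotation$transcripts
    tx_states <- node_states[match(tx2gene$gene_id, node_states$id), ]
    tx_states$id <- tx2gene$transcript_id
    node_states <- rbind(node_states, tx_states[!is.na(tx_states$state), ])
    hubs <- hub_rank(interactions, node_states)
    tables$network <- list(sites = sites, interactions = interactions,
                           hubs = hubs, node_states = node_states,
                           condition = st_cond)
    note("network: ", nrow(interactions), " consensus interactions")
  } else {
    note("network skipped: no miRNA input")
  }

  ## 7. chloroplast ---------------------------------------------------------
  cp_bsj <- circ_all[circ_all$contig == cp_contig, , drop = FALSE]
  frac <- organelle_fraction(bundle$bsj, cp_contig)
  cp_gene <- bundle$annotation$genes[bundle$annotation$genes$contig == cp_contig, ][1, ]
  clust <- if (nrow(cp_bsj) > 0) {
    clustering_enrichment(cp_bsj, cp_gene$start, cp_gene$end, cp_gene$strand,
                          window_size = floor(params$cp_window_frac *
                                                (cp_gene$end - cp_gene$start)),
                          n_perm = params$n_perm, seed = params$seed)
  } else NULL
  tables$organellar <- list(fraction = frac, clustering = clust,
                            cp_circ = cp_bsj)
  note("organellar: chloroplast read fraction ",
       round(frac$overall$fraction_reads, 3))

  report <- structure(list(tables = tables, params = params, log = log),
                      class = "pipeline_report")
  report$summary <- summarize_report(report)
  report
}

# restrict gene_features to a gene subset (used to keep the chloroplast
# gene out of nuclear host/non-host statistics)
subset_annotation_features <- function(annotation, gene_ids) {
  annotation$gene_features <- annotation$gene_features[
    annotation$gene_features$gene_id %in% gene_ids, , drop = FALSE]
  annotation
}

#' Headline summary of a pipeline report
#'
#' Every entry is an aggregation of one stage table, re-derivable from the
#' report.
#'
#' @param report A [run_pipeline()] report.
#' @return Named list of headline numbers.
#' @export
summarize_report <- function(report) {
  t <- report$tables
  cls <- t$classification$classification
  s <- list(
    n_unique_circ = nrow(t$filtering$nuclear),
    n_unique_all = nrow(t$filtering$circ),
    n_low_support = sum(t$filtering$nuclear$low_support),
    n_multi_exonic = sum(cls$circ_type == "multi-exonic"),
    n_single_exonic = sum(cls$circ_type == "single-exonic"),
    n_intronic = sum(cls$circ_type == "intronic"),
    n_unclassified = sum(cls$circ_type == "unclassified"),
    shared_all_conditions = t$filtering$overlap$shared_all,
    unique_per_condition = as.list(t$filtering$overlap$unique_per_condition),
    clr_fisher_p = t$filtering$clr_contrast$fisher_p
  )
  if (!is.null(t$conservation)) {
    s$ortholog_overlap <- t$conservation$overlap_test$overlap
    s$ortholog_overlap_p <- t$conservation$overlap_test$p
    s$conservation_counts <- as.list(t$conservation$summary)
  }
  if (!is.null(t$coupling)) {
    s$median_pearson_r <- t$coupling$median_r
    s$de_counts <- lapply(t$coupling$de_circ, function(d) sum(d$state != "ns"))
    s$n_reversed <- sum(t$coupling$patterns$pattern == "Reversed")
    s$n_coordinated <- sum(t$coupling$patterns$pattern == "Coordinated")
  }
  if (!is.null(t$network)) {
    s$n_interactions <- nrow(t$network$interactions)
    s$n_circ_with_sites <- length(unique(
      t$network$interactions$target_id[
        t$network$interactions$target_kind == "circRNA"]))
  }
  s$chloroplast_read_fraction <- t$organellar$fraction$overall$fraction_reads
  s$chloroplast_junction_fraction <- t$organellar$fraction$overall$fraction_junctions
  if (!is.null(t$organellar$clustering)) {
    s$cp_clustering_fraction <- t$organellar$clustering$observed_fraction
    s$cp_clustering_p <- t$organellar$clustering$permutation_p
  }
  s
}

#' Write a pipeline report to disk
#'
#' Stage tables as TSV, the summary (and run log) as JSON.
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  t <- report$tables
  tsv(t$filtering$circ, "circ_unique.tsv")
  tsv(t$filtering$stratification, "score_stratification.tsv")
  tsv(t$filtering$site_stats, "bsj_site_stats.tsv")
  tsv(t$classification$classification, "classification.tsv")
  tsv(t$biogenesis$intron_classes, "intron_classes.tsv")
  if (!is.null(t$conservation)) tsv(t$conservation$calls, "conservation_calls.tsv")
  if (!is.null(t$coupling)) {
    tsv(t$coupling$coupling, "coupling_records.tsv")
    tsv(t$coupling$patterns, "coupling_patterns.tsv")
  }
  if (!is.null(t$network)) tsv(t$network$interactions, "interactions.tsv")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
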