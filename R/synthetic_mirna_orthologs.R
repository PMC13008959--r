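## Synthetic miRNAs with planted binding sites, optional planted ICS, a
## synthetic second species with known splice-site conservation categories,
## and the one-call study bundle.

#' Plant a perfect inverted complementary sequence in every circRNA flank
#'
#' Writes a random `length`-nt sequence into the upstream flanking intron
#' and its reverse complement into the downstream flanking intron of every
#' exonic planted circRNA. Used to give the ICS detector a positive
#' control; the default study configuration plants none.
#'
#' @param ref Output of [generate_reference()].
#' @param length ICS length in nt.
#' @return `ref` with the genome edited and `truth$ics` recording the
#'   planted positions.
#' @export
plant_ics <- function(ref, length = 30) {
  set.seed(ref$config$seed + 4L)
  tc <- ref$truth$circ
  planted <- list()
  for (i in seq_len(nrow(tc))) {
    if (!tc$circ_type[i] %in% c("multi-exonic", "single-exonic")) next
    intr <- transcript_introns(ref$annotation, tc$transcript_id[i])
    up_i <- tc$exon_from[i] - 1L; dn_i <- tc$exon_to[i]
    if (up_i < 1 || dn_i > nrow(intr)) next
    if (intr$end[up_i] - intr$start[up_i] < length + 20 ||
        intr$end[dn_i] - intr$start[dn_i] < length + 20) next
    ics <- random_seq(length)
    up_pos <- intr$start[up_i] + 10L
    dn_pos <- intr$start[dn_i] + 10L
    ref$genome <- genome_replace(ref$genome, intr$contig[up_i], up_pos, ics)
    ref$genome <- genome_replace(ref$genome, intr$contig[dn_i], dn_pos,
                                 reverse_complement(ics))
    planted[[length(planted) + 1]] <- data.frame(
      circ_id = tc$circ_id[i], up_pos = up_pos, dn_pos = dn_pos,
      ics_length = length, stringsAsFactors = FALSE)
  }
  ref$truth$ics <- if (length(planted)) do.call(rbind, planted) else NULL
  ref
}

#' Simulate miRNAs and plant perfect binding sites
#'
#' Draws random miRNA sequences and writes their exact reverse complements
#' into exonic segments of planted circRNAs and into exons of non-host
#' gene transcripts, recording each site's offset within the spliced
#' target sequence. Also emits a per-condition miRNA RPM table.
#'
#' @param ref Output of [generate_reference()] (possibly after
#'   [plant_ics()]).
#' @return List: `ref` (genome edited), `mirnas` (data.frame mirna_id,
#'   sequence), `sites` (planted-site truth: mirna_id, target_id,
#'   target_kind, position), `mirna_expr` (RPM by condition).
#' @export
simulate_mirnas <- function(ref) {
  config <- ref$config
  set.seed(config$seed + 5L)
  L <- config$mirna_length
  mirnas <- data.frame(
    mirna_id = sprintf("syn-miR%03d", seq_len(config$n_mirna)),
    sequence = vapply(seq_len(config$n_mirna), function(i) random_seq(L), character(1)),
    stringsAsFactors = FALSE)

  tc <- ref$truth$circ
  exonic <- tc[tc$circ_type %in% c("multi-exonic", "single-exonic") &
                 tc$strand == "+", , drop = FALSE]
  nonhost <- ref$truth$roles$gene_id[ref$truth$roles$role == "nonhost"]
  gtab <- ref$annotation$genes
  plus_nonhost <- nonhost[gtab$strand[match(nonhost, gtab$gene_id)] == "+"]

  used <- list()  # per contig: planted genomic windows, to avoid collisions
  free <- function(contig, s, e) {
    u <- used[[contig]]
    if (is.null(u)) return(TRUE)
    !any(u[, 1] < e & s < u[, 2])
  }
  reserve <- function(contig, s, e) {
    used[[contig]] <<- rbind(used[[contig]], c(s, e))
  }

  sites <- list()
  for (m in seq_len(nrow(mirnas))) {
    site_seq <- reverse_complement(mirnas$sequence[m])
    # circRNA targets: plant on the transcript the classifier will match
    # (isoform skipping could otherwise drop the planted exon from the
    # spliced circle sequence)
    targets <- sample(nrow(exonic), config$circ_targets_per_mirna)
    for (t in targets) {
      cl <- classify_type(exonic$contig[t], exonic$acceptor[t],
                          exonic$donor[t], exonic$strand[t], ref$annotation, 0)
      ex <- transcript_exons(ref$annotation, cl$transcript_id)
      idx <- cl$exon_from:cl$exon_to
      placed <- FALSE
      for (attempt in 1:50) {
        e <- idx[sample.int(length(idx), 1)]
        elen <- ex$end[e] - ex$start[e]
        if (elen < L + 4) next
        off <- sample(0:(elen - L), 1)
        gpos <- ex$start[e] + off
        if (!free(ex$contig[e], gpos, gpos + L)) next
        ref$genome <- genome_replace(ref$genome, ex$contig[e], gpos, site_seq)
        reserve(ex$contig[e], gpos, gpos + L)
        spliced_off <- sum(ex$end[idx[idx < e]] - ex$start[idx[idx < e]]) + off
        sites[[length(sites) + 1]] <- data.frame(
          mirna_id = mirnas$mirna_id[m], target_id = exonic$circ_id[t],
          target_kind = "circRNA", position = spliced_off,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place circRNA site; exons too short")
    }
    # mRNA targets
    gsel <- sample(plus_nonhost, config$mrna_targets_per_mirna)
    for (g in gsel) {
      tid <- ref$annotation$transcripts$transcript_id[
        ref$annotation$transcripts$gene_id == g][1]
      ex <- transcript_exons(ref$annotation, tid)
      placed <- FALSE
      for (attempt in 1:50) {
        e <- sample(nrow(ex), 1)
        elen <- ex$end[e] - ex$start[e]
        if (elen < L + 4) next
        off <- sample(0:(elen - L), 1)
        gpos <- ex$start[e] + off
        if (!free(ex$contig[e], gpos, gpos + L)) next
        ref$genome <- genome_replace(ref$genome, ex$contig[e], gpos, site_seq)
        reserve(ex$contig[e], gpos, gpos + L)
        spliced_off <- sum(ex$end[seq_len(e - 1)] - ex$start[seq_len(e - 1)]) + off
        sites[[length(sites) + 1]] <- data.frame(
          mirna_id = mirnas$mirna_id[m], target_id = tid,
          target_kind = "mRNA", position = spliced_off,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place mRNA site; exons too short")
    }
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL

  conds <- config$conditions
  base <- stats::rlnorm(config$n_mirna, meanlog = log(100), sdlog = 1)
  fc <- matrix(2^stats::rnorm(config$n_mirna * (length(conds) - 1), 0, 1.2),
               config$n_mirna)
  expr <- cbind(base, base * fc)
  dimnames(expr) <- list(mirnas$mirna_id, conds)
  list(ref = ref, mirnas = mirnas, sites = sites, mirna_expr = expr)
}

#' Simulate a synthetic ortholog species with planted conservation labels
#'
#' Copies a subset of host genes (and extra non-host genes for the test
#' universe) into a second-species genome/annotation; each copied host
#' gene receives one circRNA whose splice sites are identical (Accordant),
#' shifted at one end (Half-accordant), or shifted at both ends
#' (Unaccordant) by more than the classification tolerance. A third of the
#' Accordant copies carry a 10-nt insertion upstream of the circle to
#' exercise alignment-based coordinate projection.
#'
#' @param ref Output of [generate_reference()].
#' @return List: `genome_b`, `annotation_b` ([genome_sequence()] /
#'   [annotation_set()] of the synthetic species), `ortholog_map`
#'   (gene_a, gene_b), `circ_b` (circ_id, gene_id, acceptor, donor),
#'   `truth` (gene_a, gene_b, category), `hosts_b`.
#' @export
simulate_orthologs <- function(ref) {
  config <- ref$config
  set.seed(config$seed + 6L)
  mix <- config$ortholog_mix
  n_pairs <- sum(mix)
  tc <- ref$truth$circ
  hosts <- sort(tc$host_gene)
  if (length(hosts) < n_pairs) stop("not enough host genes for ortholog mix")
  chosen <- sample(hosts, n_pairs)
  cats <- sample(rep(names(mix), mix))
  nonhost <- ref$truth$roles$gene_id[ref$truth$roles$role == "nonhost"]
  extra <- sample(nonhost, min(config$n_extra_ortholog_pairs, length(nonhost)))

  shift <- config$ortholog_shift
  cursor <- 0L
  contig_b <- "B_Chr01"
  seq_parts <- character(0)
  genes_b <- list(); tx_b <- list(); ex_b <- list()
  circ_b <- list(); truth <- list()
  copy_gene <- function(gid, insertion_at = NA) {
    g <- ref$annotation$genes[ref$annotation$genes$gene_id == gid, ]
    gseq <- genome_subseq(ref$genome, g$contig, g$start, g$end)
    ins <- 0L
    if (!is.na(insertion_at)) {
      gseq <- paste0(substr(gseq, 1, insertion_at),
                     random_seq(10), substr(gseq, insertion_at + 1, nchar(gseq)))
      ins <- 10L
    }
    gap <- 200L
    b_start <- cursor + gap
    b_end <- b_start + nchar(gseq)
    cursor <<- b_end
    seq_parts <<- c(seq_parts, random_seq(gap), gseq)
    bid <- paste0("B_", gid)
    genes_b[[length(genes_b) + 1]] <<- data.frame(
      gene_id = bid, contig = contig_b, start = b_start, end = b_end,
      strand = g$strand, stringsAsFactors = FALSE)
    # copy the primary transcript's exon structure
    tid_a <- sprintf("%s.t1", gid)
    ex <- transcript_exons(ref$annotation, tid_a)
    loc_start <- ex$start - g$start
    loc_end <- ex$end - g$start
    if (ins > 0) {
      loc_start <- ifelse(loc_start >= insertion_at, loc_start + ins, loc_start)
      loc_end <- ifelse(loc_end > insertion_at, loc_end + ins, loc_end)
    }
    tid_b <- paste0(bid, ".t1")
    tx_b[[length(tx_b) + 1]] <<- data.frame(
      transcript_id = tid_b, gene_id = bid, stringsAsFactors = FALSE)
    ex_b[[length(ex_b) + 1]] <<- data.frame(
      transcript_id = tid_b, gene_id = bid, contig = contig_b,
      start = b_start + loc_start, end = b_start + loc_end,
      strand = g$strand, stringsAsFactors = FALSE)
    list(bid = bid, b_start = b_start, b_end = b_end, ins = ins,
         g = g)
  }

  for (k in seq_len(n_pairs)) {
    gid <- chosen[k]; cat <- cats[k]
    circ <- tc[tc$host_gene == gid, ][1, ]
    acc_loc <- circ$acceptor - ref$annotation$genes$start[
      ref$annotation$genes$gene_id == gid]
    insertion_at <- if (cat == "Accordant" && k %% 3 == 0 && acc_loc > 30) {
      as.integer(acc_loc - 20)
    } else NA
    cp <- copy_gene(gid, insertion_at)
    g <- cp$g
    acc_b <- circ$acceptor - g$start; don_b <- circ$donor - g$start
    if (!is.na(insertion_at)) {
      if (acc_b >= insertion_at) acc_b <- acc_b + cp$ins
      if (don_b > insertion_at) don_b <- don_b + cp$ins
    }
    if (cat == "Half-accordant") {
      don_b <- don_b + shift
    } else if (cat == "Unaccordant") {
      # same-direction shift keeps the span positive for short circles
      acc_b <- acc_b + shift
      don_b <- don_b + shift
    }
    stopifnot(acc_b >= 0, don_b > acc_b, cp$b_start + don_b <= cp$b_end)
    circ_b[[length(circ_b) + 1]] <- data.frame(
      circ_id = make_circ_id(contig_b, cp$b_start + acc_b, cp$b_start + don_b, g$strand),
      gene_id = cp$bid, acceptor = cp$b_start + acc_b, donor = cp$b_start + don_b,
      strand = g$strand, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      gene_a = gid, gene_b = cp$bid, category = cat, stringsAsFactors = FALSE)
  }
  for (gid in extra) copy_gene(gid)

  genome_b <- genome_sequence(stats::setNames(paste(seq_parts, collapse = ""), contig_b))
  annotation_b <- annotation_set(do.call(rbind, genes_b), do.call(rbind, tx_b),
                                 do.call(rbind, ex_b))
  truth <- do.call(rbind, truth)
  circ_b <- do.call(rbind, circ_b)
  map <- rbind(truth[, c("gene_a", "gene_b")],
               data.frame(gene_a = extra, gene_b = paste0("B_", extra),
                          stringsAsFactors = FALSE))
  rownames(map) <- rownames(truth) <- rownames(circ_b) <- NULL
  list(genome_b = genome_b, annotation_b = annotation_b,
       ortholog_map = map, circ_b = circ_b, truth = truth,
       hosts_b = circ_b$gene_id)
}

#' Generate the complete synthetic study bundle
#'
#' One call producing every input the pipeline consumes, with planted
#' ground truth: reference genome and annotation, BSJ candidates and
#' linear reads, expression matrices, miRNAs with planted sites, synthetic
#' orthologs, and the chloroplast locus. Deterministic under
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_bundle` list with elements `config`, `genome`,
#'   `annotation`, `truth`, `bsj`, `origins`, `linear`, `expr`, `mirnas`,
#'   `mirna_sites`, `mirna_expr`, `orthologs`.
#' @export
generate_synthetic_study <- function(config = generator_config()) {
  ref <- generate_reference(config)
  if (config$ics_plant_length > 0) ref <- plant_ics(ref, config$ics_plant_length)
  mir <- simulate_mirnas(ref)
  ref <- mir$ref
  cand <- simulate_bsj_candidates(ref)
  linear <- simulate_linear_reads(ref, cand$bsj)
  expr <- simulate_expression(ref)
  orth <- simulate_orthologs(ref)
  structure(list(config = config, genome = ref$genome,
                 annotation = ref$annotation, truth = ref$truth,
                 bsj = cand$bsj, origins = cand$origins, linear = linear,
                 expr = expr, mirnas = mir$mirnas, mirna_sites = mir$sites,
                 mirna_expr = mir$mirna_expr, orthologs = orth),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to plain-text files
#'
#' FASTA for genomes and miRNAs, GFF3 for annotations, TSV for tables,
#' JSON for the truth records. File contents are byte-deterministic for a
#' fixed bundle.
#'
#' @param bundle A [generate_synthetic_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_genome_fasta(bundle$genome, fp("genome.fasta"))
  write_gff3(bundle$annotation, fp("annotation.gff3"))
  write_genome_fasta(bundle$orthologs$genome_b, fp("species_b_synthetic.fasta"))
  write_gff3(bundle$orthologs$annotation_b, fp("species_b_synthetic.gff3"))
  tsv <- function(df, name) {
    utils::write.table(df, fp(name), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(bundle$bsj, "bsj_candidates.tsv")
  tsv(bundle$linear, "linear_reads.tsv")
  tsv(data.frame(feature = rownames(bundle$expr$circ_counts),
                 bundle$expr$circ_counts, check.names = FALSE), "circ_counts.tsv")
  tsv(data.frame(feature = rownames(bundle$expr$gene_counts),
                 bundle$expr$gene_counts, check.names = FALSE), "gene_counts.tsv")
  tsv(bundle$expr$samples, "expression_samples.tsv")
  mir <- Biostrings::DNAStringSet(stats::setNames(bundle$mirnas$sequence,
                                                  bundle$mirnas$mirna_id))
  Biostrings::writeXStringSet(mir, fp("mirnas.fasta"), width = 60L)
  tsv(bundle$mirna_sites, "mirna_sites_truth.tsv")
  tsv(bundle$orthologs$ortholog_map, "ortholog_pairs.tsv")
  tsv(bundle$orthologs$circ_b, "species_b_circ.tsv")
  truth <- list(circ = bundle$truth$circ, roles = bundle$truth$roles,
                cp = bundle$truth$cp, origins = bundle$origins,
                expression_pairs = bundle$expr$pairs,
                ortholog_categories = bundle$orthologs$truth)
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "columns",
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a count matrix TSV written by [write_synthetic_bundle()]
#' @param path TSV with a leading `feature` column.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  m
}
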