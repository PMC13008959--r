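## Synthetic study generator: a toy multi-gene nuclear genome plus
## chloroplast, planted circRNAs of the three structural types,
## score-stratified artifact BSJs, expression matrices with configurable
## circRNA-host correlation, planted miRNA binding sites, synthetic
## orthologs with known conservation categories, and a psbA-like locus with
## 3'-terminus-clustered BSJs. Every emitted record is keyed in the truth
## tables, and everything is deterministic under the configured seed.

#' Generator configuration
#'
#' Defaults encode the emulated study design: five conditions (CK plus
#' cold, heat, salt, UV-B) with two replicates per library type; 60 true
#' circRNAs (20 multi-exonic, 20 single-exonic, 20 intronic), each with its
#' own host gene; 40 low-score artifacts (half intergenic) plus 5
#' high-score ultra-long artifacts; host genes with more exons (8-16),
#' more isoforms (2-4) and longer introns (500-1000 bp) than non-hosts
#' (2-6 exons, 1 isoform, 50-200 bp), mirroring the biogenesis
#' propensities under study; a latent circRNA-host correlation of 0.34;
#' and a chloroplast whose BSJ read mass dominates the pool with both
#' endpoints of the clustered junctions in the psbA-like gene's 3' window.
#'
#' @param seed Master RNG seed (all stage seeds are derived from it).
#' @param conditions Condition labels; the first is the control.
#' @param n_reps Replicates per condition and library type.
#' @param n_true_circ Named counts per planted type
#'   (multi/single/intronic).
#' @param n_nonhost_genes Number of genes without circRNAs.
#' @param host_exon_range,nonhost_exon_range Exon-count ranges.
#' @param host_isoform_range,nonhost_isoform_range Isoform-count ranges.
#' @param host_intron_range,nonhost_intron_range Intron length ranges (bp).
#' @param exon_length_range Exon length range (bp).
#' @param intergenic_gap_range Intergenic gap range (bp).
#' @param n_chromosomes Nuclear chromosome count.
#' @param n_artifact,artifact_intergenic_fraction,n_ultralong Artifact
#'   BSJ counts and the fraction placed intergenically.
#' @param ultralong_span_range Span range for ultra-long artifacts (bp).
#' @param detection_prob Probability a true circRNA is detected in a given
#'   condition (RNase R libraries).
#' @param control_detect_prob Probability of an additional control-library
#'   record per detected condition/replicate.
#' @param reads_lambda Poisson mean for BSJ read support (plus one).
#' @param linear_lambda_rnaser,linear_lambda_control Poisson means of
#'   linear reads at BSJ sites per library type.
#' @param true_score_shape,control_true_score_shape,artifact_score_shape
#'   Beta shape pairs of the simulated reliability scores.
#' @param n_expr_reps Replicates per condition in the expression matrices.
#' @param circ_mean,gene_mean Mean counts of circRNAs and genes.
#' @param sdlog Log-scale biological standard deviation.
#' @param rho Latent circRNA-host correlation.
#' @param de_plan Named counts of planted DE patterns
#'   (Reversed/Coordinated/HostStable/CircStable).
#' @param de_log2fc Planted |log2 fold change|.
#' @param n_mirna,mirna_length miRNA count and length (nt).
#' @param circ_targets_per_mirna,mrna_targets_per_mirna Planted perfect
#'   sites per miRNA.
#' @param ics_plant_length Length of a perfect ICS planted in every
#'   circRNA flank pair (0 = none, the default: the emulated system shows
#'   no ICS enrichment).
#' @param ortholog_mix Named counts of planted conservation categories.
#' @param ortholog_shift Splice-site shift (nt) for non-conserved sites;
#'   must exceed the downstream classification tolerance.
#' @param n_extra_ortholog_pairs Additional non-host ortholog pairs
#'   (the hypergeometric universe).
#' @param cp_contig,cp_genome_length,cp_gene_start,cp_gene_length,cp_gene_strand
#'   Chloroplast toy layout (single intronless psbA-like gene).
#' @param cp_window_frac 3'-terminal window as a fraction of gene length.
#' @param n_clustered_bsj,n_uniform_bsj Chloroplast junctions with both
#'   endpoints in the 3' window vs placed uniformly.
#' @param cp_reads_lambda,cp_control_reads_lambda Poisson read means for
#'   chloroplast junctions per library type.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1,
    conditions = c("CK", "cold", "heat", "salt", "UVB"),
    n_reps = 2,
    n_true_circ = c(multi = 20, single = 20, intronic = 20),
    n_nonhost_genes = 300,
    host_exon_range = c(8, 16), nonhost_exon_range = c(2, 6),
    host_isoform_range = c(2, 4), nonhost_isoform_range = c(1, 1),
    host_intron_range = c(500, 1000), nonhost_intron_range = c(50, 200),
    exon_length_range = c(100, 300),
    intergenic_gap_range = c(400, 1200),
    n_chromosomes = 3,
    n_artifact = 40, artifact_intergenic_fraction = 0.5, n_ultralong = 5,
    ultralong_span_range = c(120000, 200000),
    detection_prob = 0.7, control_detect_prob = 0.5,
    reads_lambda = 5,
    linear_lambda_rnaser = 1, linear_lambda_control = 25,
    true_score_shape = c(8, 2), control_true_score_shape = c(12, 2),
    artifact_score_shape = c(1.5, 12),
    n_expr_reps = 2, circ_mean = 200, gene_mean = 400,
    sdlog = 0.5, rho = 0.34,
    de_plan = c(Reversed = 6, Coordinated = 4, HostStable = 4, CircStable = 2),
    de_log2fc = 2.5,
    n_mirna = 8, mirna_length = 21,
    circ_targets_per_mirna = 3, mrna_targets_per_mirna = 4,
    ics_plant_length = 0,
    ortholog_mix = c(Accordant = 5, `Half-accordant` = 5, Unaccordant = 5),
    ortholog_shift = 50, n_extra_ortholog_pairs = 20,
    cp_contig = "ChrC", cp_genome_length = 4000,
    cp_gene_start = 1400, cp_gene_length = 1200, cp_gene_strand = "-",
    cp_window_frac = 0.2, n_clustered_bsj = 20, n_uniform_bsj = 10,
    cp_reads_lambda = 40, cp_control_reads_lambda = 3) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[grep("^n_", names(cfg))]) >= 0),
            artifact_intergenic_fraction >= 0, artifact_intergenic_fraction <= 1,
            rho >= -1, rho <= 1,
            cp_window_frac > 0, cp_window_frac <= 1,
            mirna_length >= 19, mirna_length <= 25,
            n_expr_reps * length(conditions) >= 3)
  if (host_exon_range[1] < 4) stop("host genes need at least 4 exons for planting")
  if (host_intron_range[1] < 100) stop("host introns too short for intronic planting")
  structure(cfg, class = "generator_config")
}

# truncated Beta draw: redraw until inside (lo, hi]
rbeta_trunc <- function(n, shape, lo = 0, hi = 1) {
  x <- stats::rbeta(n, shape[1], shape[2])
  bad <- x <= lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rbeta(sum(bad), shape[1], shape[2])
    bad <- x <= lo | x > hi
  }
  x
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

genome_replace <- function(genome, contig, pos0, replacement) {
  s <- genome$contigs[[contig]]
  substr(s, pos0 + 1L, pos0 + nchar(replacement)) <- replacement
  genome$contigs[[contig]] <- s
  genome
}

#' Generate the synthetic reference (genome, annotation, planted truth)
#'
#' Lays out host and non-host genes along toy chromosomes, plants one
#' circRNA of the configured type per host gene, and appends a chloroplast
#' contig with a single intronless psbA-like gene carrying 3'-clustered and
#' uniform junctions.
#'
#' @param config A [generator_config()].
#' @return List: `genome` ([genome_sequence()]), `annotation`
#'   ([annotation_set()]), `truth` (planted circRNAs, gene roles,
#'   chloroplast junctions), `config`.
#' @export
generate_reference <- function(config = generator_config()) {
  set.seed(config$seed)
  n_host <- sum(config$n_true_circ)
  n_genes <- n_host + config$n_nonhost_genes
  roles <- sample(c(rep("multi", config$n_true_circ[["multi"]]),
                    rep("single", config$n_true_circ[["single"]]),
                    rep("intronic", config$n_true_circ[["intronic"]]),
                    rep("nonhost", config$n_nonhost_genes)))
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n_genes))
  chrom_names <- sprintf("Chr%02d", seq_len(config$n_chromosomes))

  genes <- list(); transcripts <- list(); exons <- list()
  circ_truth <- list()
  cursor <- stats::setNames(rep(0L, config$n_chromosomes), chrom_names)
  rint <- function(range, n = 1) {
    if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
  }

  for (g in seq_len(n_genes)) {
    role <- roles[g]
    host <- role != "nonhost"
    chrom <- chrom_names[chrom_of[g]]
    gid <- sprintf("gene%03d", g)
    n_ex <- rint(if (host) config$host_exon_range else config$nonhost_exon_range)
    ex_len <- rint(config$exon_length_range, n_ex)
    in_len <- if (n_ex > 1) {
      rint(if (host) config$host_intron_range else config$nonhost_intron_range, n_ex - 1)
    } else integer(0)
    gap <- rint(config$intergenic_gap_range)
    start <- cursor[[chrom]] + gap
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len
    gend <- ex_end[n_ex]
    cursor[[chrom]] <- gend
    strand <- if (host) "+" else sample(c("+", "-"), 1)

    genes[[g]] <- data.frame(gene_id = gid, contig = chrom, start = start,
                             end = gend, strand = strand, stringsAsFactors = FALSE)
    n_iso <- rint(if (host) config$host_isoform_range else config$nonhost_isoform_range)
    if (n_ex < 3) n_iso <- 1
    iso_exons <- list(seq_len(n_ex))
    if (n_iso > 1) {
      skippable <- 2:(n_ex - 1)
      skip <- sample(skippable, min(n_iso - 1, length(skippable)))
      for (s in skip) iso_exons[[length(iso_exons) + 1]] <- setdiff(seq_len(n_ex), s)
      n_iso <- length(iso_exons)
    }
    for (k in seq_len(n_iso)) {
      tid <- sprintf("%s.t%d", gid, k)
      transcripts[[length(transcripts) + 1]] <-
        data.frame(transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
      idx <- iso_exons[[k]]
      exons[[length(exons) + 1]] <- data.frame(
        transcript_id = tid, gene_id = gid, contig = chrom,
        start = ex_start[idx], end = ex_end[idx], strand = strand,
        stringsAsFactors = FALSE)
    }

    if (host) {
      tid <- sprintf("%s.t1", gid)
      if (role == "multi") {
        span <- sample(2:min(4, n_ex - 2), 1)
        i <- sample(2:(n_ex - span), 1)
        j <- i + span - 1L
        acc <- ex_start[i]; don <- ex_end[j]
        extra <- list(exon_from = i, exon_to = j, intron_idx = NA_integer_)
        type <- "multi-exonic"
      } else if (role == "single") {
        e <- sample(2:(n_ex - 1), 1)
        acc <- ex_start[e]; don <- ex_end[e]
        extra <- list(exon_from = e, exon_to = e, intron_idx = NA_integer_)
        type <- "single-exonic"
      } else {
        m <- sample(seq_len(n_ex - 1), 1)
        istart <- ex_end[m]; iend <- ex_start[m + 1]
        acc <- istart + 20L; don <- iend - 20L
        extra <- list(exon_from = NA_integer_, exon_to = NA_integer_, intron_idx = m)
        type <- "intronic"
      }
      circ_truth[[length(circ_truth) + 1]] <- data.frame(
        circ_id = make_circ_id(chrom, acc, don, strand),
        contig = chrom, acceptor = acc, donor = don, strand = strand,
        circ_type = type, host_gene = gid, transcript_id = tid,
        exon_from = extra$exon_from, exon_to = extra$exon_to,
        intron_idx = extra$intron_idx, stringsAsFactors = FALSE)
    }
  }

  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, transcripts)
  exons <- do.call(rbind, exons)
  circ_truth <- do.call(rbind, circ_truth)

  # chloroplast: one intronless psbA-like gene
  cp_start <- config$cp_gene_start
  cp_end <- cp_start + config$cp_gene_length
  stopifnot(cp_end <= config$cp_genome_length)
  genes <- rbind(genes, data.frame(
    gene_id = "psbA_syn", contig = config$cp_contig, start = cp_start,
    end = cp_end, strand = config$cp_gene_strand, stringsAsFactors = FALSE))
  transcripts <- rbind(transcripts, data.frame(
    transcript_id = "psbA_syn.t1", gene_id = "psbA_syn", stringsAsFactors = FALSE))
  exons <- rbind(exons, data.frame(
    transcript_id = "psbA_syn.t1", gene_id = "psbA_syn",
    contig = config$cp_contig, start = cp_start, end = cp_end,
    strand = config$cp_gene_strand, stringsAsFactors = FALSE))

  # chloroplast junctions: clustered in the 3' window, or uniform
  win_size <- floor(config$cp_window_frac * config$cp_gene_length)
  win <- terminal_window(cp_start, cp_end, config$cp_gene_strand, win_size)
  draw_junction <- function(lo, hi, min_span = 30L) {
    repeat {
      p <- sort(sample(lo:(hi - 1L), 2))
      if (p[2] - p[1] >= min_span) return(p)
    }
  }
  seen <- character(0)
  cp_rows <- list()
  for (i in seq_len(config$n_clustered_bsj + config$n_uniform_bsj)) {
    clustered <- i <= config$n_clustered_bsj
    repeat {
      p <- if (clustered) draw_junction(win$start, win$end)
           else draw_junction(cp_start, cp_end, min_span = 100L)
      id <- make_circ_id(config$cp_contig, p[1], p[2], config$cp_gene_strand)
      if (!id %in% seen) break
    }
    seen <- c(seen, id)
    cp_rows[[i]] <- data.frame(
      circ_id = id, contig = config$cp_contig, acceptor = p[1], donor = p[2],
      strand = config$cp_gene_strand,
      origin = if (clustered) "cp_clustered" else "cp_uniform",
      stringsAsFactors = FALSE)
  }
  cp_truth <- do.call(rbind, cp_rows)

  chrom_len <- cursor + 2000L
  contigs <- vapply(chrom_names, function(cc) random_seq(chrom_len[[cc]]), character(1))
  contigs[[config$cp_contig]] <- random_seq(config$cp_genome_length)
  genome <- genome_sequence(contigs)

  annotation <- annotation_set(genes, transcripts, exons)
  roles_df <- data.frame(gene_id = genes$gene_id[seq_len(n_genes)],
                         role = roles, stringsAsFactors = FALSE)
  list(genome = genome, annotation = annotation,
       truth = list(circ = circ_truth, roles = roles_df,
                    hosts = circ_truth$host_gene, cp = cp_truth,
                    cp_window = win),
       config = config)
}

#' Simulate the BSJ candidate table
#'
#' True circRNAs receive scores above the RNase R retention threshold with
#' read support across a random subset of conditions (plus optional
#' control-library records); artifacts receive low scores with the
#' configured intergenic fraction; ultra-long artifacts receive credible
#' scores but spans beyond the exclusion cutoff; chloroplast junctions are
#' emitted with dominant read mass in RNase R libraries.
#'
#' @param ref Output of [generate_reference()].
#' @return List: `bsj` (candidate data.frame incl. chloroplast rows),
#'   `origins` (data.frame circ_id, origin in true / artifact / ultralong /
#'   cp_clustered / cp_uniform).
#' @export
simulate_bsj_candidates <- function(ref) {
  config <- ref$config
  set.seed(config$seed + 1L)
  conds <- config$conditions
  row_acc <- list()
  add <- function(contig, acc, don, strand, score, reads, cond, rep, lib) {
    row_acc[[length(row_acc) + 1]] <<- data.frame(
      contig = contig, acceptor = acc, donor = don, strand = strand,
      score = score, bsj_reads = reads,
      sample_id = sprintf("%s_r%d_%s", cond, rep, lib),
      condition = cond, library = lib, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(ref$truth$circ))) {
    tc <- ref$truth$circ[i, ]
    present <- conds[stats::runif(length(conds)) < config$detection_prob]
    if (!length(present)) present <- sample(conds, 1)
    for (cond in present) {
      for (r in seq_len(config$n_reps)) {
        add(tc$contig, tc$acceptor, tc$donor, tc$strand,
            rbeta_trunc(1, config$true_score_shape, lo = config$rnaser_floor %||% 0.1),
            stats::rpois(1, config$reads_lambda) + 1L, cond, r, "rnaser")
        if (stats::runif(1) < config$control_detect_prob) {
          add(tc$contig, tc$acceptor, tc$donor, tc$strand,
              stats::rbeta(1, config$control_true_score_shape[1],
                           config$control_true_score_shape[2]),
              stats::rpois(1, 1) + 1L, cond, r, "control")
        }
      }
    }
  }

  # intergenic gaps: complement of gene spans per nuclear chromosome
  origins <- data.frame(circ_id = ref$truth$circ$circ_id, origin = "true",
                        stringsAsFactors = FALSE)
  nuc <- ref$annotation$genes[ref$annotation$genes$contig != config$cp_contig, ]
  n_inter <- round(config$n_artifact * config$artifact_intergenic_fraction)
  for (a in seq_len(config$n_artifact)) {
    intergenic <- a <= n_inter
    repeat {
      if (intergenic) {
        # place the acceptor in a gap upstream of a random gene
        gi <- sample(nrow(nuc), 1)
        gap_lo <- if (gi > 1 && nuc$contig[gi - 1] == nuc$contig[gi]) nuc$end[gi - 1] else 0L
        gap_hi <- nuc$start[gi]
        if (gap_hi - gap_lo < 120) next
        acc <- sample(gap_lo:(gap_hi - 100L), 1)
        don <- acc + sample(200:3000, 1)
        if (don > ref$genome$lengths[[nuc$contig[gi]]]) next
        contig <- nuc$contig[gi]
      } else {
        gi <- sample(nrow(nuc), 1)
        glen <- nuc$end[gi] - nuc$start[gi]
        if (glen < 400) next
        off <- sort(sample(seq(7L, glen - 7L), 2))
        if (off[2] - off[1] < 100) next
        acc <- nuc$start[gi] + off[1]; don <- nuc$start[gi] + off[2]
        contig <- nuc$contig[gi]
      }
      strand <- sample(c("+", "-"), 1)
      id <- make_circ_id(contig, acc, don, strand)
      if (!id %in% origins$circ_id) break
    }
    origins <- rbind(origins, data.frame(circ_id = id, origin = "artifact",
                                         stringsAsFactors = FALSE))
    for (k in seq_len(sample(1:2, 1))) {
      cond <- sample(conds, 1); r <- sample(config$n_reps, 1)
      add(contig, acc, don, strand,
          rbeta_trunc(1, config$artifact_score_shape, hi = 0.1), 1L,
          cond, r, "rnaser")
    }
    if (stats::runif(1) < 0.5) {
      cond <- sample(conds, 1); r <- sample(config$n_reps, 1)
      add(contig, acc, don, strand,
          rbeta_trunc(1, c(2, 4), hi = 0.9), 1L, cond, r, "control")
    }
  }

  for (u in seq_len(config$n_ultralong)) {
    if (max(ref$genome$lengths[unique(nuc$contig)]) <=
          config$ultralong_span_range[1] + 10) {
      stop("chromosomes too short for the configured ultra-long span range")
    }
    repeat {
      chrom <- sample(unique(nuc$contig), 1)
      clen <- ref$genome$lengths[[chrom]]
      span <- sample(config$ultralong_span_range[1]:config$ultralong_span_range[2], 1)
      if (clen <= span + 10) next
      acc <- sample(0:(clen - span - 1L), 1)
      don <- acc + span
      strand <- sample(c("+", "-"), 1)
      id <- make_circ_id(chrom, acc, don, strand)
      if (!id %in% origins$circ_id) break
    }
    origins <- rbind(origins, data.frame(circ_id = id, origin = "ultralong",
                                         stringsAsFactors = FALSE))
    cond <- sample(conds, 1)
    add(chrom, acc, don, strand,
        rbeta_trunc(1, config$true_score_shape, lo = 0.1),
        stats::rpois(1, config$reads_lambda) + 1L, cond, 1L, "rnaser")
  }

  for (i in seq_len(nrow(ref$truth$cp))) {
    cp <- ref$truth$cp[i, ]
    for (cond in conds) {
      for (r in seq_len(config$n_reps)) {
        if (stats::runif(1) < 0.9) {
          add(cp$contig, cp$acceptor, cp$donor, cp$strand,
              rbeta_trunc(1, config$true_score_shape, lo = 0.1),
              stats::rpois(1, config$cp_reads_lambda) + 1L, cond, r, "rnaser")
        }
        if (stats::runif(1) < 0.3) {
          add(cp$contig, cp$acceptor, cp$donor, cp$strand,
              stats::rbeta(1, config$control_true_score_shape[1],
                           config$control_true_score_shape[2]),
              stats::rpois(1, config$cp_control_reads_lambda) + 1L,
              cond, r, "control")
        }
      }
    }
  }
  origins <- rbind(origins, data.frame(circ_id = ref$truth$cp$circ_id,
                                       origin = ref$truth$cp$origin,
                                       stringsAsFactors = FALSE))

  bsj <- do.call(rbind, row_acc)
  rownames(bsj) <- NULL
  validate_bsj(bsj)
  list(bsj = bsj, origins = origins)
}

#' Simulate linear reads at every emitted BSJ site
#'
#' RNase R libraries carry few linear reads (the exonuclease removed
#' them); control libraries carry many, so circular-to-linear ratios
#' separate the two library types.
#'
#' @param ref Output of [generate_reference()].
#' @param bsj BSJ candidate data.frame.
#' @return data.frame: site key columns, `sample_id`, `library`,
#'   `linear_reads`.
#' @export
simulate_linear_reads <- function(ref, bsj) {
  config <- ref$config
  set.seed(config$seed + 2L)
  key <- !duplicated(bsj[, c("contig", "acceptor", "donor", "strand",
                             "sample_id")])
  sites <- bsj[key, c("contig", "acceptor", "donor", "strand", "sample_id",
                      "condition", "library")]
  lambda <- ifelse(sites$library == "rnaser",
                   config$linear_lambda_rnaser, config$linear_lambda_control)
  sites$linear_reads <- stats::rpois(nrow(sites), lambda)
  rownames(sites) <- NULL
  sites
}

#' Simulate circRNA and host-gene expression count matrices
#'
#' Each circRNA-host pair draws a latent bivariate normal profile with the
#' target correlation on the log scale, exponentiated into Poisson means;
#' planted differential-expression pairs add condition-specific fold
#' changes realizing the configured Reversed / Coordinated / HostStable /
#' CircStable patterns.
#'
#' @param ref Output of [generate_reference()].
#' @param rho Override of the configured latent correlation.
#' @param n_reps Override of replicates per condition.
#' @param with_de Plant the configured DE patterns (default TRUE).
#' @return List: `circ_counts`, `gene_counts` (features x samples),
#'   `samples` (sample_id, condition), `pairs` (circ_id, gene_id, rho,
#'   de_pattern, de_condition).
#' @export
simulate_expression <- function(ref, rho = NULL, n_reps = NULL, with_de = TRUE) {
  config <- ref$config
  set.seed(config$seed + 3L)
  if (is.null(rho)) rho <- config$rho
  if (is.null(n_reps)) n_reps <- config$n_expr_reps
  conds <- config$conditions
  samples <- data.frame(
    sample_id = as.vector(vapply(conds, function(cc) sprintf("%s_e%d", cc, seq_len(n_reps)),
                                 character(n_reps))),
    condition = rep(conds, each = n_reps), stringsAsFactors = FALSE)
  S <- nrow(samples)
  if (S < 3) stop("need at least 3 expression samples")
  tc <- ref$truth$circ
  n_pair <- nrow(tc)

  de_pattern <- rep(NA_character_, n_pair)
  de_condition <- rep(NA_character_, n_pair)
  if (with_de && sum(config$de_plan) > 0) {
    plan <- rep(names(config$de_plan), config$de_plan)
    if (length(plan) > n_pair) plan <- plan[seq_len(n_pair)]
    de_pattern[seq_along(plan)] <- plan
    de_condition[seq_along(plan)] <- rep_len(setdiff(conds, conds[1]), length(plan))
  }
  sdl <- config$sdlog
  lfc <- config$de_log2fc
  circ_counts <- matrix(0L, n_pair, S, dimnames = list(tc$circ_id, samples$sample_id))
  gene_counts_host <- matrix(0L, n_pair, S, dimnames = list(tc$host_gene, samples$sample_id))
  for (i in seq_len(n_pair)) {
    z1 <- stats::rnorm(S)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(S)
    lam_c <- config$circ_mean * exp(sdl * z1 - sdl^2 / 2)
    lam_g <- config$gene_mean * exp(sdl * z2 - sdl^2 / 2)
    if (!is.na(de_pattern[i])) {
      idx <- samples$condition == de_condition[i]
      dir <- if (i %% 2 == 0) -1 else 1
      mult_c <- 2^(dir * lfc); mult_g_rev <- 2^(-dir * lfc); mult_g_coord <- mult_c
      switch(de_pattern[i],
             Reversed = { lam_c[idx] <- lam_c[idx] * mult_c
                          lam_g[idx] <- lam_g[idx] * mult_g_rev },
             Coordinated = { lam_c[idx] <- lam_c[idx] * mult_c
                             lam_g[idx] <- lam_g[idx] * mult_g_coord },
             HostStable = { lam_c[idx] <- lam_c[idx] * mult_c },
             CircStable = { lam_g[idx] <- lam_g[idx] * mult_c })
    }
    circ_counts[i, ] <- stats::rpois(S, lam_c)
    gene_counts_host[i, ] <- stats::rpois(S, lam_g)
  }
  nonhost <- ref$truth$roles$gene_id[ref$truth$roles$role == "nonhost"]
  gene_counts_non <- t(vapply(nonhost, function(g) {
    stats::rpois(S, config$gene_mean * exp(sdl * stats::rnorm(S) - sdl^2 / 2))
  }, integer(S)))
  colnames(gene_counts_non) <- samples$sample_id
  gene_counts <- rbind(gene_counts_host, gene_counts_non)
  pairs <- data.frame(circ_id = tc$circ_id, gene_id = tc$host_gene,
                      rho = rho, de_pattern = de_pattern,
                      de_condition = de_condition, stringsAsFactors = FALSE)
  list(circ_counts = circ_counts, gene_counts = gene_counts,
       samples = samples, pairs = pairs)
}
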