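## Biogenesis feature statistics: intron-length classes, host-gene
## exon/isoform propensity, exact tests, inverted-complementary-sequence
## (ICS) detection, and a k-mer repeat-density proxy.

#' Intron length classes: flanking, circRNA-internal, genome-wide
#'
#' Flanking introns are the intron immediately upstream of the circle's
#' acceptor and immediately downstream of its donor (on the matched
#' transcript, where they exist); internal introns lie between the spanned
#' exons; the genome-wide class is every distinct derived intron.
#'
#' @param classification Output of [classify_circs()] (exonic circles are
#'   used; intronic/unclassified circles contribute nothing).
#' @param annotation An [annotation_set()].
#' @return data.frame with columns `class`
#'   (flanking / circ_internal / genome_wide) and `length` (nt).
#' @export
intron_length_classes <- function(classification, annotation) {
  flank <- integer(0); internal <- integer(0)
  exonic <- classification[classification$circ_type %in%
                             c("multi-exonic", "single-exonic"), , drop = FALSE]
  for (k in seq_len(nrow(exonic))) {
    t <- exonic$transcript_id[k]
    intr <- transcript_introns(annotation, t)
    if (nrow(intr) == 0) next
    i <- exonic$exon_from[k]; j <- exonic$exon_to[k]
    # intron m sits between exon m and exon m+1
    if (i - 1 >= 1 && i - 1 <= nrow(intr)) {
      flank <- c(flank, intr$end[i - 1] - intr$start[i - 1])
    }
    if (j >= 1 && j <= nrow(intr)) {
      flank <- c(flank, intr$end[j] - intr$start[j])
    }
    if (j > i) {
      idx <- i:(j - 1)
      internal <- c(internal, intr$end[idx] - intr$start[idx])
    }
  }
  gw <- unique(annotation$introns[, c("contig", "start", "end")])
  gw_len <- gw$end - gw$start
  data.frame(
    class = c(rep("flanking", length(flank)),
              rep("circ_internal", length(internal)),
              rep("genome_wide", length(gw_len))),
    length = c(flank, internal, gw_len),
    stringsAsFactors = FALSE
  )
}

#' Host vs non-host gene feature comparison
#'
#' Compares exon counts (max over isoforms) and isoform counts between
#' circRNA host genes and all other genes, with two-sided Wilcoxon rank-sum
#' p-values.
#'
#' @param annotation An [annotation_set()].
#' @param host_ids Character vector of host gene ids.
#' @return List with `summary` (per group x feature mean/median),
#'   `p_exons`, `p_isoforms`.
#' @export
host_feature_comparison <- function(annotation, host_ids) {
  feat <- annotation$gene_features
  is_host <- feat$gene_id %in% host_ids
  if (!any(is_host) || all(is_host)) stop("both host and non-host genes required")
  smry <- do.call(rbind, lapply(c("n_exons_max", "n_isoforms"), function(col) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(h) {
      v <- feat[[col]][is_host == h]
      data.frame(feature = col, group = if (h) "host" else "non_host",
                 n = length(v), mean = mean(v), median = stats::median(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(smry) <- NULL
  wp <- function(col) {
    stats::wilcox.test(feat[[col]][is_host], feat[[col]][!is_host],
                       exact = FALSE, correct = FALSE)$p.value
  }
  list(summary = smry, p_exons = wp("n_exons_max"), p_isoforms = wp("n_isoforms"))
}

#' Fraction of genes producing circRNAs, per feature bin
#'
#' @param annotation An [annotation_set()].
#' @param host_ids Host gene ids.
#' @param feature `"exons"` (exon count, max over isoforms) or
#'   `"isoforms"`.
#' @param breaks Bin breaks passed to [cut()] (right-open); default
#'   unit bins covering the observed range.
#' @return data.frame: `bin`, `n_genes`, `n_hosts`, `fraction` (NA for
#'   empty bins, not 0).
#' @export
propensity_by_bin <- function(annotation, host_ids,
                              feature = c("exons", "isoforms"),
                              breaks = NULL) {
  feature <- match.arg(feature)
  v <- if (feature == "exons") annotation$gene_features$n_exons_max
       else annotation$gene_features$n_isoforms
  is_host <- annotation$gene_features$gene_id %in% host_ids
  if (is.null(breaks)) breaks <- seq(min(v), max(v) + 1L)
  bin <- cut(v, breaks = breaks, right = FALSE, include.lowest = TRUE)
  n_genes <- as.integer(table(bin))
  n_hosts <- as.integer(table(bin[is_host]))
  data.frame(bin = levels(bin), n_genes = n_genes, n_hosts = n_hosts,
             fraction = ifelse(n_genes > 0, n_hosts / n_genes, NA_real_),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric point
#' probabilities not exceeding that of the observed table (with the usual
#' 1e-7 relative slack for floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers")
  }
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  p <- sum(d[d <= d_obs * (1 + 1e-7)])
  min(1, p)
}

#' Best inverted complementary sequence (ICS) between two flanking introns
#'
#' Finds the highest-scoring local alignment between the upstream intron
#' and the reverse complement of the downstream intron (match +1, mismatch
#' -1, gap -2), i.e. the best reverse-complementary pairing between the two
#' flanks. Matches shorter than `min_length` alignment columns or below
#' `min_identity` are rejected.
#'
#' @param upstream_seq,downstream_seq Intron sequences (genomic
#'   orientation).
#' @param min_length Minimum alignment length in columns (default 10).
#' @param min_identity Minimum identity (matches/columns, default 0.8).
#' @param match,mismatch,gap Scoring parameters.
#' @return A list (`score`, `up_start`, `up_end`, `down_start`, `down_end`,
#'   `match_length`, `identity`; coordinates 0-based half-open on the input
#'   sequences) or `NULL` when no qualifying match exists.
#' @export
find_ics <- function(upstream_seq, downstream_seq, min_length = 10,
                     min_identity = 0.8, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(upstream_seq) || !nzchar(downstream_seq)) return(NULL)
  rc <- reverse_complement(downstream_seq)
  al <- cpp_local_align(upstream_seq, rc, match, mismatch, gap)
  if (!isTRUE(al$found)) return(NULL)
  if (al$n_columns < min_length) return(NULL)
  identity <- al$n_matches / al$n_columns
  if (identity < min_identity) return(NULL)
  dn <- nchar(downstream_seq)
  list(score = al$score,
       up_start = al$a_start, up_end = al$a_end,
       down_start = dn - al$b_end, down_end = dn - al$b_start,
       match_length = al$n_columns, identity = identity)
}

#' k-mer repeat-density proxy
#'
#' Fraction of sequence positions covered by at least one k-mer occurring
#' `min_occurrences` or more times within the sequence. A self-contained
#' proxy for repetitive-sequence abundance; not a repeat-family annotation.
#'
#' @param seq Nucleotide string (length >= k).
#' @param k k-mer size (default 13).
#' @param min_occurrences Occurrence threshold (default 2).
#' @return Proportion of covered positions in `[0,1]`.
#' @export
repeat_density <- function(seq, k = 13, min_occurrences = 2) {
  n <- nchar(seq)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("sequence shorter than k")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  counts <- table(kmers)
  rep_start <- starts[counts[kmers] >= min_occurrences]
  covered <- logical(n)
  for (s in rep_start) covered[s:(s + k - 1L)] <- TRUE
  mean(covered)
}

#' ICS and repeat metrics for a set of flanking intron pairs
#'
#' @param flank_pairs List of two-element lists/character vectors
#'   (upstream, downstream intron sequences).
#' @param min_length,min_identity Passed to [find_ics()].
#' @param k,min_occurrences Passed to [repeat_density()].
#' @return data.frame: per pair ICS length (0 when none), identity (0 when
#'   none), and repeat density over the concatenated flanks.
#' @export
ics_metric_table <- function(flank_pairs, min_length = 10, min_identity = 0.8,
                             k = 13, min_occurrences = 2) {
  rows <- lapply(flank_pairs, function(p) {
    up <- p[[1]]; dn <- p[[2]]
    ics <- find_ics(up, dn, min_length, min_identity)
    both <- paste0(up, dn)
    data.frame(
      ics_length = if (is.null(ics)) 0L else ics$match_length,
      ics_identity = if (is.null(ics)) 0 else ics$identity,
      repeat_density = if (nchar(both) >= k) repeat_density(both, k, min_occurrences) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flanking intron sequence pairs for classified circRNAs
#'
#' @param classification Output of [classify_circs()].
#' @param annotation An [annotation_set()].
#' @param genome A [genome_sequence()].
#' @return Named list (by circ_id) of (upstream, downstream) sequence
#'   pairs; only exonic circles with both flanking introns present
#'   contribute.
#' @export
circ_flank_pairs <- function(classification, annotation, genome) {
  out <- list()
  exonic <- classification[classification$circ_type %in%
                             c("multi-exonic", "single-exonic"), , drop = FALSE]
  for (kk in seq_len(nrow(exonic))) {
    t <- exonic$transcript_id[kk]
    intr <- transcript_introns(annotation, t)
    i <- exonic$exon_from[kk]; j <- exonic$exon_to[kk]
    if (i - 1 < 1 || j > nrow(intr)) next
    up <- genome_subseq(genome, intr$contig[i - 1], intr$start[i - 1], intr$end[i - 1])
    dn <- genome_subseq(genome, intr$contig[j], intr$start[j], intr$end[j])
    out[[exonic$circ_id[kk]]] <- list(up, dn)
  }
  out
}

#' Flanking intron pairs for random control exons
#'
#' Samples internal exons (flanked on both sides) from transcripts of
#' non-host genes, without replacement, deterministically under the seed.
#'
#' @param annotation An [annotation_set()].
#' @param genome A [genome_sequence()].
#' @param host_ids Host gene ids to exclude.
#' @param n_controls Number of control exons.
#' @param seed RNG seed.
#' @return List of (upstream, downstream) sequence pairs.
#' @export
control_flank_pairs <- function(annotation, genome, host_ids, n_controls, seed = 1) {
  cand <- list()
  txs <- annotation$transcripts[!annotation$transcripts$gene_id %in% host_ids, ]
  for (t in txs$transcript_id) {
    ex <- transcript_exons(annotation, t)
    if (nrow(ex) < 3) next
    for (i in 2:(nrow(ex) - 1)) cand[[length(cand) + 1]] <- c(t, i)
  }
  if (length(cand) < n_controls) {
    stop("insufficient internal control exons: have ", length(cand),
         ", need ", n_controls)
  }
  set.seed(seed)
  pick <- sample(length(cand), n_controls)
  lapply(cand[pick], function(ci) {
    intr <- transcript_introns(annotation, ci[1])
    i <- as.integer(ci[2])
    up <- genome_subseq(genome, intr$contig[i - 1], intr$start[i - 1], intr$end[i - 1])
    dn <- genome_subseq(genome, intr$contig[i], intr$start[i], intr$end[i])
    list(up, dn)
  })
}

#' Compare ICS/repeat metrics between circRNA flanks and controls
#'
#' Two-sided Wilcoxon rank-sum p-value per metric.
#'
#' @param circ_metrics,control_metrics Outputs of [ics_metric_table()].
#' @return List of p-values (`p_ics_length`, `p_ics_identity`,
#'   `p_repeat_density`) and the two group medians per metric.
#' @export
compare_ics_metrics <- function(circ_metrics, control_metrics) {
  one <- function(col) {
    x <- circ_metrics[[col]]; y <- control_metrics[[col]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- if (length(x) && length(y) &&
             (stats::var(c(x, y)) > 0)) {
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    } else 1
    list(p = p, median_circ = stats::median(x), median_control = stats::median(y))
  }
  a <- one("ics_length"); b <- one("ics_identity"); d <- one("repeat_density")
  list(p_ics_length = a$p, p_ics_identity = b$p, p_repeat_density = d$p,
       medians = data.frame(
         metric = c("ics_length", "ics_identity", "repeat_density"),
         circ = c(a$median_circ, b$median_circ, d$median_circ),
         control = c(a$median_control, b$median_control, d$median_control)))
}

#' ICS control comparison for a classified circRNA set
#'
#' End-to-end: extract circRNA flanking-intron pairs, sample matched
#' control exon flanks, compute ICS and repeat metrics for both, and
#' compare.
#'
#' @param classification Output of [classify_circs()].
#' @param annotation An [annotation_set()].
#' @param genome A [genome_sequence()].
#' @param host_ids Host gene ids (controls are drawn outside these).
#' @param n_controls Number of control exons (default: number of circ
#'   flank pairs).
#' @param seed RNG seed for control sampling.
#' @param ... Passed to [ics_metric_table()].
#' @return List: `circ_metrics`, `control_metrics`, `comparison`.
#' @export
ics_control_comparison <- function(classification, annotation, genome,
                                   host_ids, n_controls = NULL, seed = 1, ...) {
  circ_pairs <- circ_flank_pairs(classification, annotation, genome)
  if (length(circ_pairs) == 0) stop("no circRNA with both flanking introns")
  if (is.null(n_controls)) n_controls <- length(circ_pairs)
  ctrl_pairs <- control_flank_pairs(annotation, genome, host_ids, n_controls, seed)
  cm <- ics_metric_table(circ_pairs, ...)
  km <- ics_metric_table(ctrl_pairs, ...)
  list(circ_metrics = cm, control_metrics = km,
       comparison = compare_ics_metrics(cm, km))
}
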