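# Shared fixtures and independent reference implementations (oracles).
# The default synthetic bundle and its pipeline report are generated once
# per session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_synthetic_study(generator_config(seed = 11))
  }
  .fixture_env$bundle
}

# reduced study used where full scale adds nothing to the property checked
small_config <- function(seed = 1) {
  generator_config(
    seed = seed,
    n_true_circ = c(multi = 5, single = 5, intronic = 5),
    n_nonhost_genes = 12,
    n_artifact = 10, n_ultralong = 0,  # the small genome cannot host ultra-long spans
    n_mirna = 3,
    circ_targets_per_mirna = 2, mrna_targets_per_mirna = 2,
    ortholog_mix = c(Accordant = 2, `Half-accordant` = 2, Unaccordant = 2),
    n_extra_ortholog_pairs = 5,
    n_clustered_bsj = 8, n_uniform_bsj = 4)
}

default_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- run_pipeline(default_bundle())
  }
  .fixture_env$report
}

# a small two-gene annotation used across unit tests:
# geneA: + strand, 5 exons of length 100 at starts 100,300,500,700,900
# geneB: - strand, 2 exons
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"),
    contig = c("chr1", "chr1"),
    start = c(100L, 2000L), end = c(1000L, 2500L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("geneA.t1", "geneB.t1"),
    gene_id = c("geneA", "geneB"), stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(transcript_id = "geneA.t1", gene_id = "geneA", contig = "chr1",
               start = seq(100L, 900L, 200L), end = seq(200L, 1000L, 200L),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(transcript_id = "geneB.t1", gene_id = "geneB", contig = "chr1",
               start = c(2000L, 2300L), end = c(2200L, 2500L),
               strand = "-", stringsAsFactors = FALSE))
  annotation_set(genes, transcripts, exons)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- oracle: factorial-form hypergeometric probability ----------------------
hyper_prob_oracle <- function(a, m, n, k) {
  exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
}

fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- hyper_prob_oracle(support, m, n, k)
  d_obs <- hyper_prob_oracle(a, m, n, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

hyper_upper_tail_oracle <- function(overlap, N, K, n) {
  support <- max(0, K + n - N):min(K, n)
  sum(hyper_prob_oracle(support[support >= overlap], K, N - K, n))
}

# --- oracle: max-over-substring-pairs global alignment for local score -----
# Best local alignment score as the maximum, over every pair of substrings,
# of the end-to-end (global) alignment score of that pair. Only feasible
# for short strings; an independent route to the Smith-Waterman optimum.
nw_global_score <- function(a, b, match, mismatch, gap) {
  n <- nchar(a); m <- nchar(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
    }
  }
  D[n + 1, m + 1]
}

local_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  best <- 0
  n <- nchar(a); m <- nchar(b)
  for (i1 in 1:n) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in 1:m) for (j2 in j1:m) {
      best <- max(best, nw_global_score(sa, substr(b, j1, j2),
                                        match, mismatch, gap))
    }
  }
  best
}

# Biostrings local alignment score: independent C implementation of the
# same optimum, usable at the full test lengths.
biostrings_local_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = 0, gapExtension = gap)
  max(0, Biostrings::score(aln))
}

# --- oracle: plain-R penalty DP for miRNA site scoring ----------------------
site_penalty_oracle <- function(window, site, weight, mismatch = 1,
                                wobble = 0.5, gap = 2) {
  n <- nchar(window); m <- nchar(site)
  wv <- strsplit(window, "")[[1]]; sv <- strsplit(site, "")[[1]]
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) D[i + 1, 1] <- D[i, 1] + gap * weight[1]
  for (j in seq_len(m)) D[1, j + 1] <- D[1, j] + gap * weight[j]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (wv[i] == sv[j]) 0
             else if ((sv[j] == "C" && wv[i] == "T") ||
                      (sv[j] == "A" && wv[i] == "G")) wobble
             else mismatch
      D[i + 1, j + 1] <- min(D[i, j] + sub * weight[j],
                             D[i, j + 1] + gap * weight[j],
                             D[i + 1, j] + gap * weight[j])
    }
  }
  D[n + 1, m + 1]
}

# exhaustive window scan with greedy non-overlap resolution, in plain R
scan_targets_oracle <- function(mirna_seq, target_seq, cutoff,
                                params = target_scoring_params()) {
  L <- nchar(mirna_seq)
  site <- reverse_complement(mirna_seq)
  w <- rep(1, L)
  mir_pos <- L - seq_len(L) + 1
  w[mir_pos >= params$seed_from & mir_pos <= params$seed_to] <- params$seed_multiplier
  starts <- 0:(nchar(target_seq) - L)
  pen <- vapply(starts, function(s) {
    site_penalty_oracle(substr(target_seq, s + 1, s + L), site, w,
                        params$mismatch, params$wobble, params$gap)
  }, numeric(1))
  keep <- data.frame(position = starts, penalty = pen)
  keep <- keep[keep$penalty <= cutoff, , drop = FALSE]
  keep <- keep[order(keep$penalty, keep$position), , drop = FALSE]
  kp <- integer(0)
  for (i in seq_len(nrow(keep))) {
    p <- keep$position[i]
    if (!any(abs(kp - p) < L)) kp <- c(kp, p)
  }
  sort(kp)
}
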