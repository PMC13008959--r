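mk_bsj <- function(contig = "chr1", acceptor = 100, donor = 500, strand = "+",
                   score = 0.5, bsj_reads = 1, sample_id = "s1",
                   condition = "CK", library = "rnaser") {
  data.frame(contig = contig, acceptor = acceptor, donor = donor,
             strand = strand, score = score, bsj_reads = bsj_reads,
             sample_id = sample_id, condition = condition, library = library,
             stringsAsFactors = FALSE)
}

test_that("context classification requires both endpoints inside one gene", {
  ann <- toy_annotation()  # geneA [100,1000), geneB [2000,2500)
  b1 <- classify_context(mk_bsj(acceptor = 150, donor = 500), ann)
  expect_equal(b1$context, "intragenic")
  expect_equal(b1$host_genes, "geneA")
  # one endpoint outside all genes
  b2 <- classify_context(mk_bsj(acceptor = 150, donor = 5000), ann)
  expect_equal(b2$context, "intergenic")
  # containment in an overlapping-gene layout resolves to the containing gene
  genes <- data.frame(gene_id = c("A", "B"), contig = "chr1",
                      start = c(0L, 900L), end = c(1000L, 2000L), strand = "+")
  tx <- data.frame(transcript_id = c("A.t1", "B.t1"), gene_id = c("A", "B"))
  ex <- data.frame(transcript_id = c("A.t1", "B.t1"), gene_id = c("A", "B"),
                   contig = "chr1", start = c(0L, 900L), end = c(1000L, 2000L),
                   strand = "+")
  ann2 <- annotation_set(genes, tx, ex)
  b3 <- classify_context(mk_bsj(acceptor = 950, donor = 1500), ann2)
  expect_equal(b3$context, "intragenic")
  expect_equal(b3$host_genes, "B")
  # brute-force containment check over all genes agrees
  brute <- genes$gene_id[genes$start <= 950 & 1500 <= genes$end]
  expect_equal(b3$host_genes, paste(sort(brute), collapse = ","))
})

test_that("score stratification partitions candidates with the stated bin rule", {
  bsj <- do.call(rbind, lapply(1:10, function(i) mk_bsj(acceptor = i, score = 0.95)))
  bsj$context <- "intragenic"
  s <- score_stratification(bsj)
  expect_equal(sum(s$n), 10)
  expect_equal(s$n[s$bin_lo == 0.9], 10)
  expect_equal(s$intergenic_fraction[s$bin_lo == 0.9], 0)
  # score 1.0 falls in the last (closed) bin
  b1 <- mk_bsj(score = 1.0); b1$context <- "intergenic"
  s1 <- score_stratification(b1)
  expect_equal(s1$n[s1$bin_lo == 0.9], 1)
  # low-score bin is artifact-enriched on synthetic data
  b <- default_bundle()
  strat <- score_stratification(classify_context(b$bsj, b$annotation))
  lo <- strat$intergenic_fraction[strat$bin_lo == 0]
  hi <- strat$intergenic_fraction[strat$bin_lo == 0.9]
  expect_gt(lo, hi)
})

test_that("retention applies strict dual thresholds and the span cutoff", {
  cfg <- retention_config()
  fix <- rbind(
    mk_bsj(score = 0.05, library = "rnaser"),
    mk_bsj(score = 0.1, library = "rnaser"),
    mk_bsj(score = 0.100001, library = "rnaser"),
    mk_bsj(score = 0.9, library = "control"),
    mk_bsj(score = 0.900001, library = "control"),
    mk_bsj(score = 0.95, library = "control"),
    mk_bsj(score = 0.8, acceptor = 0, donor = 250000, library = "rnaser"))
  kept <- apply_retention(fix, cfg)
  expect_equal(kept$score, c(0.100001, 0.900001, 0.95))
  # monotonicity in the thresholds
  b <- default_bundle()
  prev <- nrow(apply_retention(b$bsj, retention_config(0, 0)))
  for (t in c(0.1, 0.3, 0.6, 0.9)) {
    cur <- nrow(apply_retention(b$bsj, retention_config(t, t)))
    expect_lte(cur, prev)
    prev <- cur
  }
  # subset relation, not just counts
  k1 <- apply_retention(b$bsj, retention_config(0.1, 0.5))
  k2 <- apply_retention(b$bsj, retention_config(0.4, 0.9))
  key <- function(d) paste(d$contig, d$acceptor, d$donor, d$strand, d$sample_id, d$score)
  expect_true(all(key(k2) %in% key(k1)))
})

test_that("merging sums support and flags single-read single-sample circles", {
  two <- rbind(mk_bsj(bsj_reads = 3, sample_id = "s1", condition = "cold"),
               mk_bsj(bsj_reads = 2, sample_id = "s2", condition = "heat"))
  m <- merge_unique(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$total_reads, 5)
  expect_equal(m$n_supporting_samples, 2)
  expect_false(m$low_support)
  expect_equal(m$reads_cold, 3)
  expect_equal(m$reads_heat, 2)
  # single read in a single sample
  m1 <- merge_unique(mk_bsj(bsj_reads = 1))
  expect_true(m1$low_support)
  # opposite strands are distinct circles
  m2 <- merge_unique(rbind(mk_bsj(strand = "+"), mk_bsj(strand = "-")))
  expect_equal(nrow(m2), 2)
})

test_that("condition overlap partitions sum to the union", {
  sets <- list(cold = c("a", "b", "c"), heat = "b", salt = "b", UVB = "b")
  ov <- condition_overlap(sets)
  expect_equal(unname(ov$unique_per_condition["cold"]), 2)
  expect_equal(ov$shared_all, 1)
  expect_equal(sum(ov$partition$count), ov$union_size)
  # disjoint sets share nothing
  expect_equal(condition_overlap(list(a = "x", b = "y"))$shared_all, 0)
  # random sets: partition counts always sum to |union|
  set.seed(2)
  for (i in 1:10) {
    s <- lapply(1:4, function(k) sample(paste0("id", 1:50), sample(5:40, 1)))
    names(s) <- paste0("c", 1:4)
    ov <- condition_overlap(s)
    expect_equal(sum(ov$partition$count), length(unique(unlist(s))))
    # brute-force membership-pattern enumeration
    ids <- unique(unlist(s))
    pat <- vapply(ids, function(id) {
      paste(names(s)[vapply(s, function(x) id %in% x, logical(1))], collapse = "&")
    }, character(1))
    expect_equal(sort(ov$partition$count), sort(as.integer(table(pat))))
  }
})

test_that("circular-to-linear ratios follow the stated convention", {
  expect_equal(circ_linear_ratio(5, 0), 1)
  expect_equal(circ_linear_ratio(0, 7), 0)
  expect_equal(circ_linear_ratio(3, 7), 0.3)
  expect_equal(circ_linear_ratio(0, 0), 0)
  expect_error(circ_linear_ratio(-1, 0), "non-negative")
})

test_that("RNase R CLR stochastically dominates control CLR on synthetic data", {
  b <- default_bundle()
  ret <- apply_retention(b$bsj)
  stats <- bsj_site_stats(ret, b$linear)
  ct <- clr_library_contrast(stats)
  expect_lt(ct$wilcox_p, 0.01)
  expect_lt(ct$fisher_p, 0.01)
  expect_gt(ct$median_clr[["rnaser"]], ct$median_clr[["control"]])
})

test_that("end-to-end retention recovers exactly the planted nuclear circRNAs", {
  b <- default_bundle()
  ret <- apply_retention(b$bsj)
  circ <- merge_unique(ret)
  nuclear <- circ[circ$contig != b$config$cp_contig, ]
  expect_setequal(nuclear$circ_id, b$truth$circ$circ_id)
  art <- b$origins$circ_id[b$origins$origin %in% c("artifact", "ultralong")]
  expect_length(intersect(circ$circ_id, art), 0)
})
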