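test_that("intron classes pick flanking and internal introns of the circle", {
  # 4-exon transcript with introns i1 [200,300), i2 [400,500), i3 [600,700)
  genes <- data.frame(gene_id = "g", contig = "c", start = 100L, end = 800L,
                      strand = "+")
  tx <- data.frame(transcript_id = "g.t1", gene_id = "g")
  ex <- data.frame(transcript_id = "g.t1", gene_id = "g", contig = "c",
                   start = c(100L, 300L, 500L, 700L),
                   end = c(200L, 400L, 600L, 800L), strand = "+")
  ann <- annotation_set(genes, tx, ex)
  cls <- classify_circs(data.frame(circ_id = "x", contig = "c", acceptor = 300,
                                   donor = 600, strand = "+"), ann)
  tab <- intron_length_classes(cls, ann)
  expect_equal(sum(tab$class == "flanking"), 2)   # introns 1 and 3
  expect_equal(sum(tab$class == "circ_internal"), 1)  # intron 2
  expect_equal(sum(tab$class == "genome_wide"), 3)
  # first-exon circle has only a downstream flanking intron
  cls2 <- classify_circs(data.frame(circ_id = "y", contig = "c", acceptor = 100,
                                    donor = 200, strand = "+"), ann)
  tab2 <- intron_length_classes(cls2, ann)
  expect_equal(sum(tab2$class == "flanking"), 1)
})

test_that("flanking intron lengths exceed genome-wide lengths on synthetic data", {
  rep <- default_report()
  tab <- rep$tables$biogenesis$intron_classes
  med <- tapply(tab$length, tab$class, median)
  expect_gt(med[["flanking"]], med[["genome_wide"]])
  # class containment: every flanking/internal intron is a genome-wide intron
  gw <- tab$length[tab$class == "genome_wide"]
  expect_true(all(tab$length[tab$class != "genome_wide"] %in% gw))
})

test_that("host feature comparison reports group means and a null identity", {
  genes <- data.frame(gene_id = paste0("g", 1:20), contig = "c",
                      start = seq(0, 19000, 1000), end = seq(500, 19500, 1000),
                      strand = "+")
  tx <- data.frame(transcript_id = paste0("g", 1:20, ".t1"),
                   gene_id = paste0("g", 1:20))
  # hosts (g1..g10) get 10 exons, non-hosts 2 exons
  ex <- do.call(rbind, lapply(1:20, function(i) {
    k <- if (i <= 10) 10 else 2
    w <- floor(500 / (2 * k))
    data.frame(transcript_id = paste0("g", i, ".t1"),
               gene_id = paste0("g", i), contig = "c",
               start = (i - 1) * 1000 + (0:(k - 1)) * 2 * w,
               end = (i - 1) * 1000 + (0:(k - 1)) * 2 * w + w, strand = "+")
  }))
  ann <- annotation_set(genes, tx, ex)
  hf <- host_feature_comparison(ann, paste0("g", 1:10))
  sm <- hf$summary
  expect_equal(sm$mean[sm$feature == "n_exons_max" & sm$group == "host"], 10)
  expect_equal(sm$mean[sm$feature == "n_exons_max" & sm$group == "non_host"], 2)
  expect_lt(hf$p_exons, 0.01)
  # identical groups: rank test p = 1
  hf2 <- host_feature_comparison(ann, paste0("g", c(1:5, 11:15)))
  expect_equal(hf2$p_exons, 1)
  expect_error(host_feature_comparison(ann, character(0)), "required")
  # brute-force arithmetic oracle
  feats <- ann$gene_features
  expect_equal(sm$mean[sm$feature == "n_isoforms" & sm$group == "host"],
               mean(feats$n_isoforms[feats$gene_id %in% paste0("g", 1:10)]))
})

test_that("propensity fractions are hosts-in-bin over genes-in-bin", {
  b <- default_bundle()
  cfg <- b$config
  nuclear <- b$annotation$genes$gene_id[b$annotation$genes$contig != cfg$cp_contig]
  ann <- b$annotation
  ann$gene_features <- ann$gene_features[ann$gene_features$gene_id %in% nuclear, ]
  hosts <- b$truth$circ$host_gene
  prop <- propensity_by_bin(ann, hosts, "exons", breaks = c(2, 6, 10, 14, 18))
  expect_equal(sum(prop$n_hosts), length(unique(hosts)))
  expect_equal(sum(prop$n_genes), length(nuclear))
  ok <- !is.na(prop$fraction)
  expect_true(all(prop$fraction[ok] >= 0 & prop$fraction[ok] <= 1))
  # generator separates host/non-host exon counts: fraction non-decreasing
  expect_true(all(diff(prop$fraction[ok]) >= 0))
  # empty bins are undefined, not zero
  prop2 <- propensity_by_bin(ann, hosts, "exons", breaks = c(2, 6, 7, 8, 18))
  expect_true(all(is.na(prop2$fraction[prop2$n_genes == 0])))
})

test_that("Fisher exact p matches hand-derived and enumerated values", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 0), 2)), "non-negative")
  # random tables: agree with the factorial oracle and stats::fisher.test
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_p_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("find_ics detects reverse-complementary stretches", {
  hit <- find_ics("AAAACCCC", "GGGGTTTT", min_length = 8)
  expect_equal(hit$match_length, 8)
  expect_equal(hit$identity, 1)
  expect_equal(hit$up_start, 0); expect_equal(hit$up_end, 8)
  expect_equal(hit$down_start, 0); expect_equal(hit$down_end, 8)
  # same sequence is not an inverted repeat
  expect_null(find_ics("AAAA", "AAAA", min_length = 4))
  expect_null(find_ics("", "ACGT"))
  # planted inverted repeat inside noise is located exactly
  set.seed(4)
  core <- random_dna(14)
  up <- paste0(random_dna(10), core, random_dna(6))
  dn <- paste0(random_dna(7), reverse_complement(core), random_dna(9))
  hit2 <- find_ics(up, dn, min_length = 14, min_identity = 1)
  expect_gte(hit2$match_length, 14)
  expect_true(grepl(core, substr(up, hit2$up_start + 1, hit2$up_end),
                    fixed = TRUE) ||
                grepl(substr(up, hit2$up_start + 1, hit2$up_end), core,
                      fixed = TRUE) || hit2$match_length > 14)
})

test_that("local alignment scores match independent oracles", {
  set.seed(12)
  # exhaustive substring-pair oracle at short lengths
  for (i in 1:25) {
    a <- random_dna(sample(4:9, 1)); d <- random_dna(sample(4:9, 1))
    rc <- reverse_complement(d)
    al <- circstress:::cpp_local_align(a, rc, 1, -1, -2)
    sc <- if (isTRUE(al$found)) al$score else 0
    expect_equal(sc, local_score_oracle(a, rc))
  }
  # independent C implementation at the full lengths
  for (i in 1:60) {
    a <- random_dna(sample(10:40, 1)); b <- random_dna(sample(10:40, 1))
    al <- circstress:::cpp_local_align(a, b, 1, -1, -2)
    sc <- if (isTRUE(al$found)) al$score else 0
    expect_equal(sc, biostrings_local_score(a, b))
  }
})

test_that("repeat density equals a brute-force coverage tally", {
  expect_equal(repeat_density("AAAAAAAAAA", k = 4), 1)
  expect_equal(repeat_density("ACGTACGTACGT", k = 12), 0)
  expect_error(repeat_density("ACG", k = 4), "shorter")
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C"), 50, replace = TRUE), collapse = "")
    k <- sample(3:6, 1)
    starts <- 1:(50 - k + 1)
    kmers <- substring(s, starts, starts + k - 1)
    cov <- logical(50)
    for (st in starts[table(kmers)[kmers] >= 2]) cov[st:(st + k - 1)] <- TRUE
    expect_equal(repeat_density(s, k = k), mean(cov))
  }
})

test_that("ICS control comparison flags planted inverted repeats only", {
  # self-comparison is null by construction
  b <- default_bundle()
  cls <- classify_circs(b$truth$circ[1:10, ], b$annotation)
  pairs <- circ_flank_pairs(cls, b$annotation, b$genome)
  m <- ics_metric_table(pairs)
  cmp <- compare_ics_metrics(m, m)
  expect_equal(cmp$p_ics_length, 1)
  expect_equal(cmp$p_repeat_density, 1)
  # planted 30-nt ICS in circ flanks separates from controls
  cfg <- generator_config(seed = 19, ics_plant_length = 30)
  ref <- plant_ics(generate_reference(cfg), 30)
  cls2 <- classify_circs(ref$truth$circ, ref$annotation)
  res <- ics_control_comparison(cls2, ref$annotation, ref$genome,
                                ref$truth$circ$host_gene, seed = 1)
  expect_lt(res$comparison$p_ics_length, 0.01)
  med <- res$comparison$medians
  expect_gt(med$circ[med$metric == "ics_length"],
            med$control[med$metric == "ics_length"])
  # requesting more controls than available internal exons errors
  expect_error(control_flank_pairs(ref$annotation, ref$genome,
                                   ref$truth$circ$host_gene, 10000),
               "insufficient")
})
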