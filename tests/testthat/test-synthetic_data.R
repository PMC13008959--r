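test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 42)
  a <- generate_synthetic_study(cfg)
  b <- generate_synthetic_study(cfg)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$bsj, b$bsj)
  expect_identical(a$expr$circ_counts, b$expr$circ_counts)
  expect_identical(a$mirna_sites, b$mirna_sites)
  expect_identical(a$orthologs$circ_b, b$orthologs$circ_b)
})

test_that("reference honours configured gene counts and biogenesis biases", {
  b <- default_bundle()
  cfg <- b$config
  n_genes <- sum(cfg$n_true_circ) + cfg$n_nonhost_genes
  nuclear_genes <- b$annotation$genes[b$annotation$genes$contig != cfg$cp_contig, ]
  expect_equal(nrow(nuclear_genes), n_genes)
  expect_equal(nrow(b$truth$circ), sum(cfg$n_true_circ))
  expect_equal(unname(table(b$truth$circ$circ_type)[c("multi-exonic", "single-exonic", "intronic")]),
               unname(cfg$n_true_circ[c("multi", "single", "intronic")]),
               ignore_attr = TRUE)
  # forced by construction: host introns longer, more exons, more isoforms
  intr <- b$annotation$introns
  host <- b$truth$circ$host_gene
  host_intr <- intr$end[intr$gene_id %in% host] - intr$start[intr$gene_id %in% host]
  non_intr <- intr$end[!intr$gene_id %in% c(host, "psbA_syn")] -
    intr$start[!intr$gene_id %in% c(host, "psbA_syn")]
  expect_gt(mean(host_intr), mean(non_intr))
  feat <- b$annotation$gene_features
  expect_gt(mean(feat$n_exons_max[feat$gene_id %in% host]),
            mean(feat$n_exons_max[feat$gene_id %in% nuclear_genes$gene_id &
                                    !feat$gene_id %in% host]))
})

test_that("true candidates clear the score threshold and artifacts do not", {
  b <- default_bundle()
  true_ids <- b$truth$circ$circ_id
  ids <- make_circ_id(b$bsj$contig, b$bsj$acceptor, b$bsj$donor, b$bsj$strand)
  rn_true <- b$bsj$library == "rnaser" & ids %in% true_ids
  expect_true(all(b$bsj$score[rn_true] > 0.1))
  art_ids <- b$origins$circ_id[b$origins$origin == "artifact"]
  art_rn <- b$bsj$library == "rnaser" & ids %in% art_ids
  art_ct <- b$bsj$library == "control" & ids %in% art_ids
  expect_true(all(b$bsj$score[art_rn] <= 0.1))
  expect_true(all(b$bsj$score[art_ct] <= 0.9))
  ul <- b$origins$circ_id[b$origins$origin == "ultralong"]
  ul_rows <- ids %in% ul
  expect_true(all(b$bsj$donor[ul_rows] - b$bsj$acceptor[ul_rows] > 1e5))
})

test_that("fully intergenic artifact placement leaves an endpoint outside all genes", {
  cfg <- generator_config(seed = 7, artifact_intergenic_fraction = 1,
                          n_artifact = 15, n_ultralong = 0)
  ref <- generate_reference(cfg)
  cand <- simulate_bsj_candidates(ref)
  art <- cand$origins$circ_id[cand$origins$origin == "artifact"]
  ids <- make_circ_id(cand$bsj$contig, cand$bsj$acceptor, cand$bsj$donor,
                      cand$bsj$strand)
  rows <- unique(cand$bsj[ids %in% art,
                          c("contig", "acceptor", "donor", "strand")])
  genes <- ref$annotation$genes
  for (i in seq_len(nrow(rows))) {
    acc_in <- any(genes$contig == rows$contig[i] &
                    genes$start <= rows$acceptor[i] & rows$acceptor[i] < genes$end)
    don_in <- any(genes$contig == rows$contig[i] &
                    genes$start < rows$donor[i] & rows$donor[i] <= genes$end)
    expect_false(acc_in && don_in)
  }
})

test_that("truth keys cover every emitted BSJ record", {
  b <- default_bundle()
  ids <- make_circ_id(b$bsj$contig, b$bsj$acceptor, b$bsj$donor, b$bsj$strand)
  expect_true(all(ids %in% b$origins$circ_id))
  expect_true(all(b$mirna_sites$target_id[b$mirna_sites$target_kind == "circRNA"]
                  %in% b$truth$circ$circ_id))
})

test_that("expression generator recovers the latent correlation", {
  ref <- generate_reference(generator_config(seed = 3))
  ex <- simulate_expression(ref, rho = 0.8, n_reps = 100, with_de = FALSE)
  prof <- coupling_profile(ex$circ_counts, ex$gene_counts,
                           ex$pairs[, c("circ_id", "gene_id")])
  expect_lt(abs(prof$median_r - 0.8), 0.05)
  ex0 <- simulate_expression(ref, rho = 0, n_reps = 100, with_de = FALSE)
  prof0 <- coupling_profile(ex0$circ_counts, ex0$gene_counts,
                            ex0$pairs[, c("circ_id", "gene_id")])
  expect_lt(mean(abs(prof0$records$pearson_r)), 0.1)
  expect_error(simulate_expression(ref, n_reps = 0), "at least 3")
})

test_that("planted miRNA sites are exact reverse complements at the recorded offset", {
  b <- default_bundle()
  cls <- classify_circs(b$truth$circ, b$annotation)
  L <- nchar(b$mirnas$sequence[1])
  for (i in seq_len(nrow(b$mirna_sites))) {
    s <- b$mirna_sites[i, ]
    mir <- b$mirnas$sequence[b$mirnas$mirna_id == s$mirna_id]
    if (s$target_kind == "circRNA") {
      cl <- cls[cls$circ_id == s$target_id, ]
      target <- circ_sequence(cl, b$annotation, b$genome)
    } else {
      ex <- transcript_exons(b$annotation, s$target_id)
      target <- paste(vapply(seq_len(nrow(ex)), function(e) {
        genome_subseq(b$genome, ex$contig[e], ex$start[e], ex$end[e])
      }, character(1)), collapse = "")
    }
    expect_identical(substr(target, s$position + 1, s$position + L),
                     reverse_complement(mir))
  }
})

test_that("ortholog generator plants the requested category mix", {
  b <- default_bundle()
  expect_equal(unname(table(b$orthologs$truth$category)),
               unname(b$config$ortholog_mix[sort(names(b$config$ortholog_mix))]),
               ignore_attr = TRUE)
  # every mapped id exists in its annotation
  expect_true(all(b$orthologs$ortholog_map$gene_a %in% b$annotation$genes$gene_id))
  expect_true(all(b$orthologs$ortholog_map$gene_b %in%
                    b$orthologs$annotation_b$genes$gene_id))
})

test_that("bundle files round-trip through the package's own readers", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  write_synthetic_bundle(b, dir)
  expect_no_warning({
    bsj <- read_bsj_table(file.path(dir, "bsj_candidates.tsv"))
    g <- read_genome_fasta(file.path(dir, "genome.fasta"))
    ann <- read_gff3(file.path(dir, "annotation.gff3"))
    cc <- read_count_matrix(file.path(dir, "circ_counts.tsv"))
  })
  expect_equal(nrow(bsj), nrow(b$bsj))
  expect_identical(g$contigs, b$genome$contigs)
  expect_equal(nrow(ann$genes), nrow(b$annotation$genes))
  expect_equal(unname(cc), unname(b$expr$circ_counts))
})
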