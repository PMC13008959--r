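test_that("ortholog overlap p matches the exact hypergeometric tail", {
  map <- data.frame(gene_a = paste0("a", 1:10), gene_b = paste0("b", 1:10))
  r <- ortholog_overlap_test(paste0("a", 1:5), paste0("b", 1:5), map)
  expect_equal(r$overlap, 5)
  expect_equal(r$p, 1 / 252, tolerance = 1e-12)
  # zero overlap is never significant
  r0 <- ortholog_overlap_test(paste0("a", 1:5), paste0("b", 6:10), map)
  expect_equal(r0$overlap, 0)
  expect_equal(r0$p, 1)
  # degenerate: no host orthologs at all
  rk <- ortholog_overlap_test(character(0), paste0("b", 1:5), map)
  expect_equal(rk$p, 1)
  expect_error(ortholog_overlap_test("a1", "b1", map[0, ]), "empty")
  # random configurations against the factorial oracle
  set.seed(21)
  for (i in 1:40) {
    N <- sample(5:60, 1)
    mapN <- data.frame(gene_a = paste0("a", 1:N), gene_b = paste0("b", 1:N))
    K <- sample(0:N, 1); n <- sample(0:N, 1)
    ha <- paste0("a", sample(N, K)); hb <- paste0("b", sample(N, n))
    r <- ortholog_overlap_test(ha, hb, mapN)
    if (K > 0 && n > 0) {
      expect_equal(r$p, hyper_upper_tail_oracle(r$overlap, N, K, n),
                   tolerance = 1e-12)
    } else {
      expect_equal(r$p, 1)
    }
  }
})

test_that("splice sites project through ortholog alignments", {
  set.seed(8)
  a <- random_dna(300)
  # identical sequences: identity mapping
  map <- ortholog_alignment_map(a, a)
  expect_equal(map_splice_site(120, map, "start"), 120)
  expect_equal(map_splice_site(200, map, "end"), 200)
  # 10-nt insertion before the site shifts the mapping by +10
  b_ins <- paste0(substr(a, 1, 50), random_dna(10), substr(a, 51, 300))
  map_ins <- ortholog_alignment_map(a, b_ins)
  expect_equal(map_splice_site(120, map_ins, "start"), 130)
  # site inside a deleted block is unmappable
  b_del <- paste0(substr(a, 1, 100), substr(a, 161, 300))
  map_del <- ortholog_alignment_map(a, b_del)
  expect_true(is.na(map_splice_site(120, map_del, "start")))
  expect_error(map_splice_site(500, map, "start"), "outside")
  # windowed mapping agrees with the full map
  expect_equal(map_splice_site_windowed(120, a, b_ins, "start"), 130)
  expect_equal(map_splice_site_windowed(200, a, a, "end"), 200)
  expect_true(is.na(map_splice_site_windowed(120, a, b_del, "start")))
})

test_that("conservation categories follow the two site flags", {
  set.seed(8)
  a <- random_dna(400)
  both <- classify_conservation(100, 300, 100, 300, a, a, tolerance = 10)
  expect_equal(both$category, "Accordant")
  half <- classify_conservation(100, 300, 100, 350, a, a, tolerance = 10)
  expect_equal(half$category, "Half-accordant")
  none <- classify_conservation(100, 300, 150, 350, a, a, tolerance = 10)
  expect_equal(none$category, "Unaccordant")
  # tolerance boundary is inclusive
  tol <- classify_conservation(100, 300, 110, 310, a, a, tolerance = 10)
  expect_equal(tol$category, "Accordant")
})

test_that("planted conservation mixes are recovered exactly", {
  b <- default_bundle()
  rep <- default_report()
  calls <- rep$tables$conservation$calls
  truth <- b$orthologs$truth
  m <- match(calls$gene_a, truth$gene_a)
  expect_true(all(!is.na(m)))
  expect_equal(calls$category, truth$category[m])
  expect_equal(unname(rep$tables$conservation$summary),
               unname(conservation_summary(calls)))
  expect_equal(sum(rep$tables$conservation$summary), nrow(calls))
  # summary tallies agree with a brute-force count
  expect_equal(rep$tables$conservation$summary[["Accordant"]],
               sum(truth$category[m] == "Accordant"))
  # empty input yields zero counts
  expect_equal(unname(conservation_summary(calls[0, ])), c(0L, 0L, 0L))
})

test_that("minus-strand junctions convert to transcription-local coordinates", {
  loc <- junction_to_local(120, 180, 100, 200, "+")
  expect_equal(c(loc$start, loc$end), c(20, 80))
  locm <- junction_to_local(120, 180, 100, 200, "-")
  expect_equal(c(locm$start, locm$end), c(20, 80))
  locm2 <- junction_to_local(100, 150, 100, 200, "-")
  expect_equal(c(locm2$start, locm2$end), c(50, 100))
})
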