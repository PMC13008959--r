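test_that("RPM and RPKM normalization follow their definitions", {
  m <- matrix(c(10, 0, 90, 0), 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  rpm <- normalize_counts(m, "RPM", lib_sizes = c(1e6, 1e6))
  expect_equal(rpm["f1", "s1"], 10)
  rpkm <- normalize_counts(m, "RPKM", lengths = c(f1 = 500, f2 = 1000),
                           lib_sizes = c(1e6, 1e6))
  expect_equal(rpkm["f1", "s1"], 20)
  expect_true(all(rpkm["f2", ] == 0))
  expect_error(normalize_counts(m, "RPM", lib_sizes = c(0, 1)), "> 0")
  expect_error(normalize_counts(m, "RPKM"), "lengths")
})

test_that("pearson_r matches closed forms and degeneracy conventions", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:3, c(3, 2, 1)), -1)
  expect_equal(pearson_r(1:4, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(1:5, rep(2, 5))))
  expect_true(is.na(pearson_r(1:2, 1:2)))
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("coupling profile skips pairs whose host is missing", {
  cm <- matrix(rpois(30, 50), 3, 10,
               dimnames = list(paste0("c", 1:3), paste0("s", 1:10)))
  gm <- matrix(rpois(20, 50), 2, 10,
               dimnames = list(paste0("g", 1:2), paste0("s", 1:10)))
  hm <- data.frame(circ_id = paste0("c", 1:3), gene_id = c("g1", "g2", "gX"))
  expect_warning(prof <- coupling_profile(cm, gm, hm), "skipped")
  expect_equal(nrow(prof$records), 2)
})

test_that("the exact conditional DE test matches its closed form", {
  # equal library sizes forced explicitly via a balancing feature
  m2 <- rbind(f = c(t = 16, c = 0), bal = c(t = 1e4 - 16, c = 1e4))
  r <- de_test(m2, "t", "c")
  expect_equal(r$p[r$feature == "f"], 2 * (1 / 2)^16, tolerance = 1e-12)
  expect_equal(r$state[r$feature == "f"], "up")
  # identical groups are null
  m3 <- rbind(a = c(50, 50), b = c(100, 100))
  r3 <- de_test(m3, 1, 2)
  expect_equal(r3$log2fc, c(0, 0))
  expect_equal(r3$state, c("ns", "ns"))
  # fold-change antisymmetry
  set.seed(30)
  m4 <- matrix(rpois(40, 80), 10, 4,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  fwd <- de_test(m4, c("s1", "s2"), c("s3", "s4"))
  rev <- de_test(m4, c("s3", "s4"), c("s1", "s2"))
  expect_equal(fwd$log2fc, -rev$log2fc)
  # BH adjusted values dominate raw p and are monotone
  expect_true(all(fwd$q >= fwd$p - 1e-12))
  o <- order(fwd$p)
  expect_true(all(diff(fwd$q[o]) >= -1e-12))
  expect_error(de_test(m4, character(0), "s1"), ">= 1 sample")
})

test_that("pattern classification is total over the nine state pairs", {
  states <- c("up", "down", "ns")
  grid <- expand.grid(circ = states, host = states, stringsAsFactors = FALSE)
  pat <- classify_pattern(grid$circ, grid$host)
  expected <- c(up.up = "Coordinated", down.up = "Reversed", ns.up = "CircStable",
                up.down = "Reversed", down.down = "Coordinated",
                ns.down = "CircStable", up.ns = "HostStable",
                down.ns = "HostStable", ns.ns = "NS")
  expect_equal(pat, unname(expected[paste(grid$circ, grid$host, sep = ".")]))
  expect_error(classify_pattern("sideways", "up"))
})

test_that("planted DE patterns are recovered in their conditions", {
  b <- default_bundle()
  rep <- default_report()
  pats <- rep$tables$coupling$patterns
  planted <- b$expr$pairs[!is.na(b$expr$pairs$de_pattern), ]
  for (i in seq_len(nrow(planted))) {
    row <- pats[pats$circ_id == planted$circ_id[i] &
                  pats$condition == planted$de_condition[i], ]
    pat <- planted$de_pattern[i]
    # the planted fold change (|log2fc| = 2.5) dwarfs the biological noise,
    # so every planted side must be called; the unplanted side of the
    # *Stable patterns carries only biological variation and may be called
    # either way, so only both-sides-planted patterns are asserted exactly
    if (pat %in% c("Reversed", "Coordinated")) {
      expect_equal(row$pattern, pat, label = paste("pattern of", row$circ_id))
    } else if (pat == "HostStable") {
      expect_true(row$circ_state != "ns", label = paste("circ DE of", row$circ_id))
    } else if (pat == "CircStable") {
      expect_true(row$host_state != "ns", label = paste("host DE of", row$circ_id))
    }
  }
  # planted Reversed pairs outnumber none: the generator's plan is realized
  expect_gte(sum(pats$pattern == "Reversed"),
             sum(planted$de_pattern == "Reversed"))
})
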