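test_that("site penalties follow the seed-weighted scoring scheme", {
  set.seed(14)
  mir <- random_dna(21)
  perfect <- reverse_complement(mir)
  expect_equal(score_site(mir, perfect)$penalty, 0)
  # single G:U outside the seed: site position pairing miRNA position 21
  # (the 5'-most window base) is outside seed 2-13
  mirv <- strsplit(mir, "")[[1]]
  m21 <- mirv[21]
  w <- strsplit(perfect, "")[[1]]
  # choose a miRNA whose relevant bases admit a wobble
  mir2 <- paste0(substr(mir, 1, 20), "G")   # position 21 = G pairs C; wobble with T
  site2 <- reverse_complement(mir2)         # starts with C
  win <- paste0("T", substr(site2, 2, 21))
  expect_equal(score_site(mir2, win)$penalty, 0.5)
  # single mismatch at miRNA position 5 (inside seed): penalty doubled
  site_pos <- 21 - 5 + 1  # site index pairing miRNA position 5
  sv <- strsplit(site2, "")[[1]]
  repl <- setdiff(c("A", "C", "G", "T"), sv[site_pos])
  # avoid accidentally creating a wobble
  repl <- repl[!((sv[site_pos] == "C" & repl == "T") |
                   (sv[site_pos] == "A" & repl == "G"))][1]
  sv2 <- sv; sv2[site_pos] <- repl
  expect_equal(score_site(mir2, paste(sv2, collapse = ""))$penalty, 2)
  expect_error(score_site(mir, random_dna(10)), "within")
})

test_that("scan_targets equals exhaustive window scoring with greedy overlap rule", {
  set.seed(15)
  mir <- random_dna(21)
  target <- random_dna(300)
  # plant one perfect site
  pos <- 120
  target <- paste0(substr(target, 1, pos), reverse_complement(mir),
                   substr(target, pos + 22, 300))
  hits <- scan_targets("m", mir, "t", target, "mRNA", cutoff = 0)
  expect_equal(hits$position, pos)
  expect_equal(hits$penalty, 0)
  # oracle equality at a permissive cutoff
  for (i in 1:3) {
    tg <- random_dna(250)
    got <- scan_targets("m", mir, "t", tg, "mRNA", cutoff = 6)
    expect_equal(got$position, scan_targets_oracle(mir, tg, 6))
  }
  # overlapping candidates: lower penalty wins
  half <- reverse_complement(mir)
  tg2 <- paste0(random_dna(40), half, random_dna(40))
  got2 <- scan_targets("m", mir, "t", tg2, "mRNA", cutoff = 8)
  best <- got2$penalty[got2$position == 40]
  expect_equal(best, 0)
  overlapping <- got2$position[got2$position != 40 & abs(got2$position - 40) < 21]
  expect_length(overlapping, 0)
})

test_that("stringency profiles nest and the consensus filter intersects", {
  set.seed(16)
  mirnas <- data.frame(mirna_id = "m1", sequence = random_dna(21))
  tg <- paste0(random_dna(60), reverse_complement(mirnas$sequence), random_dna(60))
  targets <- data.frame(target_id = "t1", sequence = tg, target_kind = "mRNA")
  sites <- scan_all_targets(mirnas, targets)
  key <- function(s) paste(s$mirna_id, s$target_id, s$position)
  expect_true(all(key(sites$strict) %in% key(sites$medium)))
  expect_true(all(key(sites$medium) %in% key(sites$lenient)))
  cons <- consensus_filter(sites)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$best_penalty, 0)
  # a site found only by the lenient profile is dropped
  fake <- list(strict = sites$strict[0, ], medium = sites$medium,
               lenient = sites$lenient)
  expect_equal(nrow(consensus_filter(fake)), 0)
  # single-profile filter degenerates to that profile's interactions
  one <- consensus_filter(sites["lenient"])
  expect_equal(nrow(one), 1)
  expect_error(consensus_filter(list()), "at least one")
})

test_that("circ target sequences expose junction-crossing windows", {
  s <- "ACGTACGTAA"
  r <- circ_target_seq(s, 4)
  expect_equal(r, paste0(s, "ACG"))
  set.seed(17)
  mir <- random_dna(21)
  # place the site across the junction: last 10 nt + first 11 nt
  site <- reverse_complement(mir)
  circ <- paste0(substr(site, 11, 21), random_dna(80), substr(site, 1, 10))
  hits <- scan_targets("m", mir, "c", circ_target_seq(circ, 21), "circRNA",
                       cutoff = 0)
  expect_equal(hits$position, 91)
})

test_that("networks are tripartite with resolvable endpoints", {
  inter <- data.frame(
    mirna_id = "m1",
    target_id = c(paste0("c", 1:3), paste0("g", 1:5)),
    target_kind = c(rep("circRNA", 3), rep("mRNA", 5)),
    best_penalty = 0, n_profiles = 3, stringsAsFactors = FALSE)
  g <- build_network(inter)
  expect_equal(igraph::ecount(g), 8)
  expect_equal(igraph::vcount(g), 9)
  kinds <- igraph::V(g)$kind
  ends <- igraph::ends(g, igraph::E(g))
  k1 <- kinds[match(ends[, 1], igraph::V(g)$name)]
  k2 <- kinds[match(ends[, 2], igraph::V(g)$name)]
  expect_true(all(k1 == "miRNA" | k2 == "miRNA"))
  expect_equal(igraph::ecount(build_network(inter[0, ])), 0)
  bad <- inter; bad$target_id[1] <- NA
  expect_error(build_network(bad))
})

test_that("hub ranking counts targets with deterministic tie-breaks", {
  inter <- data.frame(
    mirna_id = c(rep("mX", 7), rep("mY", 3), rep("mZ", 3)),
    target_id = paste0("c", 1:13),
    target_kind = "circRNA", best_penalty = 0, n_profiles = 3,
    stringsAsFactors = FALSE)
  hr <- hub_rank(inter, k = 10)
  expect_equal(hr$by_circ$mirna_id[1], "mX")
  # tie at 3 targets: lexicographic order
  expect_equal(hr$by_circ$mirna_id[2:3], c("mY", "mZ"))
  # k larger than the miRNA count returns the full ranking
  expect_equal(nrow(hub_rank(inter, k = 50)$by_circ), 3)
})

test_that("sponge consistency reports DE fractions over annotated partners", {
  inter <- data.frame(
    mirna_id = "m1",
    target_id = c(paste0("c", 1:4), paste0("g", 1:5)),
    target_kind = c(rep("circRNA", 4), rep("mRNA", 5)),
    best_penalty = 0, n_profiles = 3, stringsAsFactors = FALSE)
  states <- data.frame(
    id = c(paste0("c", 1:4), paste0("g", 1:5)),
    state = c("up", "up", "up", "down", "down", "down", "up", "ns", "ns"),
    stringsAsFactors = FALSE)
  sc <- sponge_consistency(inter, states, "m1")
  expect_equal(sc$frac_circ_up, 0.75)
  expect_equal(sc$frac_mrna_down, 0.4)
  expect_false(sc$zero_denominator)
  # ideal sponge signature
  states2 <- states; states2$state <- c(rep("up", 4), rep("down", 5))
  sc2 <- sponge_consistency(inter, states2, "m1")
  expect_equal(c(sc2$frac_circ_up, sc2$frac_mrna_down), c(1, 1))
  # no annotated partners
  sc3 <- sponge_consistency(inter, states[0, ], "m1")
  expect_true(sc3$zero_denominator)
  expect_equal(c(sc3$frac_circ_up, sc3$frac_mrna_down), c(0, 0))
  expect_error(sponge_consistency(inter, states, "nope"), "absent")
})

test_that("planted sites are recovered by all profiles; shuffled miRNAs are not", {
  b <- default_bundle()
  rep <- default_report()
  sites <- rep$tables$network$sites
  inter <- rep$tables$network$interactions
  planted <- unique(paste(b$mirna_sites$mirna_id, b$mirna_sites$target_id))
  for (profile in names(sites)) {
    key <- unique(paste(sites[[profile]]$mirna_id, sites[[profile]]$target_id))
    expect_true(all(planted %in% key), label = paste("profile", profile))
  }
  expect_setequal(paste(inter$mirna_id, inter$target_id), planted)
  # shuffled-miRNA negative control yields far fewer consensus interactions
  set.seed(18)
  shuf <- b$mirnas
  shuf$sequence <- vapply(strsplit(shuf$sequence, ""), function(x) {
    paste(sample(x), collapse = "")
  }, character(1))
  tids <- unique(b$mirna_sites$target_id[b$mirna_sites$target_kind == "circRNA"])
  tids <- tids[seq_len(min(10, length(tids)))]
  cls <- classify_circs(b$truth$circ[b$truth$circ$circ_id %in% tids, ],
                        b$annotation)
  targets <- do.call(rbind, lapply(seq_len(nrow(cls)), function(i) {
    data.frame(target_id = cls$circ_id[i],
               sequence = circ_target_seq(
                 circ_sequence(cls[i, ], b$annotation, b$genome), 21),
               target_kind = "circRNA", stringsAsFactors = FALSE)
  }))
  neg <- consensus_filter(scan_all_targets(shuf, targets))
  pos <- inter[inter$target_id %in% targets$target_id, ]
  expect_gte(nrow(pos), 10 * max(1, nrow(neg)))
})
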