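## ceRNA (miRNA sponge) network: plant-style target-site scoring with
## seed-region weighting, multi-stringency consensus filtering, tripartite
## network assembly, hub ranking, and sponge-consistency evaluation.

#' Default target-scoring parameters
#'
#' Plant-style expectation penalties: mismatch 1, G:U wobble 0.5, gap 2,
#' all doubled inside the seed region (miRNA positions 2-13, 5' numbering).
#'
#' @param mismatch,wobble,gap Penalty weights.
#' @param seed_from,seed_to Seed region bounds (miRNA 5' positions,
#'   1-based, inclusive).
#' @param seed_multiplier Weight multiplier inside the seed.
#' @return Parameter list.
#' @export
target_scoring_params <- function(mismatch = 1, wobble = 0.5, gap = 2,
                                  seed_from = 2, seed_to = 13,
                                  seed_multiplier = 2) {
  list(mismatch = mismatch, wobble = wobble, gap = gap,
       seed_from = seed_from, seed_to = seed_to,
       seed_multiplier = seed_multiplier)
}

#' Stringency profiles standing in for independent target predictors
#'
#' Three nested penalty cutoffs; the consensus filter keeps interactions
#' found under every profile.
#'
#' @return Named numeric vector of penalty cutoffs.
#' @export
stringency_profiles <- function() {
  c(strict = 0, medium = 2.5, lenient = 5.0)
}

# Seed-aware weight vector along the ideal site (revcomp of the miRNA).
# Site position j (1-based, 5'->3' on the site) pairs miRNA position
# L - j + 1, so the seed (miRNA positions seed_from..seed_to) maps to site
# positions L-seed_to+1 .. L-seed_from+1.
site_weights <- function(mir_len, params) {
  w <- rep(1, mir_len)
  mir_pos <- mir_len - seq_len(mir_len) + 1L
  w[mir_pos >= params$seed_from & mir_pos <= params$seed_to] <- params$seed_multiplier
  w
}

#' Score one candidate binding window against a miRNA
#'
#' Optimal gapped, penalty-minimizing alignment of the target window
#' against the reverse complement of the miRNA, with G:U wobbles allowed at
#' half penalty and all penalties doubled in the seed region. Lower is
#' better; 0 is a perfect site.
#'
#' @param mirna_seq miRNA sequence, 5'->3', DNA alphabet.
#' @param target_window Target subsequence (within +-5 nt of the miRNA
#'   length).
#' @param params See [target_scoring_params()].
#' @return List: `penalty`, `alignment` (three-line character vector:
#'   window, midline, site).
#' @export
score_site <- function(mirna_seq, target_window,
                       params = target_scoring_params()) {
  L <- nchar(mirna_seq)
  if (abs(nchar(target_window) - L) > 5) {
    stop("window length must be within +-5 nt of the miRNA length")
  }
  site <- reverse_complement(mirna_seq)
  res <- cpp_site_penalty(target_window, site, site_weights(L, params),
                          params$mismatch, params$wobble, params$gap)
  list(penalty = res$penalty,
       alignment = c(res$aligned_window, res$midline, res$aligned_site))
}

#' Scan a target sequence for miRNA binding sites
#'
#' Slides a window of the miRNA's length along the target, scores every
#' window, keeps those with penalty <= cutoff, and resolves overlaps
#' greedily by ascending penalty (ties to the leftmost site).
#'
#' @param mirna_id,mirna_seq miRNA identifier and sequence.
#' @param target_id,target_seq Target identifier and sequence.
#' @param target_kind `"circRNA"` or `"mRNA"`.
#' @param cutoff Penalty cutoff.
#' @param params See [target_scoring_params()].
#' @return data.frame of sites: `mirna_id`, `target_id`, `target_kind`,
#'   `position` (0-based offset), `penalty`.
#' @export
scan_targets <- function(mirna_id, mirna_seq, target_id, target_seq,
                         target_kind = c("circRNA", "mRNA"),
                         cutoff = 5.0, params = target_scoring_params()) {
  target_kind <- match.arg(target_kind)
  L <- nchar(mirna_seq)
  n <- nchar(target_seq)
  if (n < L) stop("target shorter than miRNA")
  site <- reverse_complement(mirna_seq)
  w <- site_weights(L, params)
  starts <- 0:(n - L)
  pen <- cpp_scan_penalties(target_seq, site, w,
                            params$mismatch, params$wobble, params$gap)
  cand <- data.frame(position = starts, penalty = pen)
  cand <- cand[cand$penalty <= cutoff, , drop = FALSE]
  cand <- cand[order(cand$penalty, cand$position), , drop = FALSE]
  kp <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand$position[i]
    if (!any(abs(kp - p) < L)) kp <- c(kp, p)
  }
  kp <- sort(kp)
  if (!length(kp)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), position = integer(0),
                      penalty = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(mirna_id = mirna_id, target_id = target_id,
             target_kind = target_kind, position = kp,
             penalty = cand$penalty[match(kp, cand$position)],
             stringsAsFactors = FALSE)
}

#' Junction-inclusive circRNA target sequence
#'
#' The spliced circular sequence extended by its own first `mirna_len - 1`
#' bases, so windows crossing the back-splice junction are scannable.
#'
#' @param spliced_seq Spliced circRNA sequence.
#' @param mirna_len miRNA length.
#' @return Character scalar.
#' @export
circ_target_seq <- function(spliced_seq, mirna_len) {
  if (nchar(spliced_seq) < mirna_len) return(spliced_seq)
  paste0(spliced_seq, substr(spliced_seq, 1, mirna_len - 1))
}

#' Scan a set of miRNAs against a set of targets under each profile
#'
#' @param mirnas data.frame: `mirna_id`, `sequence`.
#' @param targets data.frame: `target_id`, `sequence`, `target_kind`.
#' @param profiles Named cutoff vector (see [stringency_profiles()]).
#' @param params See [target_scoring_params()].
#' @return Named list (by profile) of site data.frames.
#' @export
scan_all_targets <- function(mirnas, targets,
                             profiles = stringency_profiles(),
                             params = target_scoring_params()) {
  # scan once at the loosest cutoff, then derive stricter profiles:
  # a site retained at cutoff c is exactly a site of the loose scan with
  # penalty <= c re-resolved for overlaps, which the greedy rule preserves
  # because removing higher-penalty sites never unblocks a kept one.
  loose <- max(profiles)
  all_sites <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(targets)), function(j) {
      scan_targets(mirnas$mirna_id[i], mirnas$sequence[i],
                   targets$target_id[j], targets$sequence[j],
                   targets$target_kind[j], cutoff = loose, params = params)
    }))
  }))
  lapply(profiles, function(cutoff) {
    s <- all_sites[all_sites$penalty <= cutoff, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
}

#' Consensus filter over stringency profiles
#'
#' An interaction (miRNA, target) is retained iff every profile reports at
#' least one site for it, mirroring the intersection-of-predictors rule.
#'
#' @param sites_by_profile Named list of site data.frames.
#' @return data.frame of retained interactions: `mirna_id`, `target_id`,
#'   `target_kind`, `best_penalty`, `n_profiles`.
#' @export
consensus_filter <- function(sites_by_profile) {
  if (!length(sites_by_profile)) stop("at least one profile required")
  keys <- lapply(sites_by_profile, function(s) {
    unique(paste(s$mirna_id, s$target_id, sep = "\r"))
  })
  common <- Reduce(intersect, keys)
  ref <- do.call(rbind, sites_by_profile)
  ref$key <- paste(ref$mirna_id, ref$target_id, sep = "\r")
  ref <- ref[ref$key %in% common, , drop = FALSE]
  if (!nrow(ref)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), best_penalty = numeric(0),
                      n_profiles = integer(0), stringsAsFactors = FALSE))
  }
  agg <- do.call(rbind, lapply(split(ref, ref$key), function(s) {
    data.frame(mirna_id = s$mirna_id[1], target_id = s$target_id[1],
               target_kind = s$target_kind[1],
               best_penalty = min(s$penalty),
               n_profiles = length(sites_by_profile),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$mirna_id, agg$target_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Assemble the tripartite circRNA-miRNA-mRNA network
#'
#' Nodes carry a `kind` attribute (circRNA/miRNA/mRNA) and optional
#' log2 fold-change and DE-state attributes; edges are retained
#' interactions. circRNA-mRNA edges are forbidden (tripartite through the
#' miRNA layer).
#'
#' @param interactions data.frame from [consensus_filter()] (both circRNA
#'   and mRNA interactions).
#' @param node_states Optional data.frame: `id`, `log2fc`, `state`.
#' @param condition Condition label stored on the graph.
#' @return An `igraph` graph.
#' @export
build_network <- function(interactions, node_states = NULL, condition = NA) {
  if (nrow(interactions) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g$condition <- condition
    return(g)
  }
  if (any(is.na(interactions$mirna_id)) || any(is.na(interactions$target_id)) ||
      any(!nzchar(interactions$mirna_id)) || any(!nzchar(interactions$target_id))) {
    stop("dangling interaction reference: missing node id")
  }
  nodes <- rbind(
    data.frame(id = unique(interactions$mirna_id), kind = "miRNA",
               stringsAsFactors = FALSE),
    unique(data.frame(id = interactions$target_id,
                      kind = interactions$target_kind,
                      stringsAsFactors = FALSE))
  )
  if (anyDuplicated(nodes$id)) stop("node id used with conflicting kinds")
  edges <- data.frame(from = interactions$mirna_id,
                      to = interactions$target_id,
                      penalty = interactions$best_penalty,
                      stringsAsFactors = FALSE)
  if (!all(edges$to %in% nodes$id)) stop("dangling interaction reference")
  if (!is.null(node_states)) {
    idx <- match(nodes$id, node_states$id)
    nodes$log2fc <- node_states$log2fc[idx]
    nodes$state <- node_states$state[idx]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  g$condition <- condition
  g
}

#' Rank hub miRNAs by target counts
#'
#' Two rankings: by number of circRNA partners and by number of DE mRNA
#' targets; ties broken by miRNA id.
#'
#' @param interactions data.frame of retained interactions.
#' @param node_states Optional `id`/`state` data.frame (needed for the DE
#'   mRNA ranking; without it all mRNA targets count).
#' @param k Number of top miRNAs to return.
#' @return List of two data.frames (`by_circ`, `by_de_mrna`): `mirna_id`,
#'   `n_targets`.
#' @export
hub_rank <- function(interactions, node_states = NULL, k = 10) {
  stopifnot(k >= 1)
  rank_of <- function(sub) {
    if (nrow(sub) == 0) {
      return(data.frame(mirna_id = character(0), n_targets = integer(0),
                        stringsAsFactors = FALSE))
    }
    tab <- table(sub$mirna_id)
    df <- data.frame(mirna_id = names(tab), n_targets = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_targets, df$mirna_id), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, k)
  }
  circ <- interactions[interactions$target_kind == "circRNA", , drop = FALSE]
  mrna <- interactions[interactions$target_kind == "mRNA", , drop = FALSE]
  if (!is.null(node_states)) {
    de_ids <- node_states$id[node_states$state %in% c("up", "down")]
    mrna <- mrna[mrna$target_id %in% de_ids, , drop = FALSE]
  }
  list(by_circ = rank_of(circ), by_de_mrna = rank_of(mrna))
}

#' Sponge-consistency signature of one miRNA
#'
#' Fraction of the miRNA's circRNA partners that are upregulated and
#' fraction of its mRNA targets that are downregulated, over DE-state
#' annotated partners; (1, 1) is the ideal sponge signature.
#'
#' @param interactions Retained interactions.
#' @param node_states data.frame `id`, `state`.
#' @param mirna_id The miRNA.
#' @return List: `frac_circ_up`, `frac_mrna_down`, `n_circ`, `n_mrna`,
#'   `zero_denominator` flag.
#' @export
sponge_consistency <- function(interactions, node_states, mirna_id) {
  sub <- interactions[interactions$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("miRNA absent from network: ", mirna_id)
  st <- function(ids) node_states$state[match(ids, node_states$id)]
  circ <- st(sub$target_id[sub$target_kind == "circRNA"])
  mrna <- st(sub$target_id[sub$target_kind == "mRNA"])
  circ <- circ[!is.na(circ)]
  mrna <- mrna[!is.na(mrna)]
  list(frac_circ_up = if (length(circ)) mean(circ == "up") else 0,
       frac_mrna_down = if (length(mrna)) mean(mrna == "down") else 0,
       n_circ = length(circ), n_mrna = length(mrna),
       zero_denominator = (length(circ) == 0 || length(mrna) == 0))
}
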