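## BSJ credibility filtering: context classification, score stratification,
## dual-threshold retention, ultra-long exclusion, merging, condition overlap,
## and circular-to-linear ratios.

#' Retention configuration for BSJ filtering
#'
#' Strictly exclusive score thresholds (score > threshold is kept), applied
#' per library type: RNase R-treated libraries use a permissive threshold,
#' untreated control libraries a stringent one. Junctions spanning more than
#' `max_span` bp are excluded as ultra-long-distance circularization
#' artifacts.
#'
#' @param rnaser_min_score Exclusive score threshold for RNase R libraries
#'   (default 0.1).
#' @param control_min_score Exclusive score threshold for control libraries
#'   (default 0.9).
#' @param max_span Maximum genomic span (donor - acceptor) in bp
#'   (default 1e5).
#' @param require_intragenic Drop intergenic candidates as well
#'   (default FALSE; the score thresholds already remove them in practice).
#' @return A `retention_config` list.
#' @export
retention_config <- function(rnaser_min_score = 0.1, control_min_score = 0.9,
                             max_span = 1e5, require_intragenic = FALSE) {
  stopifnot(rnaser_min_score >= 0, rnaser_min_score <= 1,
            control_min_score >= 0, control_min_score <= 1, max_span > 0)
  structure(list(rnaser_min_score = rnaser_min_score,
                 control_min_score = control_min_score,
                 max_span = max_span,
                 require_intragenic = require_intragenic),
            class = "retention_config")
}

#' Read a BSJ candidate table from TSV
#'
#' Expected columns: `contig`, `acceptor`, `donor`, `strand`, `score`,
#' `bsj_reads`, `sample_id`, `condition`, `library` (header required).
#'
#' @param path TSV file.
#' @return data.frame of candidates.
#' @export
read_bsj_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  req <- c("contig", "acceptor", "donor", "strand", "score", "bsj_reads",
           "sample_id", "condition", "library")
  missing <- setdiff(req, names(df))
  if (length(missing)) stop("BSJ table missing columns: ", paste(missing, collapse = ", "))
  validate_bsj(df)
  df
}

validate_bsj <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$acceptor >= df$donor)) stop("acceptor must be < donor")
  if (any(df$score < 0 | df$score > 1)) stop("score must lie in [0,1]")
  if (any(df$bsj_reads < 1)) stop("bsj_reads must be >= 1")
  if (any(!df$library %in% c("rnaser", "control"))) {
    stop("library must be 'rnaser' or 'control'")
  }
  invisible(df)
}

#' Classify BSJ candidates as intragenic or intergenic
#'
#' A junction is intragenic iff at least one gene's span contains both the
#' acceptor and the donor coordinate; a junction bridging two distinct genes
#' (or reaching outside all genes) is intergenic. Adds `context` and a
#' comma-separated `host_genes` column.
#'
#' @param bsj data.frame of candidates (see [read_bsj_table()]).
#' @param annotation An [annotation_set()].
#' @param strand_matched Require the host gene to be on the junction strand.
#' @return The input with `context` and `host_genes` columns.
#' @export
classify_context <- function(bsj, annotation, strand_matched = FALSE) {
  if (nrow(bsj) == 0) {
    bsj$context <- character(0); bsj$host_genes <- character(0)
    return(bsj)
  }
  q <- GenomicRanges::GRanges(bsj$contig,
                              IRanges::IRanges(bsj$acceptor + 1L, bsj$donor))
  hits <- GenomicRanges::findOverlaps(q, annotation$index, type = "within",
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  gene <- names(annotation$index)[S4Vectors::subjectHits(hits)]
  if (strand_matched) {
    gs <- annotation$genes$strand[match(gene, annotation$genes$gene_id)]
    keep <- gs == bsj$strand[qh]
    qh <- qh[keep]; gene <- gene[keep]
  }
  hosts <- vapply(seq_len(nrow(bsj)), function(i) {
    g <- sort(unique(gene[qh == i]))
    if (length(g)) paste(g, collapse = ",") else ""
  }, character(1))
  bsj$host_genes <- hosts
  bsj$context <- ifelse(nzchar(hosts), "intragenic", "intergenic")
  bsj
}

#' Score-stratified candidate counts by genomic context
#'
#' Bins candidate reliability scores (left-closed, right-open bins; the last
#' bin is closed so a score of 1 falls in it) and tallies intragenic vs
#' intergenic candidates per bin.
#'
#' @param bsj Candidates with a `context` column (see [classify_context()]).
#' @param bin_width Score bin width (default 0.1).
#' @return data.frame: `bin`, `bin_lo`, `bin_hi`, `n`, `n_intragenic`,
#'   `n_intergenic`, `intergenic_fraction`.
#' @export
score_stratification <- function(bsj, bin_width = 0.1) {
  edges <- seq(0, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  k <- length(edges) - 1L
  if (nrow(bsj) == 0) {
    return(data.frame(bin = character(0), bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), n_intragenic = integer(0),
                      n_intergenic = integer(0), intergenic_fraction = numeric(0)))
  }
  idx <- findInterval(bsj$score, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(
    bin = sprintf("[%.2g,%.2g%s", edges[-length(edges)], edges[-1],
                  c(rep(")", k - 1), "]")),
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    n = as.integer(tabulate(idx, nbins = k)),
    n_intragenic = as.integer(tabulate(idx[bsj$context == "intragenic"], nbins = k)),
    stringsAsFactors = FALSE
  )
  out$n_intergenic <- out$n - out$n_intragenic
  out$intergenic_fraction <- ifelse(out$n > 0, out$n_intergenic / out$n, NA_real_)
  out
}

#' Apply score and span retention rules to BSJ candidates
#'
#' Keeps a candidate iff its score strictly exceeds the threshold for its
#' library type and its genomic span does not exceed `max_span`. Retained
#' sets are monotone: raising any threshold can only shrink them.
#'
#' @param bsj Candidate data.frame.
#' @param config A [retention_config()].
#' @return The retained subset of `bsj`.
#' @export
apply_retention <- function(bsj, config = retention_config()) {
  validate_bsj(bsj)
  if (nrow(bsj) == 0) return(bsj)
  thr <- ifelse(bsj$library == "rnaser",
                config$rnaser_min_score, config$control_min_score)
  keep <- bsj$score > thr & (bsj$donor - bsj$acceptor) <= config$max_span
  if (isTRUE(config$require_intragenic)) {
    if (!"context" %in% names(bsj)) stop("require_intragenic needs a 'context' column")
    keep <- keep & bsj$context == "intragenic"
  }
  out <- bsj[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge retained candidates into unique circRNAs
#'
#' One circRNA per distinct (contig, acceptor, donor, strand) key, with
#' read support summed per condition, the number of distinct supporting
#' samples, and the low-support flag (exactly one BSJ read in exactly one
#' sample).
#'
#' @param retained Retained candidate data.frame (see [apply_retention()]).
#' @return data.frame of unique circRNAs, one row per junction.
#' @export
merge_unique <- function(retained) {
  if (nrow(retained) == 0) {
    return(data.frame(circ_id = character(0), contig = character(0),
                      acceptor = integer(0), donor = integer(0),
                      strand = character(0), total_reads = integer(0),
                      n_supporting_samples = integer(0),
                      low_support = logical(0), stringsAsFactors = FALSE))
  }
  key <- make_circ_id(retained$contig, retained$acceptor, retained$donor,
                      retained$strand)
  sp <- split(seq_len(nrow(retained)), key)
  conds <- sort(unique(retained$condition))
  rows <- lapply(names(sp), function(k) {
    idx <- sp[[k]]
    sub <- retained[idx, , drop = FALSE]
    per_cond <- vapply(conds, function(cc) sum(sub$bsj_reads[sub$condition == cc]),
                       numeric(1))
    ns <- length(unique(sub$sample_id))
    out <- data.frame(circ_id = k, contig = sub$contig[1],
                      acceptor = sub$acceptor[1], donor = sub$donor[1],
                      strand = sub$strand[1],
                      total_reads = sum(sub$bsj_reads),
                      n_supporting_samples = ns,
                      low_support = (ns == 1 && sum(sub$bsj_reads) == 1),
                      max_score = max(sub$score),
                      stringsAsFactors = FALSE)
    if ("host_genes" %in% names(sub)) {
      hg <- sort(unique(unlist(strsplit(sub$host_genes, ","))))
      hg <- hg[nzchar(hg)]
      out$host_genes <- paste(hg, collapse = ",")
      out$context <- if (length(hg)) "intragenic" else "intergenic"
    }
    for (cc in conds) out[[paste0("reads_", cc)]] <- per_cond[[cc]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$acceptor, out$donor, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-condition circRNA sets and their Venn partition
#'
#' @param sets Named list of character vectors (circRNA ids detected per
#'   condition).
#' @return List with `partition` (data.frame: membership pattern, count),
#'   `unique_per_condition` (named counts of ids seen in exactly that
#'   condition), `shared_all` (count present in every condition), and
#'   `union_size`.
#' @export
condition_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two condition sets")
  ids <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  tab <- table(pattern)
  partition <- data.frame(pattern = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE)
  uniq <- vapply(names(sets), function(nm) {
    sum(member[, nm] & rowSums(member) == 1)
  }, integer(1))
  list(partition = partition,
       unique_per_condition = uniq,
       shared_all = sum(rowSums(member) == length(sets)),
       union_size = length(ids))
}

#' Sets of circRNA ids detected per condition from retained candidates
#'
#' Detection in a condition means >= 1 retained candidate (optionally with a
#' minimum read count) in that condition's libraries.
#'
#' @param retained Retained candidates.
#' @param conditions Conditions to include (default: all except any named
#'   in `exclude`).
#' @param exclude Conditions to leave out (default "CK": the Venn of
#'   interest is across stresses).
#' @param min_reads Minimum per-candidate read count to count as detected.
#' @return Named list of circRNA id vectors.
#' @export
condition_sets <- function(retained, conditions = NULL, exclude = "CK",
                           min_reads = 1) {
  if (is.null(conditions)) conditions <- setdiff(sort(unique(retained$condition)), exclude)
  keep <- retained$bsj_reads >= min_reads
  stats::setNames(lapply(conditions, function(cc) {
    sub <- retained[keep & retained$condition == cc, , drop = FALSE]
    unique(make_circ_id(sub$contig, sub$acceptor, sub$donor, sub$strand))
  }), conditions)
}

#' Circular-to-linear ratio
#'
#' `clr = circ / (circ + linear)`, defined as 0 when both counts are zero.
#'
#' @param circ_reads,linear_reads Non-negative counts (vectorized).
#' @return Numeric vector of ratios in `[0,1]`.
#' @export
circ_linear_ratio <- function(circ_reads, linear_reads) {
  if (any(circ_reads < 0) || any(linear_reads < 0)) stop("counts must be non-negative")
  tot <- circ_reads + linear_reads
  ifelse(tot == 0, 0, circ_reads / tot)
}

#' Per-site, per-library-type BSJ statistics with CLR
#'
#' Aggregates BSJ-supporting and linear reads over samples at each junction
#' site, separately for RNase R and control libraries.
#'
#' @param bsj BSJ candidate data.frame.
#' @param linear data.frame of linear reads with columns `contig`,
#'   `acceptor`, `donor`, `strand`, `sample_id`, `library`, `linear_reads`.
#' @return data.frame: `circ_id`, `library`, `circ_reads`, `linear_reads`,
#'   `clr`.
#' @export
bsj_site_stats <- function(bsj, linear) {
  ck <- interaction(make_circ_id(bsj$contig, bsj$acceptor, bsj$donor, bsj$strand),
                    bsj$library, drop = TRUE, sep = "\r")
  circ_agg <- tapply(bsj$bsj_reads, ck, sum)
  lk <- interaction(make_circ_id(linear$contig, linear$acceptor, linear$donor,
                                 linear$strand),
                    linear$library, drop = TRUE, sep = "\r")
  lin_agg <- tapply(linear$linear_reads, lk, sum)
  keys <- union(names(circ_agg), names(lin_agg))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    circ_id = vapply(parts, `[`, character(1), 1),
    library = vapply(parts, `[`, character(1), 2),
    circ_reads = ifelse(keys %in% names(circ_agg), circ_agg[keys], 0),
    linear_reads = ifelse(keys %in% names(lin_agg), lin_agg[keys], 0),
    stringsAsFactors = FALSE
  )
  out$clr <- circ_linear_ratio(out$circ_reads, out$linear_reads)
  rownames(out) <- NULL
  out[order(out$circ_id, out$library), , drop = FALSE]
}

#' RNase R vs control contrast of CLR distributions
#'
#' Two views of the library contrast at BSJ sites: Fisher's exact test on
#' the 2x2 of library type against sites above/below a CLR cutoff, and a
#' two-sided Wilcoxon rank-sum test on the CLR values themselves.
#'
#' @param site_stats Output of [bsj_site_stats()].
#' @param clr_cutoff CLR cutoff for the contingency table (default 0.5).
#' @return List with `fisher_p`, `table`, `wilcox_p`, and per-library
#'   median CLR.
#' @export
clr_library_contrast <- function(site_stats, clr_cutoff = 0.5) {
  rn <- site_stats$clr[site_stats$library == "rnaser"]
  ct <- site_stats$clr[site_stats$library == "control"]
  if (!length(rn) || !length(ct)) stop("both library types required")
  tab <- rbind(rnaser = c(high = sum(rn >= clr_cutoff), low = sum(rn < clr_cutoff)),
               control = c(high = sum(ct >= clr_cutoff), low = sum(ct < clr_cutoff)))
  list(fisher_p = stats::fisher.test(tab)$p.value,
       table = tab,
       wilcox_p = stats::wilcox.test(rn, ct, exact = FALSE)$p.value,
       median_clr = c(rnaser = stats::median(rn), control = stats::median(ct)))
}
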