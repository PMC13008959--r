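## Chloroplast circRNA accounting: read/junction fraction per library type
## and 3'-terminus clustering enrichment by permutation.

#' Chloroplast fraction of the circRNA pool
#'
#' Tallies BSJ-supporting reads and unique junctions on chloroplast contigs
#' versus all others, overall and per library type. Both tallies are
#' reported because "fraction of the circRNA pool" can be read either way.
#'
#' @param bsj BSJ candidate data.frame (see [read_bsj_table()]).
#' @param chloroplast_contigs Character vector of chloroplast contig names.
#' @return List: `overall` (reads and junction tallies with fractions) and
#'   `per_library` (data.frame by library type).
#' @export
organelle_fraction <- function(bsj, chloroplast_contigs) {
  is_cp <- bsj$contig %in% chloroplast_contigs
  tally <- function(sub, cp) {
    reads_cp <- sum(sub$bsj_reads[cp])
    reads_all <- sum(sub$bsj_reads)
    j <- unique(make_circ_id(sub$contig, sub$acceptor, sub$donor, sub$strand)[cp])
    j_all <- unique(make_circ_id(sub$contig, sub$acceptor, sub$donor, sub$strand))
    list(reads_chloroplast = reads_cp,
         reads_other = reads_all - reads_cp,
         fraction_reads = if (reads_all > 0) reads_cp / reads_all else NA_real_,
         junctions_chloroplast = length(j),
         junctions_other = length(j_all) - length(j),
         fraction_junctions = if (length(j_all) > 0) length(j) / length(j_all) else NA_real_)
  }
  per_lib <- do.call(rbind, lapply(sort(unique(bsj$library)), function(lb) {
    idx <- bsj$library == lb
    t <- tally(bsj[idx, , drop = FALSE], is_cp[idx])
    data.frame(library = lb, as.data.frame(t), stringsAsFactors = FALSE)
  }))
  rownames(per_lib) <- NULL
  list(overall = tally(bsj, is_cp), per_library = per_lib)
}

#' 3'-terminal window of a gene
#'
#' The last `window_size` bp of the gene in transcription direction: the
#' high-coordinate end on the plus strand, the low-coordinate end on the
#' minus strand.
#'
#' @param gene_start,gene_end,gene_strand Gene span (0-based half-open) and
#'   strand.
#' @param window_size Window size in bp (<= gene length).
#' @return List `start`, `end` (0-based half-open).
#' @export
terminal_window <- function(gene_start, gene_end, gene_strand, window_size) {
  len <- gene_end - gene_start
  if (window_size > len) stop("window exceeds gene length")
  if (gene_strand == "-") {
    list(start = gene_start, end = gene_start + window_size)
  } else {
    list(start = gene_end - window_size, end = gene_end)
  }
}

#' Permutation test for 3'-terminus clustering of BSJ endpoints
#'
#' Observed statistic: fraction of BSJ endpoints (both acceptor and donor
#' by default) inside the gene's 3'-terminal window. Null: the same number
#' of endpoints placed uniformly within the gene. p = (1 + #\{null >=
#' observed\}) / (n_perm + 1), never zero and reproducible under the seed.
#'
#' @param bsj BSJ data.frame restricted to junctions at the locus (columns
#'   `acceptor`, `donor`); duplicated junction rows should be collapsed
#'   first if each junction is to count once.
#' @param gene_start,gene_end,gene_strand Gene span and strand.
#' @param window_size 3' window in bp; default 20% of the gene length.
#' @param n_perm Number of permutations (default 2000).
#' @param seed RNG seed.
#' @param endpoints `"both"` (each junction contributes acceptor and donor)
#'   or `"acceptor"`/`"donor"`.
#' @return List: `n_total`, `n_in_window`, `observed_fraction`,
#'   `permutation_p`, `n_permutations`, `seed`, `window`.
#' @export
clustering_enrichment <- function(bsj, gene_start, gene_end, gene_strand,
                                  window_size = NULL, n_perm = 2000,
                                  seed = 1, endpoints = c("both", "acceptor", "donor")) {
  endpoints <- match.arg(endpoints)
  if (is.null(window_size)) {
    window_size <- floor(0.2 * (gene_end - gene_start))
  }
  win <- terminal_window(gene_start, gene_end, gene_strand, window_size)
  pts <- switch(endpoints,
                both = c(bsj$acceptor, bsj$donor),
                acceptor = bsj$acceptor,
                donor = bsj$donor)
  if (length(pts) < 1) stop("need at least one BSJ endpoint")
  inside <- function(x) x >= win$start & x < win$end
  n <- length(pts)
  obs <- mean(inside(pts))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean(inside(sample(gene_start:(gene_end - 1L), n, replace = TRUE)))
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(n_total = n, n_in_window = sum(inside(pts)), observed_fraction = obs,
       permutation_p = p, n_permutations = n_perm, seed = seed,
       window = win)
}
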