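## Structural classification of circRNAs against gene models: multi-exonic,
## single-exonic, intronic, or unclassified, plus spliced lengths and
## chromosome distribution.

#' Classify one back-splice junction against the annotation
#'
#' A junction is multi-exonic when its acceptor matches an exon start and
#' its donor the end of a later exon of the same transcript (within
#' `tolerance` nt), spanning >= 2 exons; single-exonic when both boundaries
#' match one exon; intronic when the junction lies entirely inside one
#' intron; unclassified otherwise. When several transcripts match, the one
#' maximizing matched boundaries, then minimizing the number of exons in the
#' circle, then first by transcript id is chosen, so assignment is
#' deterministic.
#'
#' @param contig,acceptor,donor,strand Junction key (0-based half-open).
#' @param annotation An [annotation_set()].
#' @param tolerance Boundary match tolerance in nt (default 0 = exact).
#' @return List: `circ_type`, `transcript_id`, `n_exons_in_circ`,
#'   `exon_from`, `exon_to`, `spliced_length`.
#' @export
classify_type <- function(contig, acceptor, donor, strand, annotation,
                          tolerance = 0) {
  genes <- containing_genes(annotation, contig, acceptor, donor)
  txs <- annotation$transcripts$transcript_id[
    annotation$transcripts$gene_id %in% genes]
  best <- NULL
  for (t in sort(txs)) {
    ex <- transcript_exons(annotation, t)
    i <- which(abs(ex$start - acceptor) <= tolerance)
    j <- which(abs(ex$end - donor) <= tolerance)
    if (length(i) && length(j)) {
      i <- min(i); j <- max(j)
      if (j >= i) {
        n <- j - i + 1L
        cand <- list(transcript_id = t, n = n, exon_from = i, exon_to = j,
                     spliced = sum(ex$end[i:j] - ex$start[i:j]))
        if (is.null(best) || cand$n < best$n) best <- cand
      }
    }
  }
  if (!is.null(best)) {
    return(list(circ_type = if (best$n >= 2) "multi-exonic" else "single-exonic",
                transcript_id = best$transcript_id,
                n_exons_in_circ = best$n,
                exon_from = best$exon_from, exon_to = best$exon_to,
                spliced_length = best$spliced))
  }
  # no exon-boundary match: intron containment
  for (t in sort(txs)) {
    intr <- transcript_introns(annotation, t)
    hit <- which(intr$start <= acceptor & donor <= intr$end)
    if (length(hit)) {
      return(list(circ_type = "intronic", transcript_id = t,
                  n_exons_in_circ = 0L,
                  exon_from = NA_integer_, exon_to = NA_integer_,
                  spliced_length = donor - acceptor))
    }
  }
  list(circ_type = "unclassified", transcript_id = NA_character_,
       n_exons_in_circ = NA_integer_, exon_from = NA_integer_,
       exon_to = NA_integer_, spliced_length = NA_integer_)
}

#' Classify a set of circRNAs
#'
#' Vectorized wrapper over [classify_type()].
#'
#' @param circ data.frame with `circ_id`, `contig`, `acceptor`, `donor`,
#'   `strand` (e.g. from [merge_unique()]).
#' @param annotation An [annotation_set()].
#' @param tolerance Boundary tolerance in nt.
#' @return data.frame: one row per circRNA with type, matched transcript,
#'   exon span and spliced length.
#' @export
classify_circs <- function(circ, annotation, tolerance = 0) {
  rows <- lapply(seq_len(nrow(circ)), function(k) {
    cl <- classify_type(circ$contig[k], circ$acceptor[k], circ$donor[k],
                        circ$strand[k], annotation, tolerance)
    data.frame(circ_id = circ$circ_id[k], contig = circ$contig[k],
               acceptor = circ$acceptor[k], donor = circ$donor[k],
               strand = circ$strand[k],
               circ_type = cl$circ_type, transcript_id = cl$transcript_id,
               n_exons_in_circ = cl$n_exons_in_circ,
               exon_from = cl$exon_from, exon_to = cl$exon_to,
               spliced_length = cl$spliced_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spliced length of a classified circRNA
#'
#' Exonic circles: sum of the contained exon lengths; intronic circles:
#' genomic span. Errors for unclassified circles.
#'
#' @param classification One row of [classify_circs()] output (data.frame or
#'   list).
#' @return Length in nt.
#' @export
spliced_length <- function(classification) {
  if (classification$circ_type == "unclassified") {
    stop("spliced length undefined for unclassified circRNA")
  }
  classification$spliced_length
}

#' Spliced sequence of a classified circRNA
#'
#' Exonic circles: concatenation of the contained exon sequences; intronic
#' circles: the genomic segment. Minus-strand circles are reverse
#' complemented.
#'
#' @param classification One row of [classify_circs()] output.
#' @param annotation An [annotation_set()].
#' @param genome A [genome_sequence()].
#' @return Character scalar.
#' @export
circ_sequence <- function(classification, annotation, genome) {
  ct <- classification$circ_type
  if (ct == "unclassified") stop("sequence undefined for unclassified circRNA")
  if (ct == "intronic") {
    s <- genome_subseq(genome, classification$contig,
                       classification$acceptor, classification$donor)
  } else {
    ex <- transcript_exons(annotation, classification$transcript_id)
    idx <- classification$exon_from:classification$exon_to
    s <- paste(vapply(idx, function(i) {
      genome_subseq(genome, ex$contig[i], ex$start[i], ex$end[i])
    }, character(1)), collapse = "")
  }
  if (classification$strand == "-") s <- reverse_complement(s)
  s
}

#' Chromosomal distribution of circRNAs and their host genes
#'
#' @param circ data.frame of circRNAs with `contig` and optionally
#'   `host_genes` (comma-separated).
#' @param anchored_regex Regular expression naming anchored chromosomes;
#'   contigs not matching are summarized under "scaffold" as well as listed.
#' @return List with `per_contig` (data.frame: contig, n_circ,
#'   n_host_genes) and `n_unanchored`.
#' @export
chromosome_distribution <- function(circ, anchored_regex = "^Chr") {
  if (nrow(circ) == 0) {
    return(list(per_contig = data.frame(contig = character(0), n_circ = integer(0),
                                        n_host_genes = integer(0)),
                n_unanchored = 0L))
  }
  contigs <- sort(unique(circ$contig))
  per <- data.frame(
    contig = contigs,
    n_circ = vapply(contigs, function(cc) sum(circ$contig == cc), integer(1)),
    n_host_genes = vapply(contigs, function(cc) {
      if (!"host_genes" %in% names(circ)) return(NA_integer_)
      hg <- unlist(strsplit(circ$host_genes[circ$contig == cc], ","))
      length(unique(hg[nzchar(hg)]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per) <- NULL
  list(per_contig = per,
       n_unanchored = sum(per$n_circ[!grepl(anchored_regex, per$contig)]))
}
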