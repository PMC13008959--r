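#' @useDynLib circstress, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## ---------------------------------------------------------------------------
## Sequence model
## ---------------------------------------------------------------------------

#' Create a genome sequence object
#'
#' A genome is a named set of contig sequences over the alphabet
#' \{A,C,G,T,N\}. All internal coordinates in the package are 0-based
#' half-open on these sequences.
#'
#' @param contigs Named character vector of uppercase nucleotide sequences.
#' @return An object of class `genome_sequence` with elements `contigs`
#'   (named character vector) and `lengths` (named integer vector).
#' @export
genome_sequence <- function(contigs) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs)))) {
    stop("contigs must have unique non-empty names")
  }
  contigs <- toupper(unlist(contigs))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("illegal character in contig(s): ", paste(names(contigs)[bad], collapse = ", "))
  }
  structure(list(contigs = contigs, lengths = nchar(contigs)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence with", length(x$contigs), "contig(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Read a genome from a FASTA file
#' @param path FASTA file (optionally wrapped).
#' @return A [genome_sequence()] object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome_sequence(stats::setNames(as.character(ss), names(ss)))
}

#' Write a genome to a FASTA file (60-column wrapped)
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Extract a subsequence (0-based half-open coordinates)
#' @param genome A [genome_sequence()].
#' @param contig Contig name.
#' @param start,end 0-based half-open coordinates.
#' @return Character scalar.
#' @export
genome_subseq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome$contigs)) stop("unknown contig: ", contig)
  len <- genome$lengths[[contig]]
  if (start < 0 || end > len || start >= end) {
    stop("invalid interval [", start, ",", end, ") on ", contig, " (length ", len, ")")
  }
  substr(genome$contigs[[contig]], start + 1L, end)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement with N preserved; errors on any other character.
#'
#' @param seq Character vector of sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("illegal character in sequence")
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## ---------------------------------------------------------------------------
## Annotation model
## ---------------------------------------------------------------------------

#' Derive introns from a sorted exon table
#'
#' Introns are the gaps between consecutive exons of one transcript.
#' Zero-length gaps (abutting exons) are treated as annotation artifacts and
#' dropped; overlapping or unsorted exons are a structural error.
#'
#' @param exons data.frame with columns `contig`, `start`, `end`, `strand`
#'   (0-based half-open), sorted by `start`, all on one contig/strand.
#' @return data.frame of intron intervals with the same columns
#'   (`length(exons) - 1` rows at most).
#' @export
derive_introns <- function(exons) {
  empty <- exons[0, c("contig", "start", "end", "strand"), drop = FALSE]
  n <- nrow(exons)
  if (n <= 1) return(empty)
  if (length(unique(exons$contig)) != 1 || length(unique(exons$strand)) != 1) {
    stop("exons must share one contig and strand")
  }
  if (is.unsorted(exons$start, strictly = FALSE)) stop("exons must be sorted by start")
  if (any(exons$start[-1] < exons$end[-n])) stop("overlapping exons in transcript")
  introns <- data.frame(
    contig = exons$contig[1],
    start = exons$end[-n],
    end = exons$start[-1],
    strand = exons$strand[1],
    stringsAsFactors = FALSE
  )
  introns[introns$end > introns$start, , drop = FALSE]
}

#' Assemble an annotation set
#'
#' The central gene-model container: genes, transcripts, exons, derived
#' introns, and an interval index over gene spans. Exons use 0-based
#' half-open coordinates.
#'
#' @param genes data.frame: `gene_id`, `contig`, `start`, `end`, `strand`.
#' @param transcripts data.frame: `transcript_id`, `gene_id`.
#' @param exons data.frame: `transcript_id`, `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @return An `annotation_set` object with derived per-transcript introns,
#'   per-gene feature counts (`n_exons_max` = max exon count over isoforms,
#'   `n_isoforms`), and a `GRanges` index of gene spans.
#' @export
annotation_set <- function(genes, transcripts, exons) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)),
            all(c("transcript_id", "gene_id") %in% names(transcripts)),
            all(c("transcript_id", "gene_id", "contig", "start", "end", "strand") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript ids")
  if (!all(transcripts$gene_id %in% genes$gene_id)) stop("transcript with unknown gene")
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) stop("exon with unknown transcript")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  introns <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(ex) {
    intr <- derive_introns(ex)
    if (nrow(intr) == 0) return(NULL)
    intr$transcript_id <- ex$transcript_id[1]
    intr$gene_id <- ex$gene_id[1]
    intr
  }))
  if (is.null(introns)) {
    introns <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                          strand = character(0), transcript_id = character(0),
                          gene_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL

  n_exons_by_tx <- table(exons$transcript_id)
  tx_exon_counts <- as.integer(n_exons_by_tx[transcripts$transcript_id])
  feat <- data.frame(
    gene_id = genes$gene_id,
    n_exons_max = vapply(genes$gene_id, function(g) {
      idx <- transcripts$gene_id == g
      if (!any(idx)) return(NA_integer_)
      max(tx_exon_counts[idx])
    }, integer(1)),
    n_isoforms = vapply(genes$gene_id, function(g) sum(transcripts$gene_id == g), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(feat) <- NULL

  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  names(gr) <- genes$gene_id

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 introns = introns, gene_features = feat, index = gr),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Genes overlapping a query interval
#'
#' @param annotation An [annotation_set()].
#' @param contig,start,end Query interval (0-based half-open).
#' @param strand Optional; when given, only genes on that strand match
#'   (strand-agnostic by default).
#' @return Character vector of gene ids overlapping the query by >= 1 bp.
#' @export
locate_genes <- function(annotation, contig, start, end, strand = NULL) {
  if (!contig %in% as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(annotation$index))) &&
      !contig %in% unique(annotation$genes$contig)) {
    stop("unknown contig: ", contig)
  }
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, annotation$index, ignore.strand = TRUE)
  ids <- names(annotation$index)[S4Vectors::subjectHits(hits)]
  if (!is.null(strand)) {
    ids <- ids[annotation$genes$strand[match(ids, annotation$genes$gene_id)] == strand]
  }
  sort(unique(ids))
}

#' Genes fully containing an interval
#'
#' Used for the intragenic call on back-splice junctions: both endpoints of
#' the junction must sit inside one and the same gene.
#'
#' @inheritParams locate_genes
#' @return Character vector of gene ids whose span contains `[start, end)`.
#' @export
containing_genes <- function(annotation, contig, start, end, strand = NULL) {
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, annotation$index, type = "within",
                                      ignore.strand = TRUE)
  ids <- names(annotation$index)[S4Vectors::subjectHits(hits)]
  if (!is.null(strand)) {
    ids <- ids[annotation$genes$strand[match(ids, annotation$genes$gene_id)] == strand]
  }
  sort(unique(ids))
}

#' Exons of one transcript, sorted by genomic start
#' @param annotation An [annotation_set()].
#' @param transcript_id Transcript id.
#' @return data.frame of exon intervals.
#' @export
transcript_exons <- function(annotation, transcript_id) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown transcript: ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

#' Introns of one transcript, sorted by genomic start
#' @inheritParams transcript_exons
#' @return data.frame of intron intervals (possibly empty).
#' @export
transcript_introns <- function(annotation, transcript_id) {
  intr <- annotation$introns[annotation$introns$transcript_id == transcript_id, , drop = FALSE]
  intr[order(intr$start), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## GFF3 / BED I/O (1-based closed at the boundary, 0-based half-open inside)
## ---------------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Consumes `gene`, `mRNA` and `exon` features linked through `ID`/`Parent`
#' attributes and converts to the internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  take <- function(type) df[df$type == type, , drop = FALSE]
  g <- take("gene"); tx <- take("mRNA"); ex <- take("exon")
  parent1 <- function(p) vapply(p, function(x) as.character(x)[1], character(1))
  genes <- data.frame(gene_id = g$ID, contig = g$seqnames,
                      start = g$start - 1L, end = g$end, strand = g$strand,
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = tx$ID, gene_id = parent1(tx$Parent),
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = parent1(ex$Parent),
                      gene_id = transcripts$gene_id[match(parent1(ex$Parent),
                                                          transcripts$transcript_id)],
                      contig = ex$seqnames, start = ex$start - 1L, end = ex$end,
                      strand = ex$strand, stringsAsFactors = FALSE)
  annotation_set(genes, transcripts, exons)
}

#' Write gene models to GFF3
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes; tx <- annotation$transcripts; ex <- annotation$exons
  tx_contig <- g$contig[match(tx$gene_id, g$gene_id)]
  tx_ranges <- do.call(rbind, lapply(tx$transcript_id, function(t) {
    e <- annotation$exons[annotation$exons$transcript_id == t, ]
    c(min(e$start), max(e$end))
  }))
  mk <- function(contig, start0, end0, strand, type, id = NA, parent = NA) {
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1L, end0),
                                 strand = ifelse(strand %in% c("+", "-"), strand, "*"))
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- as(ifelse(is.na(parent), list(character(0)),
                                             as.list(parent)), "CharacterList")
    gr
  }
  out <- c(
    mk(g$contig, g$start, g$end, g$strand, "gene", id = g$gene_id),
    mk(tx_contig, tx_ranges[, 1], tx_ranges[, 2],
       g$strand[match(tx$gene_id, g$gene_id)], "mRNA",
       id = tx$transcript_id, parent = tx$gene_id),
    mk(ex$contig, ex$start, ex$end, ex$strand, "exon",
       id = NA_character_, parent = ex$transcript_id)
  )
  S4Vectors::mcols(out)$source <- "circstress"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED6 (0-based half-open, as BED requires)
#' @param df data.frame with columns `contig`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  bed <- data.frame(
    chrom = df$contig,
    chromStart = df$start,
    chromEnd = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Canonical circRNA identifier for a back-splice junction
#' @param contig,acceptor,donor,strand Junction key fields (0-based
#'   half-open; acceptor is the 5'-most genomic coordinate).
#' @return Character vector of ids.
#' @export
make_circ_id <- function(contig, acceptor, donor, strand) {
  sprintf("circ|%s:%d-%d:%s", contig, as.integer(acceptor), as.integer(donor), strand)
}
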