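## Cross-species conservation: ortholog-overlap hypergeometric test and
## splice-site conservation classification (Accordant / Half-accordant /
## Unaccordant) through pairwise alignment of orthologous gene sequences.

#' Hypergeometric test for circRNA host-gene ortholog overlap
#'
#' With N ortholog pairs, K pairs whose species-A member is a host and n
#' pairs whose species-B member is a host, the overlap (pairs with both
#' members hosts) is tested against the upper hypergeometric tail
#' P(X >= overlap).
#'
#' @param hosts_a,hosts_b Character vectors of host gene ids per species.
#' @param ortholog_map data.frame with columns `gene_a`, `gene_b` (unique
#'   pairs).
#' @return List: `overlap`, `p`, `N`, `K`, `n`.
#' @export
ortholog_overlap_test <- function(hosts_a, hosts_b, ortholog_map) {
  if (nrow(ortholog_map) == 0) stop("empty ortholog map")
  if (anyDuplicated(ortholog_map[, c("gene_a", "gene_b")])) {
    stop("ortholog pairs must be unique")
  }
  in_a <- ortholog_map$gene_a %in% hosts_a
  in_b <- ortholog_map$gene_b %in% hosts_b
  N <- nrow(ortholog_map); K <- sum(in_a); n <- sum(in_b)
  overlap <- sum(in_a & in_b)
  p <- if (K == 0 || n == 0) 1 else {
    stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  }
  list(overlap = overlap, p = min(1, p), N = N, K = K, n = n)
}

# shared alignment scoring for coordinate projection
.ortho_align <- function(a, b, type) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 1)
}

#' Full base-level coordinate map between two orthologous gene sequences
#'
#' Global alignment (match +1, mismatch -1, gap opening 5, gap extension
#' 1); suitable for gene sequences of a few kb. Returns a map from 0-based
#' positions in gene A to 0-based positions in gene B (NA where a base
#' aligns to a gap).
#'
#' @param seq_a,seq_b Gene sequences.
#' @return Integer vector of length `nchar(seq_a)`; element i+1 holds the
#'   B position aligned to A position i, or NA.
#' @export
ortholog_alignment_map <- function(seq_a, seq_b) {
  aln <- .ortho_align(seq_a, seq_b, "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(seq_a))
  i <- 0L; j <- 0L
  for (k in seq_along(pa)) {
    ap <- pa[k] != "-"; bp <- sa[k] != "-"
    if (ap && bp) map[i + 1L] <- j
    if (ap) i <- i + 1L
    if (bp) j <- j + 1L
  }
  map
}

#' Map a splice-site position through a precomputed coordinate map
#'
#' Positions are 0-based boundaries within the gene sequence: a `start`
#' boundary maps through the base to its right, an `end` boundary
#' (exclusive) through the base to its left.
#'
#' @param pos 0-based position in gene A.
#' @param map Output of [ortholog_alignment_map()].
#' @param type `"start"` or `"end"`.
#' @return Mapped 0-based position in gene B, or NA when the site aligns
#'   to a gap.
#' @export
map_splice_site <- function(pos, map, type = c("start", "end")) {
  type <- match.arg(type)
  n <- length(map)
  if (type == "start") {
    if (pos < 0 || pos >= n) stop("site outside gene A")
    map[pos + 1L]
  } else {
    if (pos < 1 || pos > n) stop("site outside gene A")
    m <- map[pos]
    if (is.na(m)) NA_integer_ else m + 1L
  }
}

#' Map a splice site via a site-anchored windowed alignment
#'
#' Extracts a window around the site in gene A and locally aligns it to
#' the full gene B sequence; the site's base is projected through the
#' alignment. Linear in the gene-B length per site, so it scales to genes
#' far beyond what a full global alignment map allows.
#'
#' @param pos 0-based site position in gene A.
#' @param seq_a,seq_b Gene sequences.
#' @param type `"start"` or `"end"` boundary.
#' @param window Half-window size in nt around the site (default 200).
#' @return Mapped 0-based position in gene B, or NA.
#' @export
map_splice_site_windowed <- function(pos, seq_a, seq_b,
                                     type = c("start", "end"), window = 200) {
  type <- match.arg(type)
  n <- nchar(seq_a)
  base_idx <- if (type == "start") pos else pos - 1L
  if (base_idx < 0 || base_idx >= n) stop("site outside gene A")
  wlo <- max(0L, base_idx - window)
  whi <- min(n, base_idx + window)
  awin <- substr(seq_a, wlo + 1L, whi)
  aln <- .ortho_align(awin, seq_b, "local")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- wlo + Biostrings::start(Biostrings::pattern(aln)) - 1L  # 0-based A index
  j <- Biostrings::start(Biostrings::subject(aln)) - 1L        # 0-based B index
  mapped <- NA_integer_
  for (k in seq_along(pa)) {
    ap <- pa[k] != "-"; bp <- sa[k] != "-"
    if (ap && i == base_idx) {
      mapped <- if (bp) j else NA_integer_
      break
    }
    if (ap) i <- i + 1L
    if (bp) j <- j + 1L
  }
  if (is.na(mapped)) return(NA_integer_)
  if (type == "start") mapped else mapped + 1L
}

#' Classify splice-site conservation of an orthologous circRNA pair
#'
#' A site is conserved iff its position mapped into gene B differs from
#' the partner circle's site by at most `tolerance` nt. Accordant = both
#' sites conserved; Half-accordant = exactly one; Unaccordant = neither
#' (unmappable sites count as not conserved).
#'
#' @param acc_a,don_a Gene-local 0-based half-open junction of the A
#'   circle.
#' @param acc_b,don_b Junction of the B circle, gene-local 0-based.
#' @param seq_a,seq_b Gene sequences (transcription orientation).
#' @param tolerance Positional tolerance in nt (default 10).
#' @param window Alignment half-window (see
#'   [map_splice_site_windowed()]).
#' @return List: `acceptor_conserved`, `donor_conserved`, `category`,
#'   `acceptor_distance`, `donor_distance`.
#' @export
classify_conservation <- function(acc_a, don_a, acc_b, don_b, seq_a, seq_b,
                                  tolerance = 10, window = 200) {
  ma <- map_splice_site_windowed(acc_a, seq_a, seq_b, "start", window)
  md <- map_splice_site_windowed(don_a, seq_a, seq_b, "end", window)
  da <- if (is.na(ma)) NA_integer_ else abs(ma - acc_b)
  dd <- if (is.na(md)) NA_integer_ else abs(md - don_b)
  ac <- !is.na(da) && da <= tolerance
  dc <- !is.na(dd) && dd <= tolerance
  category <- if (ac && dc) "Accordant" else if (ac || dc) "Half-accordant" else "Unaccordant"
  list(acceptor_conserved = ac, donor_conserved = dc, category = category,
       acceptor_distance = da, donor_distance = dd)
}

#' Convert genomic junction coordinates to gene-local coordinates
#'
#' Gene-local coordinates run 5' to 3' in transcription direction, 0-based
#' half-open; on the minus strand the genomic endpoints swap roles.
#'
#' @param acceptor,donor Genomic coordinates (0-based half-open).
#' @param gene_start,gene_end,gene_strand Gene span and strand.
#' @return List `start`, `end` (local coordinates, start < end).
#' @export
junction_to_local <- function(acceptor, donor, gene_start, gene_end, gene_strand) {
  if (gene_strand == "-") {
    list(start = gene_end - donor, end = gene_end - acceptor)
  } else {
    list(start = acceptor - gene_start, end = donor - gene_start)
  }
}

#' Conservation calls for all circRNA pairs of orthologous host genes
#'
#' For every ortholog pair hosting circRNAs in both species, every A x B
#' circle pair is classified and the most-conserved category per A circle
#' is reported.
#'
#' @param circ_a data.frame: `circ_id`, `gene_id`, `acceptor`, `donor`
#'   (genomic) for species A (`gene_id` = host gene).
#' @param circ_b Same for species B.
#' @param ortholog_map data.frame `gene_a`, `gene_b`.
#' @param annotation_a,annotation_b [annotation_set()] per species.
#' @param genome_a,genome_b [genome_sequence()] per species.
#' @param tolerance Positional tolerance in nt.
#' @return data.frame of per-A-circle best calls: `circ_a`, `circ_b`,
#'   `gene_a`, `gene_b`, `category`.
#' @export
conservation_calls <- function(circ_a, circ_b, ortholog_map,
                               annotation_a, annotation_b,
                               genome_a, genome_b, tolerance = 10) {
  rank <- c(Accordant = 1, `Half-accordant` = 2, Unaccordant = 3)
  rows <- list()
  for (p in seq_len(nrow(ortholog_map))) {
    ga <- ortholog_map$gene_a[p]; gb <- ortholog_map$gene_b[p]
    ca <- circ_a[circ_a$gene_id == ga, , drop = FALSE]
    cb <- circ_b[circ_b$gene_id == gb, , drop = FALSE]
    if (nrow(ca) == 0 || nrow(cb) == 0) next
    gra <- annotation_a$genes[annotation_a$genes$gene_id == ga, ]
    grb <- annotation_b$genes[annotation_b$genes$gene_id == gb, ]
    sa <- genome_subseq(genome_a, gra$contig, gra$start, gra$end)
    sb <- genome_subseq(genome_b, grb$contig, grb$start, grb$end)
    if (gra$strand == "-") sa <- reverse_complement(sa)
    if (grb$strand == "-") sb <- reverse_complement(sb)
    for (i in seq_len(nrow(ca))) {
      la <- junction_to_local(ca$acceptor[i], ca$donor[i],
                              gra$start, gra$end, gra$strand)
      best <- NULL
      for (j in seq_len(nrow(cb))) {
        lb <- junction_to_local(cb$acceptor[j], cb$donor[j],
                                grb$start, grb$end, grb$strand)
        call <- classify_conservation(la$start, la$end, lb$start, lb$end,
                                      sa, sb, tolerance)
        if (is.null(best) || rank[call$category] < rank[best$category]) {
          best <- call; best$circ_b <- cb$circ_id[j]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        circ_a = ca$circ_id[i], circ_b = best$circ_b,
        gene_a = ga, gene_b = gb, category = best$category,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(circ_a = character(0), circ_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category counts over conservation calls
#'
#' @param calls Output of [conservation_calls()].
#' @return Named integer vector (Accordant, Half-accordant, Unaccordant).
#' @export
conservation_summary <- function(calls) {
  cats <- c("Accordant", "Half-accordant", "Unaccordant")
  out <- vapply(cats, function(cc) sum(calls$category == cc), integer(1))
  names(out) <- cats
  out
}
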