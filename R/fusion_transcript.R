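# Consensus junction assembly from junction-crossing reads, exon-boundary
# assignment, fusion cDNA modelling, and in-silico PCR validation.

#' Build the consensus junction from split reads
#'
#' Junction-crossing reads are stacked anchored at their split point and a
#' per-column majority vote is taken; exact ties are broken alphabetically
#' (A < C < G < T) so the consensus stays free of ambiguity codes and can be
#' translated downstream. Columns with no coverage are trimmed. The terminal
#' hexamers on each side of the junction are extracted as breakpoint motifs.
#'
#' @param splits List of `split_alignment` objects supporting one breakpoint
#'   cluster (same oriented gene pair, breakpoints within `cluster_tol`).
#' @param cluster_tol Maximum breakpoint scatter tolerated before the reads
#'   are declared conflicting.
#' @return An object of class `fusion_junction`.
#' @export
build_consensus_junction <- function(splits, cluster_tol = 5L) {
  if (length(splits) == 0L) stop("at least one split read required", call. = FALSE)
  g5 <- vapply(splits, function(s) s$gene5, "")
  g3 <- vapply(splits, function(s) s$gene3, "")
  bp5 <- vapply(splits, function(s) s$bp5, 0L)
  bp3 <- vapply(splits, function(s) s$bp3, 0L)
  if (length(unique(g5)) > 1L || length(unique(g3)) > 1L ||
      diff(range(bp5)) > cluster_tol || diff(range(bp3)) > cluster_tol) {
    stop("split reads support conflicting breakpoints (cluster conflict)",
         call. = FALSE)
  }
  # column index relative to the junction: <= 0 is 5' side, >= 1 is 3' side
  votes <- list()
  for (s in splits) {
    chars <- strsplit(s$oriented_seq, "")[[1]]
    cols <- seq_along(chars) - s$junction_offset_in_read
    for (i in seq_along(chars)) {
      key <- as.character(cols[i])
      votes[[key]] <- c(votes[[key]], chars[i])
    }
  }
  col_idx <- sort(as.integer(names(votes)))
  consensus <- vapply(as.character(col_idx), function(k) {
    tab <- table(factor(votes[[k]], levels = DNA_BASES))
    names(tab)[which.max(tab)]  # which.max: first max, i.e. A < C < G < T
  }, "")
  seqc <- paste(consensus, collapse = "")
  junction_offset <- sum(col_idx <= 0L)
  five_motif <- substr(seqc, junction_offset - 5L, junction_offset)
  three_motif <- substr(seqc, junction_offset + 1L, junction_offset + 6L)
  structure(list(consensus_seq = seqc, junction_offset = junction_offset,
                 five_gene = g5[1], three_gene = g3[1],
                 bp5 = modal_value(bp5), bp3 = modal_value(bp3),
                 five_motif = five_motif, three_motif = three_motif,
                 n_supporting_reads = length(unique(vapply(splits, function(s) s$read_id, ""))),
                 five_boundary = NULL, three_boundary = NULL),
            class = "fusion_junction")
}

#' @export
print.fusion_junction <- function(x, ...) {
  cat(sprintf("fusion_junction %s|%s: %d reads, motifs %s / %s\n",
              x$five_gene, x$three_gene, x$n_supporting_reads,
              x$five_motif, x$three_motif))
  invisible(x)
}

#' Assign exon boundaries to a fusion junction
#'
#' The 5' breakpoint is matched to the nearest annotated exon *end* of the
#' 5' gene and the 3' breakpoint to the nearest exon *start* of the 3' gene
#' (in spliced-transcript coordinates). Breakpoints farther than
#' `max_exon_boundary_distance` from any boundary raise an error.
#'
#' @param junction A `fusion_junction`.
#' @param index A `transcript_index`.
#' @param max_exon_boundary_distance Tolerance in nt (default 10).
#' @return The junction with `five_boundary` / `three_boundary` filled
#'   (gene, exon, distance, exact flag).
#' @export
map_exon_boundaries <- function(junction, index,
                                max_exon_boundary_distance = 10L) {
  d5 <- nearest_exon_boundary(index, junction$five_gene, junction$bp5, "end")
  d3 <- nearest_exon_boundary(index, junction$three_gene, junction$bp3, "start")
  if (d5$distance > max_exon_boundary_distance ||
      d3$distance > max_exon_boundary_distance) {
    stop("breakpoint lies beyond the exon-boundary tolerance (unannotated breakpoint)",
         call. = FALSE)
  }
  junction$five_boundary <- list(gene = junction$five_gene, exon = d5$exon,
                                 distance = d5$distance, exact = d5$distance == 0L)
  junction$three_boundary <- list(gene = junction$three_gene, exon = d3$exon,
                                  distance = d3$distance, exact = d3$distance == 0L)
  junction
}

#' Assemble a fusion cDNA model from exon boundaries
#'
#' Splices exons 1..b5 of the 5' gene to exons b3..n of the 3' gene.
#'
#' @param reference A `fusion_reference`.
#' @param five_boundary,three_boundary Lists with `gene` and `exon` (as
#'   produced by [map_exon_boundaries()]).
#' @return A `fusion_transcript`.
#' @export
assemble_fusion_cdna <- function(reference, five_boundary, three_boundary) {
  fusion <- planted_fusion(five_boundary$gene, five_boundary$exon,
                           three_boundary$gene, three_boundary$exon,
                           expression_weight = 0)
  build_fusion_cdna_truth(reference, fusion)
}

#' In-silico PCR
#'
#' Finds all products delimited by the forward primer and the reverse
#' complement of the reverse primer, reporting outer-to-outer amplicon
#' lengths (both primers included). Returns an empty integer vector when a
#' primer is absent or the orientation is wrong.
#'
#' @param cdna Template nucleotide string.
#' @param forward_primer,reverse_primer Primer sequences (>= 15 nt), both
#'   written 5' to 3'.
#' @return Integer vector of amplicon lengths (possibly empty), sorted.
#' @export
in_silico_pcr <- function(cdna, forward_primer, reverse_primer) {
  if (nchar(forward_primer) < 15L || nchar(reverse_primer) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  if (inherits(cdna, "fusion_transcript")) cdna <- cdna$cdna
  subject <- Biostrings::DNAString(cdna)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(forward_primer), subject)
  rev_rc <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse_primer)), subject)
  if (length(fwd) == 0L || length(rev_rc) == 0L) return(integer(0))
  sizes <- integer(0)
  for (f in Biostrings::start(fwd)) {
    for (e in Biostrings::end(rev_rc)) {
      if (e >= f + nchar(forward_primer)) sizes <- c(sizes, e - f + 1L)
    }
  }
  sort(unique(sizes))
}

#' Write a fusion junction report (FASTA + TSV)
#'
#' @param junction A `fusion_junction` with boundaries assigned.
#' @param prefix Output prefix; writes `<prefix>.fa` and `<prefix>.tsv`.
#' @param window Half-width of the consensus window written to FASTA
#'   (clipped to the available consensus).
#' @export
write_junction_report <- function(junction, prefix, window = 60L) {
  j <- junction$junction_offset
  n <- nchar(junction$consensus_seq)
  lo <- max(1L, j - window + 1L); hi <- min(n, j + window)
  fa <- Biostrings::DNAStringSet(setNames(
    substr(junction$consensus_seq, lo, hi),
    sprintf("%s|%s_junction", junction$five_gene, junction$three_gene)))
  Biostrings::writeXStringSet(fa, paste0(prefix, ".fa"))
  df <- data.frame(
    gene5 = junction$five_gene, gene3 = junction$three_gene,
    exon5 = junction$five_boundary$exon %||% NA_integer_,
    exon3 = junction$three_boundary$exon %||% NA_integer_,
    dist5 = junction$five_boundary$distance %||% NA_integer_,
    dist3 = junction$three_boundary$distance %||% NA_integer_,
    five_motif = junction$five_motif, three_motif = junction$three_motif,
    n_supporting_reads = junction$n_supporting_reads,
    stringsAsFactors = FALSE)
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
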