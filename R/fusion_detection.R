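# Turn per-sample alignment evidence into fusion candidates: discordant
# pairs propose a gene pair, at least one junction-crossing split read must
# confirm it (the false-positive filter), promiscuous genes are removed,
# and a refinement pass re-counts junction reads against a fusion reference
# built around each candidate junction.

#' Detection configuration
#'
#' Defaults: maximum distance to an exon boundary 10, maximum broken-pair
#' distance 1000, gene promiscuity threshold 7 (distinct partner cap), and
#' at least 1 junction-crossing read per candidate.
#'
#' @param max_exon_boundary_distance Breakpoints farther than this from any
#'   annotated exon boundary do not support a candidate.
#' @param max_broken_pair_distance Maximum distance between a discordant
#'   mate and the breakpoint it supports.
#' @param gene_promiscuity_threshold Genes linked to more than this many
#'   distinct partner genes are dropped with all their candidates
#'   (mapping-artifact guard; unrelated to *peptide* promiscuity in the MHC
#'   ranking stage).
#' @param min_junction_reads_fp_filter Minimum split reads per candidate.
#' @param breakpoint_cluster_tol Split-read breakpoints within this many nt
#'   are merged to the modal breakpoint.
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(max_exon_boundary_distance = 10L,
                          max_broken_pair_distance = 1000L,
                          gene_promiscuity_threshold = 7L,
                          min_junction_reads_fp_filter = 1L,
                          breakpoint_cluster_tol = 5L) {
  vals <- c(max_exon_boundary_distance, max_broken_pair_distance,
            gene_promiscuity_threshold, min_junction_reads_fp_filter,
            breakpoint_cluster_tol)
  if (any(vals < 0)) stop("detection parameters must be >= 0", call. = FALSE)
  structure(list(max_exon_boundary_distance = as.integer(max_exon_boundary_distance),
                 max_broken_pair_distance = as.integer(max_broken_pair_distance),
                 gene_promiscuity_threshold = as.integer(gene_promiscuity_threshold),
                 min_junction_reads_fp_filter = as.integer(min_junction_reads_fp_filter),
                 breakpoint_cluster_tol = as.integer(breakpoint_cluster_tol)),
            class = "detect_config")
}

empty_candidates <- function() {
  structure(data.frame(gene5 = character(), gene3 = character(),
                       bp5 = integer(), bp3 = integer(),
                       exon5 = integer(), exon3 = integer(),
                       dist5 = integer(), dist3 = integer(),
                       junction_reads = integer(), spanning_pairs = integer(),
                       stringsAsFactors = FALSE),
            splits = list())
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
}

#' Detect fusion candidates in one sample
#'
#' A candidate for gene pair (G5, G3) is emitted iff (a) at least one
#' discordant pair links the two genes with both mates within
#' `max_broken_pair_distance` of the breakpoints and (b) at least
#' `min_junction_reads_fp_filter` split reads support the same breakpoint
#' pair with both breakpoints within `max_exon_boundary_distance` of an
#' annotated exon boundary. Genes partnered with more than
#' `gene_promiscuity_threshold` distinct other genes are removed together
#' with all their candidates. Evidence counts are distinct read / pair ids.
#'
#' @param evidence Result of [collect_sample_evidence()].
#' @param index A `transcript_index`.
#' @param cfg A [detect_config()].
#' @param align_cfg The [align_config()] used to produce the evidence.
#' @return Candidate table (class keeps a `splits` attribute: the supporting
#'   split alignments per candidate, keyed `gene5|gene3`).
#' @export
detect_fusions <- function(evidence, index, cfg = detect_config(),
                           align_cfg = align_config()) {
  pairs <- evidence$pairs
  splits <- evidence$splits
  known <- names(index$seqs)
  ref_genes <- unique(c(pairs$gene1, pairs$gene2,
                        vapply(splits, function(s) s$gene5, ""),
                        vapply(splits, function(s) s$gene3, "")))
  ref_genes <- ref_genes[!is.na(ref_genes)]
  if (length(setdiff(ref_genes, known)) > 0L) {
    stop(sprintf("alignments reference genes missing from the annotation: %s",
                 paste(setdiff(ref_genes, known), collapse = ", ")),
         call. = FALSE)
  }
  disc <- pairs[pairs$class == "discordant_two_genes" & !pairs$multimapped, ,
                drop = FALSE]
  if (length(splits) == 0L || nrow(disc) == 0L) return(empty_candidates())

  # group split reads by oriented gene pair, cluster breakpoints
  keys <- vapply(splits, function(s) paste(s$gene5, s$gene3, sep = "|"), "")
  out <- list(); sup <- list()
  for (key in unique(keys)) {
    sp <- splits[keys == key]
    g5 <- sp[[1]]$gene5; g3 <- sp[[1]]$gene3
    bp5s <- vapply(sp, function(s) s$bp5, 0L)
    bp3s <- vapply(sp, function(s) s$bp3, 0L)
    bp5 <- modal_value(bp5s); bp3 <- modal_value(bp3s)
    keep <- abs(bp5s - bp5) <= cfg$breakpoint_cluster_tol &
      abs(bp3s - bp3) <= cfg$breakpoint_cluster_tol
    sp <- sp[keep]
    if (length(sp) < cfg$min_junction_reads_fp_filter) next
    # exon-boundary proximity at the modal breakpoint
    d5 <- nearest_exon_boundary(index, g5, bp5, "end")
    d3 <- nearest_exon_boundary(index, g3, bp3, "start")
    if (d5$distance > cfg$max_exon_boundary_distance ||
        d3$distance > cfg$max_exon_boundary_distance) next
    # discordant support for the same (unordered) gene pair near breakpoints
    m <- disc[(disc$gene1 == g5 & disc$gene2 == g3) |
                (disc$gene1 == g3 & disc$gene2 == g5), , drop = FALSE]
    if (nrow(m) == 0L) next
    near <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      if (m$gene1[i] == g5) {
        e5 <- m$end1[i]; s3 <- m$start2[i]
      } else {
        e5 <- m$end2[i]; s3 <- m$start1[i]
      }
      near[i] <- (bp5 - e5) >= -cfg$breakpoint_cluster_tol &&
        (bp5 - e5) <= cfg$max_broken_pair_distance &&
        (s3 - bp3) >= -cfg$breakpoint_cluster_tol &&
        (s3 - bp3) <= cfg$max_broken_pair_distance
    }
    m <- m[near, , drop = FALSE]
    if (nrow(m) == 0L) next
    out[[key]] <- data.frame(
      gene5 = g5, gene3 = g3, bp5 = bp5, bp3 = bp3,
      exon5 = d5$exon, exon3 = d3$exon,
      dist5 = d5$distance, dist3 = d3$distance,
      junction_reads = length(unique(vapply(sp, function(s) s$read_id, ""))),
      spanning_pairs = length(unique(m$pair_id)),
      stringsAsFactors = FALSE)
    sup[[key]] <- sp
  }
  if (length(out) == 0L) return(empty_candidates())
  cand <- do.call(rbind, out)
  rownames(cand) <- NULL

  # gene promiscuity guard, counted over discordant-pair gene links
  links <- unique(data.frame(a = pmin(disc$gene1, disc$gene2),
                             b = pmax(disc$gene1, disc$gene2)))
  partners <- table(c(links$a, links$b))
  promisc <- names(partners)[partners > cfg$gene_promiscuity_threshold]
  drop <- cand$gene5 %in% promisc | cand$gene3 %in% promisc
  cand <- cand[!drop, , drop = FALSE]
  sup <- sup[paste(cand$gene5, cand$gene3, sep = "|")]
  attr(cand, "splits") <- sup
  cand
}

#' Re-count junction reads against per-candidate fusion references
#'
#' For each candidate a fusion reference (±`window` nt around the junction
#' on the fusion cDNA) is built; previously unplaced reads aligning across
#' the junction with at least `min_unaligned` nt on each side increment the
#' junction-crossing count. Counts never decrease.
#'
#' @param candidates Output of [detect_fusions()].
#' @param unplaced Data frame of still-unplaced reads (`read_id`, `seq`).
#' @param index A `transcript_index`.
#' @param align_cfg An [align_config()].
#' @param window Half-width (nt) of the fusion reference around the junction.
#' @return The candidate table with updated `junction_reads` and a
#'   `refined_reads` column.
#' @export
refine_fusion_counts <- function(candidates, unplaced, index,
                                 align_cfg = align_config(), window = 150L) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates$refined_reads <- 0L
  if (is.null(unplaced) || nrow(unplaced) == 0L) return(candidates)
  for (k in seq_len(nrow(candidates))) {
    g5 <- candidates$gene5[k]; g3 <- candidates$gene3[k]
    bp5 <- candidates$bp5[k]; bp3 <- candidates$bp3[k]
    tx5 <- index$seqs[[g5]]; tx3 <- index$seqs[[g3]]
    left <- substr(tx5, max(1L, bp5 - window + 1L), bp5)
    right <- substr(tx3, bp3 + 1L, min(nchar(tx3), bp3 + window))
    fref <- paste0(left, right)
    jw <- nchar(left)  # junction offset inside the window
    accepted <- character(0)
    for (i in seq_len(nrow(unplaced))) {
      for (orient in c("+", "-")) {
        r <- if (orient == "+") unplaced$seq[i] else revcomp(unplaced$seq[i])
        a <- cpp_semiglobal(r, fref, align_cfg$mismatch_cost,
                            align_cfg$insertion_cost, align_cfg$deletion_cost)
        cols <- a$matches + a$mismatches + a$insertions + a$deletions
        identity <- a$matches / cols
        coverage <- (a$matches + a$mismatches) / nchar(r)
        spans <- a$ref_start <= jw - align_cfg$min_unaligned &&
          a$ref_end >= jw + align_cfg$min_unaligned
        if (identity >= align_cfg$similarity_fraction &&
            coverage >= align_cfg$length_fraction && spans) {
          accepted <- c(accepted, unplaced$read_id[i])
          break
        }
      }
    }
    n_new <- length(unique(accepted))
    candidates$refined_reads[k] <- n_new
    candidates$junction_reads[k] <- candidates$junction_reads[k] + n_new
  }
  candidates
}
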