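# Desk-scale read mapping with explicit cost-model semantics: integer costs
# for mismatch/insertion/deletion, length and similarity fractions, a hit
# cap, and split mapping of junction-crossing reads. Reads are mapped
# against the spliced transcriptome (one transcript per gene); transcript
# coordinates are translated back to exon boundaries via the gene models.

#' Alignment configuration
#'
#' Defaults encode the detection parameters used throughout the pipeline:
#' mismatch cost 2, insertion cost 3, deletion cost 3, length fraction 0.8,
#' similarity fraction 0.8, at most 10 hits per read, and a minimum of 15 nt
#' of unaligned sequence before a split mapping is attempted.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost Positive integer costs.
#' @param length_fraction Minimum fraction of the read aligned to reference
#'   bases (match or mismatch columns), in (0, 1].
#' @param similarity_fraction Minimum identity over aligned columns
#'   (matches / all alignment columns, indel columns included), in (0, 1].
#' @param max_hits Reads with more reported hits than this are treated as
#'   multi-mapping and dropped from fusion evidence.
#' @param min_unaligned Minimum length (nt) of each arm of a split mapping.
#' @param max_pair_distance Maximum mate separation for a concordant pair
#'   and for linking discordant mates to a breakpoint.
#' @param seed_k Exact-seed length used to locate candidate loci.
#' @param window_pad Extra reference bases around a seeded window handed to
#'   the dynamic-programming extension.
#' @return A list of class `align_config`.
#' @export
align_config <- function(mismatch_cost = 2L, insertion_cost = 3L,
                         deletion_cost = 3L, length_fraction = 0.8,
                         similarity_fraction = 0.8, max_hits = 10L,
                         min_unaligned = 15L, max_pair_distance = 1000L,
                         seed_k = 16L, window_pad = 12L) {
  if (any(c(mismatch_cost, insertion_cost, deletion_cost) <= 0)) {
    stop("alignment costs must be positive", call. = FALSE)
  }
  assert_scalar_number(length_fraction, "length_fraction", 1e-9, 1)
  assert_scalar_number(similarity_fraction, "similarity_fraction", 1e-9, 1)
  if (max_hits < 1L) stop("`max_hits` must be >= 1", call. = FALSE)
  structure(list(mismatch_cost = as.integer(mismatch_cost),
                 insertion_cost = as.integer(insertion_cost),
                 deletion_cost = as.integer(deletion_cost),
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction,
                 max_hits = as.integer(max_hits),
                 min_unaligned = as.integer(min_unaligned),
                 max_pair_distance = as.integer(max_pair_distance),
                 seed_k = as.integer(seed_k),
                 window_pad = as.integer(window_pad)),
            class = "align_config")
}

#' Build a transcript index for alignment
#'
#' Precomputes the spliced transcript of every gene together with its exon
#' boundary table in transcript coordinates.
#'
#' @param reference A `fusion_reference`.
#' @return A list of class `transcript_index` with `seqs` (named character
#'   vector), `bounds` (list of per-gene exon boundary tables) and the
#'   originating `reference`.
#' @export
transcript_index <- function(reference) {
  seqs <- transcriptome(reference)
  bounds <- lapply(names(seqs), function(g) tx_exon_bounds(reference, g))
  names(bounds) <- names(seqs)
  structure(list(seqs = seqs, bounds = bounds, reference = reference),
            class = "transcript_index")
}

align_one_strand <- function(read_seq, index, cfg, strand) {
  r <- if (strand == "+") read_seq else revcomp(read_seq)
  hits <- cpp_align_read(r, unname(index$seqs),
                         cfg$mismatch_cost, cfg$insertion_cost,
                         cfg$deletion_cost, cfg$seed_k, cfg$window_pad)
  if (nrow(hits) == 0L) return(empty_hits())
  data.frame(target = names(index$seqs)[hits$target], strand = strand,
             ref_start = hits$ref_start, ref_end = hits$ref_end,
             score = hits$cost, matches = hits$matches,
             mismatches = hits$mismatches,
             indels = hits$insertions + hits$deletions,
             identity = hits$matches /
               (hits$matches + hits$mismatches + hits$insertions + hits$deletions),
             coverage = (hits$matches + hits$mismatches) / nchar(read_seq),
             stringsAsFactors = FALSE)
}

#' Align one read against the transcript index
#'
#' Both strands are searched. A hit is reported when it covers at least
#' `length_fraction` of the read with identity at least
#' `similarity_fraction`; hits are ordered by cost, ties broken by
#' (target, position), and capped at `max_hits` (the total number found is
#' kept in the `total_hits` attribute so multi-mappers can be excluded from
#' fusion evidence).
#'
#' @param read_seq Nucleotide string.
#' @param index A `transcript_index`.
#' @param cfg An [align_config()].
#' @return Data frame of hits (possibly empty).
#' @export
align_read <- function(read_seq, index, cfg = align_config()) {
  if (!nzchar(read_seq)) stop("read must be non-empty", call. = FALSE)
  hits <- rbind(align_one_strand(read_seq, index, cfg, "+"),
                align_one_strand(read_seq, index, cfg, "-"))
  hits <- hits[hits$coverage >= cfg$length_fraction &
                 hits$identity >= cfg$similarity_fraction, , drop = FALSE]
  hits <- hits[order(hits$score, hits$target, hits$ref_start), , drop = FALSE]
  rownames(hits) <- NULL
  total <- nrow(hits)
  if (total > cfg$max_hits) hits <- hits[seq_len(cfg$max_hits), , drop = FALSE]
  attr(hits, "total_hits") <- total
  hits
}

#' Classify a read pair from its per-mate hits
#'
#' `concordant`: best mates on the same gene in opposite orientations within
#' `max_pair_distance`; `discordant_two_genes`: best mates inside two
#' different genes; `half_mapped`: exactly one mate has hits; `unmapped`:
#' neither does. Same-gene pairs in improper orientation are labelled
#' `other` (they are never fusion evidence).
#'
#' @param mate1_hits,mate2_hits Hit tables from [align_read()].
#' @param index A `transcript_index`.
#' @param max_pair_distance Maximum inner distance for a concordant pair.
#' @return List with `class` and, when both mates map, `gene1`/`gene2` and
#'   the best hit rows.
#' @export
classify_pair <- function(mate1_hits, mate2_hits, index,
                          max_pair_distance = 1000L) {
  n1 <- nrow(mate1_hits); n2 <- nrow(mate2_hits)
  if (n1 == 0L && n2 == 0L) return(list(class = "unmapped"))
  if (n1 == 0L || n2 == 0L) return(list(class = "half_mapped"))
  b1 <- mate1_hits[1, ]; b2 <- mate2_hits[1, ]
  multi <- isTRUE(attr(mate1_hits, "total_hits") > nrow(mate1_hits)) ||
    isTRUE(attr(mate2_hits, "total_hits") > nrow(mate2_hits))
  out <- list(gene1 = b1$target, gene2 = b2$target, hit1 = b1, hit2 = b2,
              multimapped = multi)
  if (b1$target == b2$target) {
    gap <- max(b1$ref_start, b2$ref_start) - min(b1$ref_end, b2$ref_end)
    proper <- b1$strand != b2$strand && gap <= max_pair_distance
    out$class <- if (proper) "concordant" else "other"
  } else {
    out$class <- "discordant_two_genes"
  }
  out
}

nearest_exon_boundary <- function(index, gene, pos, side = c("end", "start")) {
  side <- match.arg(side)
  b <- index$bounds[[gene]]
  vals <- if (side == "end") b$tx_end else b$tx_start
  d <- abs(vals - pos)
  i <- which.min(d)
  list(exon = b$exon_number[i], distance = d[i])
}

#' Split-map a junction-crossing read
#'
#' Searches every split point between `min_unaligned` and
#' `read length - min_unaligned` for a prefix and complementary suffix that
#' align to two different genes, choosing the split with the lowest total
#' alignment cost. Cost ties (which arise whenever the bases flanking the
#' junction coincide between the two genes) are broken by proximity of the
#' breakpoints to annotated exon boundaries, then by the leftmost split,
#' then by forward orientation. Each
#' arm must individually satisfy the length and similarity fractions. The
#' genomic breakpoints are annotated with their distance to the nearest
#' exon boundary.
#'
#' @param read_seq Nucleotide string.
#' @param index A `transcript_index`.
#' @param cfg An [align_config()].
#' @param read_id Optional identifier carried into the result.
#' @return A `split_alignment` (list) or `NULL` when no valid split exists.
#' @export
split_map <- function(read_seq, index, cfg = align_config(), read_id = NA_character_) {
  L <- nchar(read_seq)
  if (L < 2L * cfg$min_unaligned) return(NULL)
  seqs <- unname(index$seqs)
  genes <- names(index$seqs)
  same <- outer(genes, genes, "==")
  cands <- list()
  oriented <- c("+" = read_seq, "-" = revcomp(read_seq))
  for (strand in c("+", "-")) {
    r <- oriented[[strand]]
    prof <- cpp_split_costs(r, seqs, cfg$mismatch_cost, cfg$insertion_cost,
                            cfg$deletion_cost)
    for (s in cfg$min_unaligned:(L - cfg$min_unaligned)) {
      pc <- prof$pref_cost[s + 1L, ]
      sc <- prof$suf_cost[s + 1L, ]
      tot <- outer(pc, sc, "+")
      tot[same] <- NA  # arms must land on two *different genes*
      if (all(is.na(tot))) next
      m <- which(tot == min(tot, na.rm = TRUE), arr.ind = TRUE)
      for (row in seq_len(nrow(m))) {
        tA <- m[row, 1]; tB <- m[row, 2]
        cands[[length(cands) + 1L]] <- data.frame(
          strand = strand, s = s, tA = tA, tB = tB,
          total_cost = tot[tA, tB],
          bp5 = prof$pref_end[s + 1L, tA],
          bp3 = prof$suf_start[s + 1L, tB],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0L) return(NULL)
  cands <- do.call(rbind, cands)
  cands <- cands[cands$total_cost == min(cands$total_cost), , drop = FALSE]
  # cost ties: prefer splits whose breakpoints sit on annotated exon
  # boundaries (the caller's boundary-distance filter semantics), then the
  # leftmost split, then the forward orientation
  cands$bdist <- vapply(seq_len(nrow(cands)), function(i) {
    nearest_exon_boundary(index, genes[cands$tA[i]], cands$bp5[i], "end")$distance +
      nearest_exon_boundary(index, genes[cands$tB[i]], cands$bp3[i], "start")$distance
  }, 0)
  cands <- cands[order(cands$bdist, cands$s, cands$strand), , drop = FALSE]
  best <- list(strand = cands$strand[1], s = cands$s[1],
               tA = cands$tA[1], tB = cands$tB[1],
               total_cost = cands$total_cost[1],
               oriented = oriented[[cands$strand[1]]])
  r <- best$oriented; s <- best$s
  seg <- function(sub, t) {
    a <- cpp_semiglobal(sub, seqs[[t]], cfg$mismatch_cost, cfg$insertion_cost,
                        cfg$deletion_cost)
    cols <- a$matches + a$mismatches + a$insertions + a$deletions
    list(target = genes[t], ref_start = a$ref_start, ref_end = a$ref_end,
         mismatches = a$mismatches, indels = a$insertions + a$deletions,
         score = a$cost,
         identity = a$matches / cols,
         coverage = (a$matches + a$mismatches) / nchar(sub))
  }
  left <- seg(substr(r, 1L, s), best$tA)
  right <- seg(substr(r, s + 1L, L), best$tB)
  ok <- function(a) a$identity >= cfg$similarity_fraction &&
    a$coverage >= cfg$length_fraction
  if (!ok(left) || !ok(right)) return(NULL)
  d5 <- nearest_exon_boundary(index, left$target, left$ref_end, "end")
  d3 <- nearest_exon_boundary(index, right$target, right$ref_start, "start")
  structure(list(read_id = read_id, strand = best$strand,
                 junction_offset_in_read = s, oriented_seq = r,
                 left_segment = left, right_segment = right,
                 gene5 = left$target, gene3 = right$target,
                 bp5 = left$ref_end, bp3 = right$ref_start,
                 dist5 = d5$distance, exon5 = d5$exon,
                 dist3 = d3$distance, exon3 = d3$exon,
                 total_cost = best$total_cost),
            class = "split_alignment")
}

# Batched alignment of many reads: returns the best passing hit per read
# plus per-read hit counts, all computed vectorized over one C++ call.
align_best_batch <- function(read_seqs, index, cfg) {
  hits <- cpp_align_batch(read_seqs, unname(index$seqs),
                          cfg$mismatch_cost, cfg$insertion_cost,
                          cfg$deletion_cost, cfg$seed_k, cfg$window_pad)
  cols <- hits$matches + hits$mismatches + hits$insertions + hits$deletions
  identity <- ifelse(cols > 0, hits$matches / cols, 0)
  coverage <- (hits$matches + hits$mismatches) / nchar(read_seqs)[hits$read]
  hits <- hits[coverage >= cfg$length_fraction &
                 identity >= cfg$similarity_fraction, , drop = FALSE]
  n <- length(read_seqs)
  out <- data.frame(has_hit = rep(FALSE, n), n_hits = 0L,
                    target = NA_character_, strand = NA_character_,
                    ref_start = NA_integer_, ref_end = NA_integer_,
                    cost = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  tname <- names(index$seqs)[hits$target]
  o <- order(hits$read, hits$cost, tname, hits$ref_start)
  hits <- hits[o, , drop = FALSE]
  tname <- tname[o]
  first <- !duplicated(hits$read)
  idx <- hits$read[first]
  out$has_hit[idx] <- TRUE
  counts <- tabulate(hits$read, nbins = n)
  out$n_hits <- counts
  out$target[idx] <- tname[first]
  out$strand[idx] <- hits$strand[first]
  out$ref_start[idx] <- hits$ref_start[first]
  out$ref_end[idx] <- hits$ref_end[first]
  out$cost[idx] <- hits$cost[first]
  out
}

#' Collect per-sample alignment evidence
#'
#' Aligns every mate, classifies pairs, attempts split mapping of mates that
#' failed single-segment alignment, and sets aside still-unplaced reads for
#' the refinement re-count.
#'
#' @param sample Result of [simulate_sample()] (or a data frame of the same
#'   shape under `$reads`).
#' @param index A `transcript_index`.
#' @param cfg An [align_config()].
#' @return List with `pairs` (classification table), `splits` (list of
#'   `split_alignment`), and `unplaced` (data frame of read id + sequence).
#' @export
collect_sample_evidence <- function(sample, index, cfg = align_config()) {
  reads <- sample$reads
  n <- nrow(reads)
  b1 <- align_best_batch(reads$mate1_seq, index, cfg)
  b2 <- align_best_batch(reads$mate2_seq, index, cfg)
  cls <- rep("unmapped", n)
  cls[xor(b1$has_hit, b2$has_hit)] <- "half_mapped"
  both <- b1$has_hit & b2$has_hit
  same <- both & b1$target == b2$target
  gap <- pmax(b1$ref_start, b2$ref_start) - pmin(b1$ref_end, b2$ref_end)
  proper <- same & b1$strand != b2$strand & gap <= cfg$max_pair_distance
  cls[same & proper] <- "concordant"
  cls[same & !proper] <- "other"
  cls[both & !same] <- "discordant_two_genes"
  multi <- b1$n_hits > cfg$max_hits | b2$n_hits > cfg$max_hits
  pairs <- data.frame(pair_id = reads$pair_id, class = cls,
                      gene1 = b1$target, gene2 = b2$target,
                      start1 = b1$ref_start, end1 = b1$ref_end,
                      start2 = b2$ref_start, end2 = b2$ref_end,
                      multimapped = multi, stringsAsFactors = FALSE)
  splits <- list()
  unplaced_id <- character(0); unplaced_seq <- character(0)
  for (i in which(cls %in% c("half_mapped", "unmapped"))) {
    for (mate in 1:2) {
      if ((mate == 1 && b1$has_hit[i]) || (mate == 2 && b2$has_hit[i])) next
      rid <- paste0(reads$pair_id[i], "/", mate)
      seqv <- if (mate == 1) reads$mate1_seq[i] else reads$mate2_seq[i]
      sp <- split_map(seqv, index, cfg, read_id = rid)
      if (!is.null(sp)) {
        splits[[length(splits) + 1L]] <- sp
      } else {
        unplaced_id <- c(unplaced_id, rid)
        unplaced_seq <- c(unplaced_seq, seqv)
      }
    }
  }
  list(pairs = pairs, splits = splits,
       unplaced = data.frame(read_id = unplaced_id, seq = unplaced_seq,
                             stringsAsFactors = FALSE))
}

#' Write alignments as a minimal SAM file
#'
#' Single-end records; split alignments are emitted as two lines with
#' soft-clips, the second flagged supplementary.
#'
#' @param hits Either a hit table from [align_read()] (with a `read` and
#'   `read_id` attribute-free single read) or a list of `split_alignment`.
#' @param index A `transcript_index`.
#' @param path Output path.
#' @param read_seqs Named character vector of read sequences by read id
#'   (required for hit tables).
#' @export
write_sam <- function(hits, index, path, read_seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(index$seqs), nchar(index$seqs)))
  recs <- character(0)
  if (inherits(hits, "data.frame")) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      rid <- rownames(hits)[i]
      seqv <- if (!is.null(read_seqs)) read_seqs[[rid]] %||% "*" else "*"
      flag <- if (h$strand == "-") 16L else 0L
      cig <- sprintf("%dM", h$ref_end - h$ref_start)
      recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                              rid, flag, h$target, h$ref_start + 1L, cig, seqv))
    }
  } else {
    for (sp in hits) {
      L <- nchar(sp$oriented_seq); s <- sp$junction_offset_in_read
      flag0 <- if (sp$strand == "-") 16L else 0L
      recs <- c(recs,
                sprintf("%s\t%d\t%s\t%d\t60\t%dM%dS\t*\t0\t0\t%s\t*",
                        sp$read_id, flag0, sp$gene5,
                        sp$left_segment$ref_start + 1L, s, L - s, sp$oriented_seq),
                sprintf("%s\t%d\t%s\t%d\t60\t%dS%dM\t*\t0\t0\t%s\t*",
                        sp$read_id, flag0 + 2048L, sp$gene3,
                        sp$right_segment$ref_start + 1L, s, L - s, sp$oriented_seq))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
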