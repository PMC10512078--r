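# Synthetic cohort generator: toy references, planted read-through fusions,
# and paired-end read sets with the statistical structure the downstream
# analysis assumes, plus per-pair truth tables.

#' Generate a toy reference (contig + gene models)
#'
#' Builds one contig carrying `n_genes` non-overlapping genes on the `+`
#' strand (the colinear, same-strand geometry required for a read-through
#' fusion between adjacent genes). Exon/intron structure is drawn uniformly
#' from the supplied ranges; all coordinates are 0-based, half-open, and
#' exons are numbered 1..n in transcription order.
#'
#' @param seed Integer seed; the same seed reproduces the reference
#'   byte-for-byte.
#' @param n_genes Number of genes (>= 2, so a read-through pair exists).
#' @param exon_count_range,exon_len_range,intron_len_range Integer pairs
#'   (min, max) for exons per gene, exon length (nt) and intron length (nt).
#' @param intergenic_len_range Integer pair for the gap between consecutive
#'   genes.
#' @return An object of class `fusion_reference`: a list with `genome`
#'   (named character vector of contig sequences) and `genes` (data frame
#'   with `gene_id`, `chrom`, `strand`, `exon_number`, `start`, `end`).
#' @export
generate_reference <- function(seed, n_genes = 4L,
                               exon_count_range = c(2L, 4L),
                               exon_len_range = c(120L, 200L),
                               intron_len_range = c(50L, 100L),
                               intergenic_len_range = c(150L, 300L)) {
  check_range <- function(r, name) {
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a positive (min, max) pair", name),
           call. = FALSE)
    }
  }
  check_range(exon_count_range, "exon_count_range")
  check_range(exon_len_range, "exon_len_range")
  check_range(intron_len_range, "intron_len_range")
  check_range(intergenic_len_range, "intergenic_len_range")
  if (n_genes < 2L) stop("`n_genes` must be >= 2", call. = FALSE)

  with_seed(seed, {
    pos <- sample(intergenic_len_range[1]:intergenic_len_range[2], 1L)
    rows <- list()
    for (g in seq_len(n_genes)) {
      n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1L)
      for (e in seq_len(n_ex)) {
        len <- sample(exon_len_range[1]:exon_len_range[2], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("gene%02d", g), chrom = "chr1", strand = "+",
          exon_number = e, start = pos, end = pos + len,
          stringsAsFactors = FALSE)
        pos <- pos + len
        if (e < n_ex) pos <- pos + sample(intron_len_range[1]:intron_len_range[2], 1L)
      }
      pos <- pos + sample(intergenic_len_range[1]:intergenic_len_range[2], 1L)
    }
    genes <- do.call(rbind, rows)
    contig_len <- max(genes$end) + sample(intergenic_len_range[1]:intergenic_len_range[2], 1L)
    genome <- c(chr1 = random_dna(contig_len))
    structure(list(genome = genome, genes = genes), class = "fusion_reference")
  })
}

#' @export
print.fusion_reference <- function(x, ...) {
  cat(sprintf("fusion_reference: %d contig(s), %d gene(s), %d exon rows\n",
              length(x$genome), length(unique(x$genes$gene_id)), nrow(x$genes)))
  invisible(x)
}

gene_exons <- function(reference, gene_id) {
  ex <- reference$genes[reference$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  ex[order(ex$exon_number), , drop = FALSE]
}

#' Spliced transcript sequence of one gene
#'
#' Concatenates the gene's exons in transcription order (introns removed).
#' All toy genes live on the `+` strand, so the spliced sequence is read
#' directly off the contig.
#'
#' @param reference A `fusion_reference`.
#' @param gene_id Gene identifier.
#' @return Nucleotide string of the spliced transcript.
#' @export
spliced_transcript <- function(reference, gene_id) {
  ex <- gene_exons(reference, gene_id)
  contig <- reference$genome[[ex$chrom[1]]]
  paste(substring(contig, ex$start + 1L, ex$end), collapse = "")
}

#' All spliced transcripts of a reference
#' @param reference A `fusion_reference`.
#' @return Named character vector, one spliced transcript per gene.
#' @export
transcriptome <- function(reference) {
  ids <- unique(reference$genes$gene_id)
  setNames(vapply(ids, function(g) spliced_transcript(reference, g), ""), ids)
}

# Cumulative exon boundaries of a gene in spliced-transcript coordinates:
# data frame with exon_number, tx_start, tx_end (0-based, half-open).
tx_exon_bounds <- function(reference, gene_id) {
  ex <- gene_exons(reference, gene_id)
  lens <- ex$end - ex$start
  ends <- cumsum(lens)
  data.frame(exon_number = ex$exon_number,
             tx_start = ends - lens, tx_end = ends)
}

#' Describe a planted fusion between two genes
#'
#' Only same-strand, 5'-to-3' colinear gene pairs are supported (the
#' read-through / cis-splicing geometry); antisense pairs are rejected.
#'
#' @param five_gene,three_gene Gene ids of the 5' and 3' partners.
#' @param five_last_exon Last retained exon of the 5' gene.
#' @param three_first_exon First retained exon of the 3' gene.
#' @param expression_weight Fraction of a sample's fragments drawn from the
#'   fusion cDNA, in \[0, 1\].
#' @return An object of class `planted_fusion`.
#' @export
planted_fusion <- function(five_gene, five_last_exon, three_gene,
                           three_first_exon, expression_weight = 0.3) {
  if (identical(five_gene, three_gene)) {
    stop("fusion partners must be two different genes", call. = FALSE)
  }
  assert_scalar_number(expression_weight, "expression_weight", 0, 1)
  structure(list(five_gene = five_gene, five_last_exon = as.integer(five_last_exon),
                 three_gene = three_gene, three_first_exon = as.integer(three_first_exon),
                 expression_weight = expression_weight),
            class = "planted_fusion")
}

#' Ground-truth fusion cDNA of a planted fusion
#'
#' Splices exons 1..`five_last_exon` of the 5' gene to exons
#' `three_first_exon`..n of the 3' gene on the coding strand and records the
#' junction offset. This is the truth the detection stages must recover.
#'
#' @param reference A `fusion_reference`.
#' @param fusion A `planted_fusion`.
#' @return An object of class `fusion_transcript` with fields `cdna`,
#'   `segments`, `junction_offset_nt` and `length_nt`.
#' @export
build_fusion_cdna_truth <- function(reference, fusion) {
  ex5 <- gene_exons(reference, fusion$five_gene)
  ex3 <- gene_exons(reference, fusion$three_gene)
  if (ex5$strand[1] != ex3$strand[1]) {
    stop("unsupported orientation: fusion partners must be on the same strand",
         call. = FALSE)
  }
  if (fusion$five_last_exon < 1L || fusion$five_last_exon > max(ex5$exon_number)) {
    stop("`five_last_exon` outside the 5' gene's exon range", call. = FALSE)
  }
  if (fusion$three_first_exon < 1L || fusion$three_first_exon > max(ex3$exon_number)) {
    stop("`three_first_exon` outside the 3' gene's exon range", call. = FALSE)
  }
  splice <- function(ex, keep) {
    contig <- reference$genome[[ex$chrom[1]]]
    ex <- ex[ex$exon_number %in% keep, , drop = FALSE]
    paste(substring(contig, ex$start + 1L, ex$end), collapse = "")
  }
  part5 <- splice(ex5, seq_len(fusion$five_last_exon))
  part3 <- splice(ex3, fusion$three_first_exon:max(ex3$exon_number))
  cdna <- paste0(part5, part3)
  segments <- data.frame(
    gene_id = c(fusion$five_gene, fusion$three_gene),
    exon_from = c(1L, fusion$three_first_exon),
    exon_to = c(fusion$five_last_exon, max(ex3$exon_number)),
    length_nt = c(nchar(part5), nchar(part3)),
    stringsAsFactors = FALSE)
  structure(list(cdna = cdna, segments = segments,
                 junction_offset_nt = nchar(part5), length_nt = nchar(cdna)),
            class = "fusion_transcript")
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat(sprintf("fusion_transcript: %d nt, junction at %d (%s | %s)\n",
              x$length_nt, x$junction_offset_nt,
              x$segments$gene_id[1], x$segments$gene_id[2]))
  invisible(x)
}

#' Sample metadata record
#'
#' @param sample_id Sample label.
#' @param group One of `TNBC`, `HER2+`, `HR+`, `adjacent_normal`,
#'   `cancer_free_control`.
#' @return One-row data frame with `sample_id`, `group`, `is_case`.
#' @export
sample_meta <- function(sample_id, group) {
  groups <- c("TNBC", "HER2+", "HR+", "adjacent_normal", "cancer_free_control")
  group <- match.arg(group, groups)
  data.frame(sample_id = sample_id, group = group,
             is_case = group %in% c("TNBC", "HER2+", "HR+"),
             stringsAsFactors = FALSE)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate one sample's paired-end reads
#'
#' Fragments are drawn from the spliced wild-type transcripts and, with
#' probability equal to each fusion's `expression_weight`, from the fusion
#' cDNA. Fragment lengths follow a truncated normal (resampled until at
#' least `read_len`); mate 2 is reverse-complemented; per-base substitution
#' errors are applied at `error_rate` (the default models the assumed
#' sequencing error rate of 0.001). Each pair carries a truth label:
#' `fusion_junction_crossing` if a mate's footprint straddles the junction,
#' `fusion_spanning` if the mates flank the junction without straddling it,
#' and `wildtype` otherwise (including fusion fragments indistinguishable
#' from wild type).
#'
#' @param reference A `fusion_reference`.
#' @param fusions List of `planted_fusion` objects (possibly empty).
#' @param meta One-row data frame from [sample_meta()].
#' @param n_pairs Number of read pairs (> 0).
#' @param read_len Read length, default 76 nt.
#' @param fragment_mean,fragment_sd Fragment-length distribution (nt).
#' @param error_rate Per-base substitution probability in \[0, 0.5).
#' @param seed Integer seed; output is deterministic per seed.
#' @return List with `reads` (data frame: `pair_id`, `mate1_seq`,
#'   `mate2_seq`, `sample_id`, `truth_origin`, plus provenance columns
#'   `source_transcript`, `frag_start`, `frag_len`) and `meta`.
#' @export
simulate_sample <- function(reference, fusions = list(), meta,
                            n_pairs, read_len = 76L,
                            fragment_mean = 180, fragment_sd = 30,
                            error_rate = 0.001, seed = 1L) {
  if (n_pairs <= 0L) stop("`n_pairs` must be > 0", call. = FALSE)
  assert_scalar_number(error_rate, "error_rate", 0, 0.5 - 1e-12)
  if (fragment_mean <= read_len) {
    stop("`fragment_mean` must exceed `read_len`", call. = FALSE)
  }
  if (inherits(fusions, "planted_fusion")) fusions <- list(fusions)
  txs <- transcriptome(reference)
  if (length(txs) == 0L) stop("reference contains no transcripts", call. = FALSE)
  fus_cdna <- lapply(fusions, function(f) build_fusion_cdna_truth(reference, f))
  w <- vapply(fusions, function(f) f$expression_weight, 0)
  if (sum(w) > 1) stop("fusion expression weights sum to > 1", call. = FALSE)

  with_seed(seed, {
    # source per pair: fusion i w.p. w[i], else a wild-type transcript
    u <- runif(n_pairs)
    src_fusion <- rep(0L, n_pairs)
    if (length(w) > 0L) {
      cw <- cumsum(w)
      for (i in seq_along(w)) {
        src_fusion[u < cw[i] & src_fusion == 0L] <- i
      }
    }
    wt_pick <- sample(seq_along(txs), n_pairs, replace = TRUE)
    seq_src <- ifelse(src_fusion > 0L,
                      vapply(src_fusion, function(i) if (i > 0L) fus_cdna[[i]]$cdna else "", ""),
                      unname(txs[wt_pick]))
    tx_len <- nchar(seq_src)
    # truncated-normal fragment lengths, resampled until >= read_len
    frag <- round(rnorm(n_pairs, fragment_mean, fragment_sd))
    bad <- which(frag < read_len)
    while (length(bad) > 0L) {
      frag[bad] <- round(rnorm(length(bad), fragment_mean, fragment_sd))
      bad <- bad[frag[bad] < read_len]
    }
    frag <- pmin(frag, tx_len)
    start0 <- floor(runif(n_pairs) * (tx_len - frag + 1L))  # 0-based
    m1 <- substring(seq_src, start0 + 1L, start0 + read_len)
    m2 <- substring(seq_src, start0 + frag - read_len + 1L, start0 + frag)
    m2 <- vapply(m2, revcomp, "", USE.NAMES = FALSE)

    origin <- rep("wildtype", n_pairs)
    for (i in which(src_fusion > 0L)) {
      j <- fus_cdna[[src_fusion[i]]]$junction_offset_nt
      m1_iv <- c(start0[i], start0[i] + read_len)
      m2_iv <- c(start0[i] + frag[i] - read_len, start0[i] + frag[i])
      straddle <- function(iv) iv[1] < j && iv[2] > j
      if (straddle(m1_iv) || straddle(m2_iv)) {
        origin[i] <- "fusion_junction_crossing"
      } else if (m1_iv[2] <= j && m2_iv[1] >= j) {
        origin[i] <- "fusion_spanning"
      }
    }
    m1 <- apply_errors(m1, error_rate)
    m2 <- apply_errors(m2, error_rate)
    source_label <- ifelse(src_fusion > 0L, paste0("fusion", src_fusion),
                           names(txs)[wt_pick])
    reads <- data.frame(
      pair_id = sprintf("%s_pair%05d", meta$sample_id, seq_len(n_pairs)),
      mate1_seq = m1, mate2_seq = m2,
      sample_id = meta$sample_id, truth_origin = origin,
      source_transcript = source_label,
      frag_start = start0, frag_len = frag,
      stringsAsFactors = FALSE)
    list(reads = reads, meta = meta)
  })
}

#' Write reference FASTA
#' @param reference A `fusion_reference`.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(reference, path) {
  set <- Biostrings::DNAStringSet(reference$genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write gene annotation as GTF (1-based, inclusive)
#' @param reference A `fusion_reference`.
#' @param path Output GTF path.
#' @export
write_annotation_gtf <- function(reference, path) {
  g <- reference$genes
  lines <- sprintf(
    '%s\tfusionneo\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; exon_number "%d";',
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$exon_number)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated sample as a gzipped FASTQ pair
#'
#' Qualities are constant (the pipeline filters on alignment, not base
#' quality).
#'
#' @param sample Result of [simulate_sample()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz`.
#' @export
write_fastq_pair <- function(sample, prefix) {
  reads <- sample$reads
  for (mate in 1:2) {
    seqs <- if (mate == 1) reads$mate1_seq else reads$mate2_seq
    path <- sprintf("%s_%d.fastq.gz", prefix, mate)
    con <- gzfile(path, "w")
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(paste0("@", reads$pair_id, "/", mate, "\n", seqs, "\n+\n", qual), con)
    close(con)
  }
  invisible(prefix)
}

#' Write the truth table of a simulated sample
#' @param sample Result of [simulate_sample()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(sample, path) {
  write.table(sample$reads[, c("pair_id", "truth_origin", "sample_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default cohort design for the synthetic study
#'
#' Six tumor samples (two per subtype) and two cancer-free controls. Fusion
#' `f1` (gene01 -> gene02) is planted in four cases; fusion `f2`
#' (gene03 -> gene04) is planted in one control and two cases, so that the
#' control-exclusion filter has something to remove.
#'
#' @param n_pairs Read pairs per sample.
#' @param weight Fusion expression weight.
#' @return Data frame with one row per sample and a `fusions` list-column of
#'   fusion labels.
#' @export
cohort_design <- function(n_pairs = 2000L, weight = 0.3) {
  d <- data.frame(
    sample_id = c("case01", "case02", "case03", "case04", "case05", "case06",
                  "ctrl01", "ctrl02"),
    group = c("TNBC", "TNBC", "HER2+", "HER2+", "HR+", "HR+",
              "cancer_free_control", "cancer_free_control"),
    stringsAsFactors = FALSE)
  d$is_case <- d$group %in% c("TNBC", "HER2+", "HR+")
  d$n_pairs <- n_pairs
  d$fusions <- list(c("f1"), c("f1"), c("f1"), c("f1"), c("f2"), c("f2"),
                    c("f2"), character(0))
  d$weight <- weight
  d
}

#' Simulate a whole cohort
#'
#' @param reference A `fusion_reference`.
#' @param design Data frame from [cohort_design()] (or same shape).
#' @param fusion_defs Named list of `planted_fusion` objects keyed by the
#'   labels used in `design$fusions`.
#' @param seed Global seed; per-sample seeds are derived from it.
#' @param ... Passed to [simulate_sample()].
#' @return List with `samples` (named list of simulated samples) and `meta`.
#' @export
simulate_cohort <- function(reference, design, fusion_defs, seed = 1L, ...) {
  samples <- list()
  for (i in seq_len(nrow(design))) {
    meta <- sample_meta(design$sample_id[i], design$group[i])
    labs <- design$fusions[[i]]
    fus <- lapply(labs, function(l) {
      f <- fusion_defs[[l]]
      if (is.null(f)) stop(sprintf("no fusion definition for '%s'", l), call. = FALSE)
      f$expression_weight <- design$weight[i]
      f
    })
    samples[[meta$sample_id]] <- simulate_sample(
      reference, fus, meta, n_pairs = design$n_pairs[i],
      seed = seed + i * 101L, ...)
  }
  meta <- do.call(rbind, lapply(samples, `[[`, "meta"))
  rownames(meta) <- NULL
  list(samples = samples, meta = meta)
}
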