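# Synthetic cohort generator: reference construction, planted fusion truth,
# read simulation and its invariants.

test_that("generate_reference is deterministic and structurally sound", {
  r1 <- generate_reference(7, n_genes = 3)
  r2 <- generate_reference(7, n_genes = 3)
  expect_identical(r1, r2)

  r3 <- generate_reference(3, n_genes = 5)
  contig_len <- nchar(r3$genome[["chr1"]])
  # brute-force interval containment over all exons
  expect_true(all(r3$genes$start >= 0 & r3$genes$end <= contig_len))
  expect_true(all(r3$genes$end > r3$genes$start))
  # exons ordered and non-overlapping within each gene, all same strand
  for (g in unique(r3$genes$gene_id)) {
    ex <- r3$genes[r3$genes$gene_id == g, ]
    ex <- ex[order(ex$exon_number), ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  expect_true(all(r3$genes$strand == "+"))

  expect_error(generate_reference(1, n_genes = 1), "n_genes")
  expect_error(generate_reference(1, exon_len_range = c(200, 100)), "exon_len_range")
})

test_that("fusion cDNA truth equals per-exon concatenation", {
  # toy genes with 3 exons of 10 nt each
  ref <- manual_reference(list(c(10, 10, 10), c(10, 10, 10)), seed = 5)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 0.5)
  tr <- build_fusion_cdna_truth(ref, fus)
  expect_equal(tr$length_nt, 40L)
  expect_equal(tr$junction_offset_nt, 20L)

  # identity case: all exons of both genes
  fus_all <- planted_fusion("gene01", 3, "gene02", 1, 0.5)
  tr_all <- build_fusion_cdna_truth(ref, fus_all)
  expect_equal(tr_all$cdna, paste0(spliced_transcript(ref, "gene01"),
                                   spliced_transcript(ref, "gene02")))

  # random toy pairs vs an independent per-exon concatenation oracle
  for (seed in 1:20) {
    r <- generate_reference(seed, n_genes = 2)
    n5 <- max(r$genes$exon_number[r$genes$gene_id == "gene01"])
    n3 <- max(r$genes$exon_number[r$genes$gene_id == "gene02"])
    b5 <- 1L + (seed %% n5)
    b3 <- 1L + (seed %% n3)
    tr <- build_fusion_cdna_truth(r, planted_fusion("gene01", b5, "gene02", b3, 0.1))
    contig <- r$genome[["chr1"]]
    oracle <- ""
    for (g in list(c("gene01", 1, b5), c("gene02", b3, n3))) {
      ex <- r$genes[r$genes$gene_id == g[1] &
                      r$genes$exon_number >= as.integer(g[2]) &
                      r$genes$exon_number <= as.integer(g[3]), ]
      ex <- ex[order(ex$exon_number), ]
      for (i in seq_len(nrow(ex))) {
        oracle <- paste0(oracle, substr(contig, ex$start[i] + 1, ex$end[i]))
      }
    }
    expect_identical(tr$cdna, oracle)
  }
})

test_that("antisense fusion partners are rejected", {
  ref <- manual_reference(list(c(30, 30), c(30, 30)))
  ref$genes$strand[ref$genes$gene_id == "gene02"] <- "-"
  expect_error(build_fusion_cdna_truth(ref, planted_fusion("gene01", 1, "gene02", 1)),
               "orientation")
})

test_that("simulated reads carry correct truth labels and structure", {
  ref <- generate_reference(2, n_genes = 3)
  meta <- sample_meta("s1", "HR+")
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)

  # weight 0: no fusion-derived pairs
  fus0 <- planted_fusion("gene01", 2, "gene02", 2, 0)
  s0 <- simulate_sample(ref, list(fus0), meta, n_pairs = 200, error_rate = 0, seed = 4)
  expect_true(all(s0$reads$truth_origin == "wildtype"))
  expect_true(all(s0$reads$source_transcript != "fusion1"))

  # error_rate 0, weight 1: junction reads covering >= 6 nt on both sides
  # contain the junction 12-mer verbatim
  s1 <- simulate_sample(ref, list(fus), meta, n_pairs = 500, error_rate = 0, seed = 11)
  truth <- build_fusion_cdna_truth(ref, fus)
  j <- truth$junction_offset_nt
  twelve <- substr(truth$cdna, j - 5, j + 6)
  jc <- s1$reads[s1$reads$truth_origin == "fusion_junction_crossing", ]
  expect_gt(nrow(jc), 0)
  rl <- nchar(jc$mate1_seq[1])
  found <- 0L
  for (i in seq_len(nrow(jc))) {
    m1 <- c(jc$frag_start[i], jc$frag_start[i] + rl)
    m2 <- c(jc$frag_start[i] + jc$frag_len[i] - rl, jc$frag_start[i] + jc$frag_len[i])
    if (m1[1] <= j - 6 && m1[2] >= j + 6) {
      expect_true(grepl(twelve, jc$mate1_seq[i], fixed = TRUE))
      found <- found + 1L
    }
    if (m2[1] <= j - 6 && m2[2] >= j + 6) {
      mate2_fwd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(jc$mate2_seq[i])))
      expect_true(grepl(twelve, mate2_fwd, fixed = TRUE))
      found <- found + 1L
    }
  }
  expect_gt(found, 0)

  # weight 0.5: fusion-derived fraction within 3 binomial SDs of 0.5
  fus5 <- planted_fusion("gene01", 2, "gene02", 2, 0.5)
  s5 <- simulate_sample(ref, list(fus5), meta, n_pairs = 2000, error_rate = 0, seed = 8)
  frac <- mean(s5$reads$source_transcript == "fusion1")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("simulation is deterministic and conserves pairs", {
  ref <- generate_reference(2, n_genes = 3)
  meta <- sample_meta("s1", "TNBC")
  fus <- planted_fusion("gene01", 2, "gene02", 2, 0.3)
  a <- simulate_sample(ref, list(fus), meta, n_pairs = 150, seed = 21)
  b <- simulate_sample(ref, list(fus), meta, n_pairs = 150, seed = 21)
  expect_identical(a, b)
  expect_equal(nrow(a$reads), 150L)
  expect_true(all(a$reads$truth_origin %in%
                    c("wildtype", "fusion_spanning", "fusion_junction_crossing")))

  # error_rate 0: every read is an exact substring of a truth transcript
  # (or its reverse complement)
  s <- simulate_sample(ref, list(fus), meta, n_pairs = 100, error_rate = 0, seed = 3)
  truths <- c(unname(transcriptome(ref)), build_fusion_cdna_truth(ref, fus)$cdna)
  all_reads <- c(s$reads$mate1_seq,
                 vapply(s$reads$mate2_seq, function(x)
                   as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))), ""))
  for (rd in all_reads) {
    expect_true(any(vapply(truths, function(t) grepl(rd, t, fixed = TRUE), TRUE)))
  }
})

test_that("reference, annotation and FASTQ writers round-trip", {
  ref <- generate_reference(5, n_genes = 2)
  meta <- sample_meta("s1", "HER2+")
  smp <- simulate_sample(ref, list(), meta, n_pairs = 20, seed = 2)
  d <- withr::local_tempdir()
  write_reference_fasta(ref, file.path(d, "ref.fa"))
  fa <- Biostrings::readDNAStringSet(file.path(d, "ref.fa"))
  expect_identical(as.character(fa[["chr1"]]), unname(ref$genome["chr1"]))

  write_annotation_gtf(ref, file.path(d, "ann.gtf"))
  gtf <- read.delim(file.path(d, "ann.gtf"), header = FALSE)
  expect_equal(nrow(gtf), nrow(ref$genes))
  expect_equal(gtf$V4, ref$genes$start + 1L)  # GTF is 1-based inclusive
  expect_equal(gtf$V5, ref$genes$end)

  write_fastq_pair(smp, file.path(d, "s1"))
  fq1 <- Biostrings::readDNAStringSet(file.path(d, "s1_1.fastq.gz"), format = "fastq")
  expect_equal(length(fq1), 20L)
  expect_identical(unname(as.character(fq1)), smp$reads$mate1_seq)
  write_truth_table(smp, file.path(d, "truth.tsv"))
  tt <- read.delim(file.path(d, "truth.tsv"))
  expect_equal(nrow(tt), 20L)
})
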