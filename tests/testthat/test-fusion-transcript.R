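# Consensus junction, exon-boundary mapping, fusion cDNA assembly, and
# in-silico PCR.

junction_splits <- function(ref, idx, fus, n_reads = 10, error_rate = 0,
                            seed = 5, arm_min = 20) {
  truth <- build_fusion_cdna_truth(ref, fus)
  j <- truth$junction_offset_nt
  set.seed(seed)
  splits <- list()
  for (i in seq_len(n_reads)) {
    left <- sample(arm_min:55, 1)
    read <- substr(truth$cdna, j - left + 1, j - left + 76)
    if (error_rate > 0) {
      n_err <- rbinom(1, 76, error_rate)
      if (n_err > 0) {
        for (p in sample(76, n_err)) {
          substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(read, p, p)), 1)
        }
      }
    }
    sp <- split_map(read, idx, read_id = sprintf("r%03d", i))
    if (!is.null(sp)) splits[[length(splits) + 1L]] <- sp
  }
  list(splits = splits, truth = truth)
}

test_that("consensus junction reproduces the planted sequence and motifs", {
  ref <- generate_reference(51, n_genes = 3)
  idx <- transcript_index(ref)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)
  js <- junction_splits(ref, idx, fus, n_reads = 10)
  expect_gte(length(js$splits), 5)
  jn <- build_consensus_junction(js$splits)
  j <- js$truth$junction_offset_nt
  # the consensus window must equal the corresponding slice of the truth cDNA
  width5 <- jn$junction_offset
  width3 <- nchar(jn$consensus_seq) - jn$junction_offset
  expect_identical(jn$consensus_seq,
                   substr(js$truth$cdna, j - width5 + 1, j + width3))
  expect_identical(jn$five_motif, substr(js$truth$cdna, j - 5, j))
  expect_identical(jn$three_motif, substr(js$truth$cdna, j + 1, j + 6))
  expect_equal(jn$n_supporting_reads, length(js$splits))
  # motif invariant
  expect_identical(jn$five_motif,
                   substr(jn$consensus_seq, jn$junction_offset - 5, jn$junction_offset))
  expect_identical(jn$three_motif,
                   substr(jn$consensus_seq, jn$junction_offset + 1, jn$junction_offset + 6))
})

test_that("a single split read is its own consensus", {
  ref <- generate_reference(52, n_genes = 3)
  idx <- transcript_index(ref)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)
  js <- junction_splits(ref, idx, fus, n_reads = 1)
  jn <- build_consensus_junction(js$splits)
  expect_identical(jn$consensus_seq, js$splits[[1]]$oriented_seq)
})

test_that("noisy reads still vote out to the true consensus where coverage is deep", {
  ref <- generate_reference(53, n_genes = 3)
  idx <- transcript_index(ref)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)
  for (seed in c(1, 2, 3)) {
    js <- junction_splits(ref, idx, fus, n_reads = 20, error_rate = 0.001,
                          seed = seed)
    jn <- build_consensus_junction(js$splits)
    j <- js$truth$junction_offset_nt
    # compare only the deeply covered center (+/- 20 nt, coverage >= 10 there)
    expect_identical(substr(jn$consensus_seq, jn$junction_offset - 19,
                            jn$junction_offset + 20),
                     substr(js$truth$cdna, j - 19, j + 20))
  }
})

test_that("reads from different breakpoints raise a cluster conflict", {
  ref <- generate_reference(54, n_genes = 4)
  idx <- transcript_index(ref)
  js1 <- junction_splits(ref, idx, planted_fusion("gene01", 2, "gene02", 2, 1))
  js2 <- junction_splits(ref, idx, planted_fusion("gene01", 1, "gene02", 2, 1))
  expect_error(build_consensus_junction(c(js1$splits, js2$splits)), "conflict")
  expect_error(build_consensus_junction(list()), "split read")
})

test_that("exon boundaries map with distances and tolerance", {
  ref <- generate_reference(55, n_genes = 3)
  idx <- transcript_index(ref)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)
  js <- junction_splits(ref, idx, fus)
  jn <- build_consensus_junction(js$splits)
  jn <- map_exon_boundaries(jn, idx)
  expect_equal(jn$five_boundary$exon, 2L)
  expect_equal(jn$three_boundary$exon, 2L)
  expect_equal(jn$five_boundary$distance, 0L)
  expect_true(jn$five_boundary$exact)

  # breakpoint shifted 3 nt inside the exon: still assigned, distance 3
  jn3 <- jn; jn3$bp5 <- jn$bp5 - 3L
  jn3 <- map_exon_boundaries(jn3, idx)
  expect_equal(jn3$five_boundary$distance, 3L)
  expect_equal(jn3$five_boundary$exon, 2L)

  # 11 nt from any boundary: beyond the tolerance
  b <- idx$bounds[["gene01"]]
  off_bp <- b$tx_end[b$exon_number == 1] + 11L
  stopifnot(min(abs(c(b$tx_end, b$tx_start) - off_bp)) == 11L)
  jn11 <- jn; jn11$bp5 <- off_bp
  expect_error(map_exon_boundaries(jn11, idx), "unannotated")
})

test_that("assembled fusion cDNA matches constructed lengths and the truth builder", {
  # gene A exons 100 + 120, gene B exons 80 + 90, boundaries exon 2 | exon 2
  ref <- manual_reference(list(c(100, 120), c(80, 90)), seed = 3)
  tr <- assemble_fusion_cdna(ref, list(gene = "gene01", exon = 2),
                             list(gene = "gene02", exon = 2))
  expect_equal(tr$length_nt, 100L + 120L + 90L)
  expect_equal(tr$junction_offset_nt, 220L)

  # full genes: plain concatenation of the spliced transcripts
  tr_full <- assemble_fusion_cdna(ref, list(gene = "gene01", exon = 2),
                                  list(gene = "gene02", exon = 1))
  expect_identical(tr_full$cdna, paste0(spliced_transcript(ref, "gene01"),
                                        spliced_transcript(ref, "gene02")))

  # equality with the simulation truth across random fusions
  for (seed in c(61, 62, 63)) {
    r <- generate_reference(seed, n_genes = 2)
    n5 <- max(r$genes$exon_number[r$genes$gene_id == "gene01"])
    fus <- planted_fusion("gene01", n5, "gene02", 2, 0.5)
    truth <- build_fusion_cdna_truth(r, fus)
    asm <- assemble_fusion_cdna(r, list(gene = "gene01", exon = n5),
                                list(gene = "gene02", exon = 2))
    expect_identical(asm$cdna, truth$cdna)
    expect_equal(asm$junction_offset_nt, truth$junction_offset_nt)
  }
})

test_that("in-silico PCR reports outer-to-outer product sizes", {
  set.seed(77)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  fwd <- "GATTACAGATTACAGATTACA"   # 21 nt
  rev <- "CTGCTAGACCTGCTAGACC"     # 19 nt
  rev_site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  mid <- rnd(100 - nchar(fwd) - nchar(rev_site))  # outer span 100
  left <- rnd(40); right <- rnd(40)
  tmpl <- paste0(left, fwd, mid, rev_site, right)
  expect_equal(in_silico_pcr(tmpl, fwd, rev), 100L)

  # invariant to flanking sequence content
  tmpl2 <- paste0(rnd(40), fwd, mid, rev_site, rnd(40))
  expect_equal(in_silico_pcr(tmpl2, fwd, rev), 100L)

  # missing reverse primer site: no product; wrong orientation: no product
  expect_equal(length(in_silico_pcr(paste0(left, fwd, mid, right), fwd, rev)), 0L)
  flipped <- paste0(left, rev_site, mid, fwd, right)
  expect_equal(length(in_silico_pcr(flipped, fwd, rev)), 0L)
  expect_error(in_silico_pcr(tmpl, "ACGTACGT", rev), "15 nt")
})
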