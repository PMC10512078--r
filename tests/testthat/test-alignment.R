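# Read alignment: cost-model semantics, the exhaustive-DP oracle
# equivalence, pair classification, and split mapping.

make_index <- function(seed = 10, n_genes = 3) {
  transcript_index(generate_reference(seed, n_genes = n_genes))
}

test_that("exact and near-exact reads align with the expected costs", {
  idx <- make_index()
  tx <- idx$seqs[[1]]
  read <- substr(tx, 31, 106)  # a 76-mer
  hits <- align_read(read, idx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches[1], 0L)
  expect_equal(hits$score[1], 0L)
  expect_equal(hits$coverage[1], 1)
  expect_equal(hits$ref_start[1], 30L)

  # one substitution: mismatches = 1, score = mismatch cost = 2
  sub <- read
  ch <- substr(sub, 40, 40)
  substr(sub, 40, 40) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  hits2 <- align_read(sub, idx)
  expect_equal(hits2$mismatches[1], 1L)
  expect_equal(hits2$score[1], 2L)

  # reverse-complement reads are found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits3 <- align_read(rc, idx)
  expect_equal(hits3$strand[1], "-")
  expect_equal(hits3$ref_start[1], 30L)
})

test_that("best alignment cost matches the exhaustive DP oracle", {
  idx <- make_index(seed = 14, n_genes = 2)
  seqs <- unname(idx$seqs)
  set.seed(42)
  for (i in 1:50) {
    tx <- sample(seqs, 1)
    start <- sample(nchar(tx) - 76, 1)
    read <- substr(tx, start, start + 75)
    # plant 0-3 substitutions
    n_mut <- sample(0:3, 1)
    if (n_mut > 0) {
      pos <- sample(76, n_mut)
      for (p in pos) {
        substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(read, p, p)), 1)
      }
    }
    if (i %% 2 == 0) {
      read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    }
    hits <- align_read(read, idx)
    expect_gt(nrow(hits), 0)
    expect_equal(hits$score[1], oracle_best_cost(read, seqs))
  }
})

test_that("pair classification distinguishes concordant, discordant and half-mapped", {
  ref <- generate_reference(20, n_genes = 3)
  idx <- transcript_index(ref)
  tx1 <- idx$seqs[["gene01"]]

  # both mates from the same wild-type transcript, proper orientation
  frag <- substr(tx1, 11, 190)
  m1 <- substr(frag, 1, 76)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(frag, nchar(frag) - 75, nchar(frag)))))
  h1 <- align_read(m1, idx); h2 <- align_read(m2, idx)
  expect_equal(classify_pair(h1, h2, idx)$class, "concordant")

  # mates in two different genes (planted fusion fragment geometry)
  m2b <- substr(idx$seqs[["gene02"]], 21, 96)
  h2b <- align_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(m2b))), idx)
  expect_equal(classify_pair(h1, h2b, idx)$class, "discordant_two_genes")

  # scrambled mate 2
  set.seed(1)
  garbage <- paste(sample(c("A", "C", "G", "T"), 76, TRUE), collapse = "")
  h2c <- align_read(garbage, idx)
  expect_equal(nrow(h2c), 0L)
  expect_equal(classify_pair(h1, h2c, idx)$class, "half_mapped")
  expect_equal(classify_pair(h2c, h2c, idx)$class, "unmapped")
})

test_that("split mapping recovers the true junction and respects min_unaligned", {
  ref <- generate_reference(30, n_genes = 3)
  idx <- transcript_index(ref)
  fus <- planted_fusion("gene01", 2, "gene02", 2, 1)
  truth <- build_fusion_cdna_truth(ref, fus)
  j <- truth$junction_offset_nt
  cfg <- align_config()

  # error-free junction read, 40 nt on the 5' side and 36 on the 3' side
  read <- substr(truth$cdna, j - 39, j + 36)
  sp <- split_map(read, idx, cfg)
  expect_false(is.null(sp))
  expect_equal(sp$junction_offset_in_read, 40L)
  expect_equal(sp$gene5, "gene01")
  expect_equal(sp$gene3, "gene02")
  expect_equal(sp$dist5, 0L)
  expect_equal(sp$dist3, 0L)
  # split consistency: the two arms tile the read exactly
  expect_equal(sp$junction_offset_in_read + (nchar(read) - sp$junction_offset_in_read),
               nchar(read))
  expect_true(sp$junction_offset_in_read >= cfg$min_unaligned)
  expect_true(nchar(read) - sp$junction_offset_in_read >= cfg$min_unaligned)

  # the same read given as mate 2 (reverse complement) splits identically
  sp_rc <- split_map(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read))), idx, cfg)
  expect_equal(sp_rc$strand, "-")
  expect_equal(sp_rc$gene5, "gene01")
  expect_equal(sp_rc$bp5, sp$bp5)

  # read fully inside one exon: no split
  inside <- substr(idx$seqs[["gene01"]], 5, 80)
  expect_null(split_map(inside, idx, cfg))

  # only 8 nt past the junction, below the minimum unaligned length: no split
  short <- substr(truth$cdna, j - 67, j + 8)
  expect_null(split_map(short, idx, cfg))
})

test_that("reads hitting many targets are flagged as multi-mapping", {
  # a fake index whose transcripts all share one segment
  seg <- paste(rep(c("A", "C", "G", "T"), 30), collapse = "")
  seqs <- setNames(vapply(1:12, function(i) {
    set.seed(i + 100)
    paste0(paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), seg)
  }, ""), sprintf("g%02d", 1:12))
  bounds <- lapply(seqs, function(s) data.frame(exon_number = 1L, tx_start = 0L,
                                                tx_end = nchar(s)))
  idx <- structure(list(seqs = seqs, bounds = bounds), class = "transcript_index")
  read <- substr(seg, 1, 76)
  hits <- align_read(read, idx)
  expect_equal(nrow(hits), 10L)  # capped at max_hits
  expect_gt(attr(hits, "total_hits"), 10L)
})
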