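# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations (quadratic DP, full enumeration, brute
# force window scans) kept separate from the package's own code paths.

# Exhaustive semi-global edit-cost oracle: best cost of aligning `read` in
# full against any substring of `ref` under (mismatch, insertion, deletion)
# costs. Quadratic DP, no seeding, no windows.
oracle_semiglobal_cost <- function(read, ref, mm = 2, ins = 3, del = 3) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  L <- length(r); n <- length(s)
  prev <- rep(0L, n + 1L)
  for (i in seq_len(L)) {
    cur <- integer(n + 1L)
    cur[1] <- prev[1] + ins
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + if (r[i] == s[j]) 0L else mm,
                        prev[j + 1] + ins,
                        cur[j] + del)
    }
    prev <- cur
  }
  min(prev)
}

# Best alignment cost of a read against a transcript set, both orientations.
oracle_best_cost <- function(read, seqs, mm = 2, ins = 3, del = 3) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  min(vapply(seqs, function(s) {
    min(oracle_semiglobal_cost(read, s, mm, ins, del),
        oracle_semiglobal_cost(rc, s, mm, ins, del))
  }, 0))
}

# Full-enumeration Mann-Whitney oracle: exact two-sided p over all
# choose(n1 + n2, n1) group assignments (assumes no ties).
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force count of distinct k-windows of `context` overlapping the
# terminal novel run (mask given explicitly).
oracle_window_count <- function(context, mask, k) {
  L <- nchar(context)
  if (L < k) return(0L)
  seqs <- character(0)
  for (i in seq_len(L - k + 1L)) {
    if (any(mask[i:(i + k - 1L)])) {
      seqs <- c(seqs, substr(context, i, i + k - 1L))
    }
  }
  length(unique(seqs))
}

# Hand-built reference with exact exon lengths: gene ids gene01..geneNN on
# one contig, '+' strand, fixed intron/gap lengths, random exon sequence.
manual_reference <- function(exon_lens_per_gene, intron_len = 20L,
                             gap_len = 100L, seed = 99L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  pos <- gap_len
  contig <- strrep("N", 0)
  contig <- rnd(gap_len)
  rows <- list()
  for (g in seq_along(exon_lens_per_gene)) {
    lens <- exon_lens_per_gene[[g]]
    for (e in seq_along(lens)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("gene%02d", g), chrom = "chr1", strand = "+",
        exon_number = e, start = pos, end = pos + lens[e],
        stringsAsFactors = FALSE)
      contig <- paste0(contig, rnd(lens[e]))
      pos <- pos + lens[e]
      if (e < length(lens)) {
        contig <- paste0(contig, rnd(intron_len))
        pos <- pos + intron_len
      }
    }
    contig <- paste0(contig, rnd(gap_len))
    pos <- pos + gap_len
  }
  structure(list(genome = c(chr1 = contig), genes = do.call(rbind, rows)),
            class = "fusion_reference")
}

# Published junction-region fixtures: the two truncation contexts with
# their fusion-derived terminal runs.
region_5p <- function() neopeptide_region("FLASLENDIKPKFPRKLYFLH", 10L, "five_truncation")
region_3p <- function() neopeptide_region("MISNQNFQGNYISYID", 5L, "three_truncation")

peptides_5p_published <- c("LENDIKPK", "ENDIKPKF", "NDIKPKFP", "DIKPKFPR",
                           "IKPKFPRK", "KPKFPRKL", "PKFPRKLY", "KFPRKLYF",
                           "FPRKLYFL", "PRKLYFLH")
peptides_3p_published <- c("MISNQNFQ", "ISNQNFQG", "SNQNFQGN", "NQNFQGNY",
                           "QNFQGNYI")

binding_fixture <- function() nsfp1_lrrc37a2_binding_table()

# Small ELISpot plate builder: plate_from(NC = c(...), CMV = c(...), ...).
plate_from <- function(...) {
  conds <- list(...)
  df <- do.call(rbind, lapply(names(conds), function(nm) {
    data.frame(condition = nm, sfu = conds[[nm]], stringsAsFactors = FALSE)
  }))
  elispot_plate(df)
}
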