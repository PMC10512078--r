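# ORF discovery on the fusion cDNA, delineation of the fusion-derived
# (novel) residues of each truncation product, and enumeration of
# junction-overlapping k-mer neopeptides.

#' Find open reading frames
#'
#' All ATG-to-stop ORFs of at least `min_len_aa` amino acids in the three
#' forward frames (the fusion cDNA orientation is known; set
#' `reverse = TRUE` to scan the reverse complement too), translated with
#' the standard genetic code and sorted by length, longest first.
#'
#' @param cdna Nucleotide string (or `fusion_transcript`).
#' @param min_len_aa Minimum protein length (stop excluded).
#' @param reverse Also scan the three reverse frames?
#' @return Data frame: `frame`, `strand`, `nt_start`, `nt_end` (0-based,
#'   half-open, stop codon included), `protein`, `length_aa`.
#' @export
find_orfs <- function(cdna, min_len_aa = 100L, reverse = FALSE) {
  if (inherits(cdna, "fusion_transcript")) cdna <- cdna$cdna
  scan_strand <- function(seqx, strand) {
    n <- nchar(seqx)
    rows <- list()
    for (f in 0:2) {
      n_cod <- (n - f) %/% 3L
      if (n_cod < 2L) next
      sub <- substr(seqx, f + 1L, f + 3L * n_cod)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), no.init.codon = TRUE))
      aa <- strsplit(prot, "")[[1]]
      stops <- which(aa == "*")
      starts <- which(aa == "M")
      prev_stop <- 0L
      for (st in stops) {
        ms <- starts[starts > prev_stop & starts < st]
        for (m in ms) {
          len_aa <- st - m
          if (len_aa >= min_len_aa) {
            rows[[length(rows) + 1L]] <- data.frame(
              frame = f, strand = strand,
              nt_start = f + (m - 1L) * 3L, nt_end = f + st * 3L,
              protein = substr(prot, m, st - 1L), length_aa = len_aa,
              stringsAsFactors = FALSE)
          }
        }
        prev_stop <- st
      }
    }
    rows
  }
  rows <- scan_strand(cdna, "+")
  if (reverse) rows <- c(rows, scan_strand(revcomp(cdna), "-"))
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(), strand = character(),
                      nt_start = integer(), nt_end = integer(),
                      protein = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length_aa, out$nt_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(substr(a, 1L, n), "")[[1]]
  cb <- strsplit(substr(b, 1L, n), "")[[1]]
  d <- which(ca != cb)
  if (length(d) == 0L) n else d[1] - 1L
}

longest_common_suffix <- function(a, b) {
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  longest_common_prefix(rev_str(a), rev_str(b))
}

#' Construct a neopeptide region directly
#'
#' Used when the junction-proximal context and its fusion-derived residues
#' are already known (for example from a published region string).
#'
#' @param context Amino-acid string around the junction.
#' @param novel Either a logical mask the length of `context` or an integer
#'   count of novel residues at the relevant terminus.
#' @param source `"five_truncation"` (novel run C-terminal) or
#'   `"three_truncation"` (novel run N-terminal).
#' @return An object of class `neopeptide_region`.
#' @export
neopeptide_region <- function(context, novel,
                              source = c("five_truncation", "three_truncation")) {
  source <- match.arg(source)
  L <- nchar(context)
  if (is.numeric(novel)) {
    u <- as.integer(novel)
    mask <- if (source == "five_truncation") {
      c(rep(FALSE, L - u), rep(TRUE, u))
    } else {
      c(rep(TRUE, u), rep(FALSE, L - u))
    }
  } else {
    mask <- as.logical(novel)
  }
  if (length(mask) != L) stop("mask length must equal context length", call. = FALSE)
  if (!any(mask)) stop("region must contain at least one novel residue", call. = FALSE)
  run <- range(which(mask))
  if (!all(mask[run[1]:run[2]])) stop("novel residues must be contiguous", call. = FALSE)
  if (source == "five_truncation" && run[2] != L) {
    stop("novel run must be C-terminal for a 5' truncation", call. = FALSE)
  }
  if (source == "three_truncation" && run[1] != 1L) {
    stop("novel run must be N-terminal for a 3' truncation", call. = FALSE)
  }
  junction_aa_index <- if (source == "five_truncation") run[1] else run[2]
  structure(list(context = context, novel_mask = mask, source = source,
                 junction_aa_index = junction_aa_index),
            class = "neopeptide_region")
}

#' @export
print.neopeptide_region <- function(x, ...) {
  marks <- ifelse(x$novel_mask, "^", " ")
  cat(x$context, "\n", paste(marks, collapse = ""), "\n", sep = "")
  cat(sprintf("%s: %d novel residues\n", x$source, sum(x$novel_mask)))
  invisible(x)
}

#' Delineate the novel residues of a fusion truncation ORF
#'
#' Classifies the fusion ORF as a 5' truncation (shares an N-terminal prefix
#' with the 5' wild-type protein; novel run at the C-terminus) or a 3'
#' truncation (shares a C-terminal suffix with the 3' wild-type protein;
#' novel run at the N-terminus), computing the novel run from sequence
#' comparison rather than trusting annotation. The context is the novel run
#' plus `k - 1` flanking wild-type residues, so every k-mer overlapping a
#' novel residue fits inside it.
#'
#' @param fusion_orf Protein string of the fusion ORF (or a row of
#'   [find_orfs()] output).
#' @param wildtype_5p_protein,wildtype_3p_protein Wild-type translations at
#'   the matching termini.
#' @param k Peptide length the region should support.
#' @return A `neopeptide_region`.
#' @export
delineate_novel_region <- function(fusion_orf, wildtype_5p_protein,
                                   wildtype_3p_protein, k = 8L) {
  p <- if (is.data.frame(fusion_orf)) fusion_orf$protein[1] else fusion_orf
  n <- nchar(p)
  l5 <- longest_common_prefix(p, wildtype_5p_protein %||% "")
  l3 <- longest_common_suffix(p, wildtype_3p_protein %||% "")
  if (l5 == 0L && l3 == 0L) {
    stop("fusion ORF matches neither wild-type protein (classification error)",
         call. = FALSE)
  }
  if (max(l5, l3) >= n) {
    stop("fusion ORF is identical to a wild-type protein: no novel residues",
         call. = FALSE)
  }
  if (l5 >= l3) {
    u <- n - l5
    flank <- min(k - 1L, l5)
    context <- substr(p, l5 - flank + 1L, n)
    neopeptide_region(context, u, "five_truncation")
  } else {
    u <- n - l3
    flank <- min(k - 1L, l3)
    context <- substr(p, 1L, u + flank)
    neopeptide_region(context, u, "three_truncation")
  }
}

#' Enumerate junction-overlapping k-mer neopeptides
#'
#' All distinct k-mers of the region context whose window covers at least
#' one novel (fusion-derived) position, ordered by start; duplicate
#' sequences are collapsed keeping the first occurrence.
#'
#' @param region A `neopeptide_region`.
#' @param k Peptide length (default 8; 8-11 are the usual MHC class I
#'   ligand lengths).
#' @return Data frame: `seq`, `k`, `start_in_region`, `source`,
#'   `novel_overlap`.
#' @export
enumerate_neopeptides <- function(region, k = 8L) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  L <- nchar(region$context)
  empty <- data.frame(seq = character(), k = integer(),
                      start_in_region = integer(), source = character(),
                      novel_overlap = integer(), stringsAsFactors = FALSE)
  if (L < k) return(empty)
  starts <- seq_len(L - k + 1L)
  overlap <- vapply(starts, function(i) sum(region$novel_mask[i:(i + k - 1L)]), 0L)
  starts <- starts[overlap > 0L]
  if (length(starts) == 0L) return(empty)
  seqs <- substring(region$context, starts, starts + k - 1L)
  keep <- !duplicated(seqs)
  data.frame(seq = seqs[keep], k = k, start_in_region = starts[keep],
             source = region$source,
             novel_overlap = overlap[overlap > 0L][keep],
             stringsAsFactors = FALSE)
}
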