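# Synthetic stand-in for the NSFP1-LRRC37A2 fusion cDNA. The real 3833 nt
# transcript is distributed as supplementary material of the originating
# study and is not bundled here; this generator builds an artificial
# sequence that reproduces its printed, measurable features so the
# transcript-level operations can be exercised end to end:
#   * total length 3833 nt;
#   * two major open reading frames of 835 aa and 500 aa (the only ORFs of
#     >= 100 aa), the 500 aa product ending ...FLASLENDIKPKFPRKLYFLH and
#     the 835 aa product starting MISNQNFQGNYISYID;
#   * junction hexamers AAACCA | AAATTC at the breakpoint (the AAATTC
#     doubling as the codons of the novel K-F dipeptide);
#   * the published validation primer pair amplifying a 121 bp product
#     across the junction.
# Everything else (UTRs, filler codons) is synthetic scaffolding; the two
# ORFs overlap in different frames, as they must on any 3833 nt template.

cycle_fill <- function(n, unit) {
  chars <- strsplit(unit, "")[[1]]
  paste(chars[(seq_len(n) - 1L) %% length(chars) + 1L], collapse = "")
}

#' Synthetic fusion cDNA with the published summary features planted
#'
#' Deterministic (no randomness). See the source file header for exactly
#' which features are reproduced; this is a synthetic emulation for testing
#' transcript-level operations, not the real fusion transcript.
#'
#' @return List with `cdna` (3833 nt string), `junction_offset` (0-based
#'   index of the first 3'-gene base), `forward_primer`, `reverse_primer`.
#' @export
synthetic_sm1_cdna <- function() {
  utr5 <- cycle_fill(60L, "TCCTTC")
  orf1_start <- "ATG"
  filler1 <- strrep("GCC", 407L)
  bridge <- "G"  # completes a GAT codon with the AT of the next ATG
  orf2_head <- "ATGATCTCCAACCAGAACTTCCAGGGCAACTACATCTCCTACATCGAC"  # MISNQNFQGNYISYID
  dual1 <- cycle_fill(142L, "GCC")
  fwd_primer <- "GCCTGCAAGTGACGAGAG"
  dual2 <- "CCGC"  # continues the GCC phase across the primer insert
  orf1_tail <- "TTCCTGGCCTCCCTGGAAAACGACATCAAACCAAAATTCCCAAGAAAACTGTACTTCCTGCACTAA"
  gap1 <- cycle_fill(13L, "GCC")
  rev_site <- "GAAAGCATACAGTTGGACCG"  # reverse complement of the reverse primer
  filler2 <- cycle_fill(2194L, "GCC")
  orf2_stop <- "TAA"
  utr3 <- cycle_fill(40L, "TCCTTC")
  cdna <- paste0(utr5, orf1_start, filler1, bridge, orf2_head, dual1,
                 fwd_primer, dual2, orf1_tail, gap1, rev_site, filler2,
                 orf2_stop, utr3)
  stopifnot(nchar(cdna) == 3833L)
  junction <- 1530L
  stopifnot(substr(cdna, junction - 5L, junction) == "AAACCA",
            substr(cdna, junction + 1L, junction + 6L) == "AAATTC")
  list(cdna = cdna, junction_offset = junction,
       forward_primer = "GCCTGCAAGTGACGAGAG",
       reverse_primer = "CGGTCCAACTGTATGCTTTC")
}
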