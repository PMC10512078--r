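---
title: "Fusion neoantigen discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion neoantigen discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionneo)
```

## The problem

Chimeric RNAs — transcripts joining exons of two distinct genes through
rearrangement, read-through transcription, or trans-splicing — create amino
acid sequence that exists in no wild-type protein. At the fusion junction,
a truncated 5'-gene product acquires a novel C-terminal run (the reading
frame continues into the 3' gene), and a truncated 3'-gene product acquires
a novel N-terminal run. Short peptides tiled over these novel residues are
candidate tumor neoantigens: if an MHC class I allele presents one of them,
CD8+ T cells can recognize the tumor cell. Because some fusions recur across
patients, such peptides are candidates for "off the shelf" (non-personalized)
tumor vaccines. The motivating application is breast cancer, where the low
somatic mutation burden limits SNV/indel-derived neoantigens, and where a
recurrent read-through fusion between the NSFP1 pseudogene and its immediate
3' neighbor LRRC37A2 yields 15 junction 8-mers, one of which (ENDIKPKF)
elicited a T-cell response in vitro.

`fusionneo` implements the full computational path of that analysis as a
reusable, tested pipeline: cohort simulation, read alignment under an
explicit cost model, fusion calling from split reads plus discordant pairs,
cohort-level filtering, consensus-junction and fusion-cDNA assembly,
neopeptide enumeration, MHC-promiscuity ranking of an external predictor's
IC50 table, and ELISpot response statistics.

## The detection model

A paired-end fragment drawn from a fusion transcript produces one of two
kinds of evidence:

* a **discordant (spanning) pair** — the two mates map inside two different
  genes, neither crossing the junction; and
* a **junction-crossing (split) read** — one read straddles the breakpoint
  and only aligns if it is split, each arm mapping to a different gene.

Discordant pairs are sensitive but notoriously unspecific (mapping
artifacts, gene-family cross-mapping). The pipeline therefore applies a
**false-positive filter**: a gene pair is only called if at least one split
read confirms the same breakpoint pair, with both breakpoints within 10 nt
of an annotated exon boundary. Genes linked to more than 7 distinct partner
genes by discordant evidence are removed entirely (the *gene promiscuity*
guard — a mapping-artifact heuristic, not to be confused with *peptide*
promiscuity below). A refinement pass then re-aligns previously unplaced
reads against a per-candidate fusion reference (±150 nt around the
junction, twice the read length, so any junction-crossing read fits) and
re-counts junction reads; counts are monotonically non-decreasing.

At cohort level, a **false-negative filter** keeps low-abundance fusions:
a pair is retained if supported by at least one junction read in at least 3
independent patients, pooled across subtypes. Two baselines play different
roles, and the distinction matters: fusions called in **cancer-free
controls** are treated as normal-tissue chimeras and excluded everywhere,
while fusions seen in **adjacent-normal tissue** from cancer patients are
*retained* (they may mark pre-malignant clones). An optional final filter
requires presence in an external evidence table (an independent cohort);
it defaults to off and is applied last when enabled — the ordering of the
per-pair predicate filters is immaterial, which the test suite checks by
commuting them.

## Alignment semantics

The contract is the *cost model*, not the engine: mismatch 2, insertion 3,
deletion 3, length fraction 0.8, similarity fraction 0.8, at most 10 hits
per read, minimum unaligned (split arm) length 15, maximum broken-pair
distance 1000. Reads are mapped with exact 16-mer seeds followed by a
windowed semi-global dynamic program (Rcpp) that consumes the read in full
with free reference ends; identity is matches over all alignment columns
(indel columns included — a documented dialect choice, since "similarity
fraction" is ambiguous under indels), and coverage is the fraction of read
bases in match/mismatch columns. On toy instances the seeded aligner is
verified against an exhaustive quadratic DP oracle.

Reads are aligned against the **spliced transcriptome** (one transcript per
gene), not the genomic contig. Reads are simulated from spliced
transcripts, and spliced alignment of wild-type introns is out of scope; a
transcript-coordinate mapping turns breakpoints back into exon numbers and
genomic positions. This keeps every alignment contiguous and makes the
"distance to exon boundary" semantics exact.

Split mapping tries every split point between 15 and `read length - 15`,
aligning prefix and suffix independently (prefix/suffix cost profiles are
computed in one forward and one backward DP per transcript) and minimizing
total cost. Two numerical details deserve note:

* **Tie-breaking.** Whenever the base just 3' of the junction in the 5'
  gene equals the first junction base of the 3' gene (probability ~1/4 per
  flanking base), adjacent split points have identical cost. A naive
  "leftmost split" rule then lands systematically 1+ nt off the exon
  boundary. Ties are therefore broken by summed breakpoint distance to
  annotated exon boundaries, then leftmost, then forward orientation.
* **Short overhangs.** A junction read with fewer than ~15 nt past the
  junction still aligns as a single segment (the overhang is absorbed as
  terminal mismatches/insertions within the 0.8 fractions), so it never
  produces split evidence — which is exactly the minimum-unaligned-length
  rule — while overhangs of 16+ nt fail the single-segment filters and
  enter split mapping.

## Consensus junction and transcript model

Junction-crossing reads are stacked anchored at their split points and a
per-column majority vote is taken; exact ties go to the alphabetically
first base (A < C < G < T) so the consensus never contains ambiguity codes
that would break translation. Reads supporting breakpoints more than 5 nt
apart are a cluster conflict (split reads within 5 nt are merged to the
modal breakpoint; this absorbs alignment jitter). The terminal hexamers on
each side of the junction are reported as breakpoint motifs — hexamers
because that is the granularity at which such motifs are conventionally
printed (e.g. AAACCA | AAATTC for the motivating fusion). The fusion cDNA
model is then spliced directly from the annotation (5' gene exons 1..b5,
3' gene exons b3..n), and in-silico PCR reports outer-to-outer product
sizes (both primers included), the conventional definition of amplicon
length.

## Neopeptides and MHC ranking

ORF discovery scans the three forward frames for ATG-to-stop ORFs (the
fusion cDNA orientation is known; reverse frames are behind a flag) and
translates them with the standard genetic code. For a fusion ORF, the
novel run is computed by *sequence comparison* — the longest common prefix
against the 5' wild-type protein, or the longest common suffix against the
3' wild-type protein — rather than trusted from annotation, so the
operation works on any fusion. The junction region is the novel run plus
k−1 flanking wild-type residues, and the enumerator emits every distinct
k-mer window that overlaps at least one novel residue (k = 8 by default;
8–11 supported, as MHC class I ligand lengths). A brute-force
window-intersection oracle checks the count law on random instances.

MHC binding prediction is deliberately an *interface*, not a dependency:
any predictor that emits (peptide, HLA allele, IC50 nM) rows can feed the
ranking, and the published MHCnuggets predictions for the 15
NSFP1-LRRC37A2 junction peptides ship as a fixture. Peptide promiscuity is
the number of distinct alleles bound with IC50 *strictly below* a
threshold (the convention used throughout is `IC50 < 500 nM`; 50 and 1000
are also profiled). Counting is strict because the source analysis writes
the thresholds as strict inequalities; a record at exactly 500 nM is not a
binder. Ranking is by promiscuity at 500 nM, ties by best IC50 then
lexicographic. An optional lower bound can drop very strong binders
(< 50 nM), which some authors argue fail to elicit responses; it is off by
default because the published tables include them.

Two internal inconsistencies of the published tables are worth recording.
The per-peptide rows support a 23-allele union for the ten 5'-side
peptides, while the prose says 28; only the 3'-side union (7) is
internally consistent, and the package asserts the table-derived values.
Likewise the prose calls the novel N-terminal run a 6-mer while the
printed peptide set implies 5 novel residues; the package computes the run
from sequence and the fixtures use 5.

## ELISpot statistics

Plates are background-subtracted by the mean of the unstimulated
(negative-control) wells — every well, including the positive control, has
that mean subtracted, so the adjusted negative-control mean is identically
zero. A condition is called positive iff its adjusted mean is at least 20
SFU per million cells *and* a Mann–Whitney U test against the positive
control gives p ≤ 0.05, with no multiple-comparison correction (a property
of the assay's standard analysis, preserved deliberately). The test is
two-sided by default; sidedness is not derivable from the published
summary statistics, so it is a documented, flag-switchable choice. The U
test delegates to `stats::wilcox.test` (exact for small untied samples,
mid-rank normal approximation under ties); an independent full-enumeration
oracle in the test suite confirms exact p-values for all group sizes up to
6 + 6. Note that with 3 replicates per condition the smallest achievable
exact two-sided p is 2/20 = 0.1, so positives require 4+ replicates; the
plate simulator defaults to 3 replicates (matching common practice) and
tests that need significance use 4.

## The synthetic cohort

The simulator generates what the analysis assumes and nothing more: one
contig of colinear same-strand genes (the read-through geometry —
antisense fusions are rejected with a clear error), uniform exon/intron
sizes within configurable ranges, a planted fusion splicing exons
1..b5 of the 5' gene to exons b3..n of its neighbor, and paired 2×76 nt
reads with per-base substitution errors at 0.001 — the error rate the
detection parameters assume. Fragment lengths are truncated normal
(mean 180, sd 30, resampled until ≥ read length); the source protocol does
not state a fragment-size distribution, so this is an explicit stand-in,
exposed in the config. Qualities are constant because the pipeline filters
on alignment, not base quality. Every pair carries a truth label
(`wildtype`, `fusion_spanning`, `fusion_junction_crossing` — fusion
fragments indistinguishable from wild type are labelled wildtype) plus
provenance columns, so recall and false-positive rates are measurable
exactly.

The default study conditions are a 6-case / 2-control cohort (two cases
per subtype), 2000 pairs per sample, fusion expression weight 0.3: a
planted recurrent fusion in four cases, and a second fusion planted in two
cases *and one cancer-free control* so the control-exclusion filter has
work to do. These sizes keep a full end-to-end run around one to two
minutes on a single core while leaving dozens of junction-crossing reads
per positive sample — deep enough that recovery of the junction, exon
boundaries, and breakpoint hexamers is exact, which the acceptance-level
test asserts.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: indels and quality-dependent errors in reads,
PCR duplicates, expression dispersion across genes, strand-specific
protocols, intronic/intergenic transcription, multi-isoform genes, and
genuine pseudogene homology (the promiscuity guard is exercised with
synthetic cross-links instead). Real-data performance rests on the
published analysis; the synthetic cohort demonstrates correctness of the
machinery, not benchmark sensitivity.

## Worked example

```{r example, eval = FALSE}
run <- run_all(list(seed = 42))
run
#> fusionneo run (seed 42): 8 sample(s), 1 fusion(s) retained
#>   retained: gene01|gene02
#>   2 junction neopeptide(s)

run$junction$five_motif; run$junction$three_motif

# published binding table: promiscuity ranking and allele unions
records <- nsfp1_lrrc37a2_binding_table()
rank_and_distribution(records)$ranking[1:3, ]
allele_union(records, c("MISNQNFQ", "ISNQNFQG", "SNQNFQGN",
                        "NQNFQGNY", "QNFQGNYI"), 500)$size  # 7
min_ic50_by_allele(records, "HLA-C*07:02")                  # ENDIKPKF, 39 nM
```

## Known limitations

* One transcript per gene; no alternative isoforms.
* Only colinear, same-strand (read-through-style) fusions are modelled;
  inversions and inter-chromosomal events are out of scope.
* The aligner is desk-scale by design (exact seeds + windowed DP); it is
  the *semantics* of the production mapper, not its throughput.
* The real 3833 nt fusion cDNA is not redistributable here;
  `synthetic_sm1_cdna()` is a clearly-labelled synthetic stand-in that
  plants the published measurable features (length, the 835/500-aa ORF
  pair, junction hexamers, the 121 bp validation amplicon). The published
  ORF geometry is in fact arithmetically over-constrained on a 3833 nt
  template (500 aa ending 10 aa past the junction plus 835 aa starting 5
  aa before it need ~3960 nt of non-overlapping frame), so the stand-in
  overlaps the two ORFs in different frames — as the real transcript must.
* ELISpot replicate counts and test sidedness are not stated in the
  published summary; defaults (3 replicates, two-sided) are documented
  choices.
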