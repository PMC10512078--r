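# fusionneo

Chimeric RNA fusion detection and neoantigen peptide discovery, as an R
package.

## What it is for

Tumors with few point mutations (breast cancer prototypically) offer few
conventional neoantigens, but chimeric RNAs — fusion transcripts arising
from read-through transcription or intergenic splicing — create amino acid
sequence found in no wild-type protein. The novel residues at a fusion
junction can be tiled into 8–11-mer peptides, screened for MHC class I
binding, and tested for CD8+ T-cell responses: a path to "off the shelf"
tumor vaccines for recurrent fusions such as NSFP1-LRRC37A2.

`fusionneo` implements that whole computational path at desk scale, for
method development and teaching:

1. **Synthetic cohort** — toy references, planted read-through fusions,
   paired-end 2×76 nt reads (error rate 0.001) with exact truth tables.
2. **Alignment** — exact-seed + dynamic-programming mapping under the cost
   model mismatch 2 / insertion 3 / deletion 3, length and similarity
   fractions 0.8, ≤10 hits per read; split mapping of junction-crossing
   reads (arms ≥ 15 nt).
3. **Fusion detection** — discordant pairs propose gene pairs, ≥1 split
   read within 10 nt of exon boundaries must confirm (false-positive
   filter), genes with >7 partners are dropped, unplaced reads are
   re-counted against a per-candidate fusion reference.
4. **Cohort filters** — fusions called in cancer-free controls are
   excluded everywhere (adjacent-normal calls are retained); retained
   pairs need ≥1 junction read in ≥3 independent patients; optional
   external-dataset recurrence; per-subtype prevalence report.
5. **Fusion transcript** — majority-vote consensus junction with
   breakpoint hexamer motifs, exon-boundary assignment, fusion cDNA
   assembly, in-silico PCR.
6. **Neopeptides** — ATG→stop ORFs, novel-run delineation by sequence
   comparison against the wild-type proteins, k-mer enumeration over
   windows that overlap fusion-derived residues.
7. **MHC ranking** — consumes any predictor's (peptide, allele, IC50)
   table; peptide promiscuity = distinct alleles with IC50 strictly below
   50/500/1000 nM; ranking, allele unions, per-allele best binders. The
   published MHCnuggets table for the 15 NSFP1-LRRC37A2 junction peptides
   ships as a fixture.
8. **ELISpot** — background subtraction against unstimulated wells, the
   ≥20 SFU/10⁶ cells threshold, exact Mann–Whitney comparison against the
   positive control (p ≤ 0.05, uncorrected), fold changes.

## Worked example

```r
library(fusionneo)

# end-to-end on the default synthetic cohort: 6 tumor + 2 control samples,
# 2000 read pairs each, one recurrent planted fusion, one fusion planted
# in a cancer-free control
run <- run_all(list(seed = 42))
run
#> fusionneo run (seed 42): 8 sample(s), 1 fusion(s) retained
#>   retained: gene01|gene02
#>   2 junction neopeptide(s)
```

The control-planted fusion (`gene03|gene04`) is called in its samples but
removed by control exclusion; the recurrent fusion is recovered with exact
exon boundaries, breakpoint hexamers and consensus junction
(`run$junction`), and its cDNA model and junction neopeptides are in
`run$fusion_cdna` and `run$peptides`.

The published binding predictions reproduce the headline numbers:

```r
records <- nsfp1_lrrc37a2_binding_table()
promiscuity_profile(records, "FPRKLYFL")[, c("n_lt_50", "n_lt_500", "n_lt_1000")]
#>   n_lt_50 n_lt_500 n_lt_1000
#> 1       6       15        18

allele_union(records, c("MISNQNFQ", "ISNQNFQG", "SNQNFQGN",
                        "NQNFQGNY", "QNFQGNYI"), 500)$size
#> [1] 7

min_ic50_by_allele(records, "HLA-C*07:02")
#> $peptide
#> [1] "ENDIKPKF"
#> $ic50_nm
#> [1] 39
```

That is: the most promiscuous 5'-side peptide binds 15 alleles below
500 nM (6 below 50 nM), the five 3'-side peptides together cover 7 distinct
alleles, and the strongest HLA-C\*07:02 binder is ENDIKPKF at 39 nM — the
peptide that scored positive in the ELISpot assay.

A thin CLI over the same functions is at `inst/scripts/fusionneo.R`
(subcommands `simulate`, `run-all`, `peptides`, `rank`, `pcr`, `elispot`).

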