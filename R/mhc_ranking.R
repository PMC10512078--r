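# Peptide-allele IC50 handling: any external MHC class I binding predictor
# that emits (peptide, allele, IC50 nM) rows can feed this module. The
# ranking statistic is peptide promiscuity: the number of distinct alleles
# bound below an IC50 threshold (strict inequality, IC50 < threshold).

HLA_PATTERN <- "^HLA-[ABC]\\*\\d{2}:\\d{2,}$"

#' Normalize an HLA class I allele name
#'
#' Accepts common spellings (`hla-c0702`, `HLA-C07:02`, `C*07:02`) and
#' returns the standard `HLA-C*07:02` form.
#'
#' @param x Character vector of allele names.
#' @return Normalized character vector; invalid entries raise an error.
#' @export
normalize_hla <- function(x) {
  out <- toupper(trimws(x))
  out <- sub("^HLA-?", "", out)
  digits <- gsub("[^0-9]", "", substring(out, 2L))
  gene <- substring(out, 1L, 1L)
  bad <- !(gene %in% c("A", "B", "C")) | nchar(digits) < 4L
  if (any(bad)) {
    stop(sprintf("malformed HLA allele name(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  sprintf("HLA-%s*%s:%s", gene, substring(digits, 1L, 2L), substring(digits, 3L))
}

#' Load a peptide-allele IC50 binding table
#'
#' @param x Path to a TSV with columns `peptide`, `allele` and `ic50_nm`
#'   (or `ic50`), or an equivalent data frame.
#' @return Data frame of class `binding_records` with normalized alleles;
#'   duplicate (peptide, allele) rows are an error.
#' @export
load_binding_table <- function(x) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else as.data.frame(x)
  if (!"ic50_nm" %in% names(df) && "ic50" %in% names(df)) {
    names(df)[names(df) == "ic50"] <- "ic50_nm"
  }
  need <- c("peptide", "allele", "ic50_nm")
  if (!all(need %in% names(df))) {
    stop("binding table needs columns peptide, allele, ic50_nm", call. = FALSE)
  }
  df$allele <- normalize_hla(df$allele)
  if (any(df$ic50_nm <= 0)) stop("IC50 values must be positive", call. = FALSE)
  dup <- duplicated(df[, c("peptide", "allele")])
  if (any(dup)) {
    stop(sprintf("duplicate (peptide, allele) rows: %s",
                 paste(unique(paste(df$peptide[dup], df$allele[dup])), collapse = "; ")),
         call. = FALSE)
  }
  class(df) <- c("binding_records", "data.frame")
  df
}

#' Bundled IC50 table for the NSFP1-LRRC37A2 junction peptides
#'
#' The published MHCnuggets predictions for the 15 8-mer neopeptides tiled
#' over the NSFP1 C-terminal truncation region (FLASLENDIKPKFPRKLYFLH) and
#' the LRRC37A2 N-terminal truncation region (MISNQNFQGNYISYID).
#'
#' @return A `binding_records` data frame (77 rows).
#' @export
nsfp1_lrrc37a2_binding_table <- function() {
  load_binding_table(system.file("extdata", "nsfp1_lrrc37a2_ic50.tsv",
                                 package = "fusionneo", mustWork = TRUE))
}

#' Promiscuity profile of one peptide
#'
#' Counts the distinct alleles bound with IC50 strictly below each
#' threshold, plus the best (lowest-IC50) allele.
#'
#' @param records A `binding_records` table.
#' @param peptide Peptide sequence.
#' @param thresholds IC50 thresholds in nM.
#' @return One-row data frame: `peptide`, one `n_lt_<t>` column per
#'   threshold, `best_allele`, `best_ic50`. Unknown peptides yield zero
#'   counts.
#' @export
promiscuity_profile <- function(records, peptide,
                                thresholds = c(50, 500, 1000)) {
  r <- records[records$peptide == peptide, , drop = FALSE]
  out <- data.frame(peptide = peptide, stringsAsFactors = FALSE)
  for (t in sort(thresholds)) {
    out[[paste0("n_lt_", t)]] <- length(unique(r$allele[r$ic50_nm < t]))
  }
  if (nrow(r) == 0L) {
    out$best_allele <- NA_character_
    out$best_ic50 <- NA_real_
  } else {
    r <- r[order(r$ic50_nm, r$allele), , drop = FALSE]
    out$best_allele <- r$allele[1]
    out$best_ic50 <- r$ic50_nm[1]
  }
  out
}

#' Union of alleles bound below a threshold
#'
#' @param records A `binding_records` table.
#' @param peptides Peptides to pool.
#' @param threshold IC50 threshold (nM), strict.
#' @return List with `alleles` (sorted) and `size`.
#' @export
allele_union <- function(records, peptides, threshold = 500) {
  r <- records[records$peptide %in% peptides & records$ic50_nm < threshold, ,
               drop = FALSE]
  alleles <- sort(unique(r$allele))
  list(alleles = alleles, size = length(alleles))
}

#' Strongest binder of one allele
#'
#' @param records A `binding_records` table.
#' @param allele HLA allele (any accepted spelling).
#' @return List with `peptide` and `ic50_nm`; ties go to the
#'   lexicographically smallest peptide. Absent alleles raise a
#'   `fusionneo_not_found` condition.
#' @export
min_ic50_by_allele <- function(records, allele) {
  allele <- normalize_hla(allele)
  r <- records[records$allele == allele, , drop = FALSE]
  if (nrow(r) == 0L) {
    stop(structure(class = c("fusionneo_not_found", "error", "condition"),
                   list(message = sprintf("no records for allele %s", allele),
                        call = NULL)))
  }
  r <- r[order(r$ic50_nm, r$peptide), , drop = FALSE]
  list(peptide = r$peptide[1], ic50_nm = r$ic50_nm[1])
}

#' Rank peptides by promiscuity and summarize the distribution
#'
#' Peptides are ranked by allele count below `threshold` (descending), ties
#' broken by best IC50 (ascending) then peptide lexicographically. The
#' distribution is a histogram of peptides per integer promiscuity value.
#' Optionally, records below `lower_bound` nM can be excluded first (very
#' strong binders are sometimes argued not to elicit responses; off by
#' default).
#'
#' @param records A `binding_records` table.
#' @param threshold Ranking threshold (nM).
#' @param thresholds All thresholds profiled.
#' @param lower_bound Optional strict lower IC50 bound applied to records
#'   before profiling (`NULL` = off).
#' @return List with `ranking` (data frame) and `distribution` (data frame
#'   `promiscuity`, `n_peptides`).
#' @export
rank_and_distribution <- function(records, threshold = 500,
                                  thresholds = c(50, 500, 1000),
                                  lower_bound = NULL) {
  if (!is.null(lower_bound)) {
    records <- records[records$ic50_nm >= lower_bound, , drop = FALSE]
  }
  peptides <- unique(records$peptide)
  profs <- do.call(rbind, lapply(peptides, function(p) {
    promiscuity_profile(records, p, thresholds)
  }))
  if (is.null(profs)) {
    return(list(ranking = data.frame(), distribution = data.frame(
      promiscuity = integer(), n_peptides = integer())))
  }
  key <- paste0("n_lt_", threshold)
  profs <- profs[order(-profs[[key]], profs$best_ic50, profs$peptide), ,
                 drop = FALSE]
  rownames(profs) <- NULL
  counts <- profs[[key]]
  tab <- table(factor(counts, levels = 0:max(counts)))
  dist <- data.frame(promiscuity = as.integer(names(tab)),
                     n_peptides = as.integer(tab))
  list(ranking = profs, distribution = dist)
}
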