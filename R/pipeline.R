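# End-to-end orchestration: one nested config drives
# simulate -> align -> detect -> filter -> consensus -> peptides
# (-> rank -> elispot when their inputs are supplied), with per-stage
# logging and deterministic, seed-stamped artifacts.

#' Default pipeline configuration
#'
#' The defaults reproduce the analysis parameters used throughout the
#' package: alignment costs (2, 3, 3), length/similarity fractions 0.8, at
#' most 10 hits, minimum unaligned length 15, exon-boundary distance 10,
#' broken-pair distance 1000, gene promiscuity threshold 7, recurrence in 3
#' patients, peptide length k = 8, IC50 thresholds 50/500/1000 nM, ELISpot
#' threshold 20 SFU and alpha 0.05.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    simulate = list(
      n_pairs = 2000L, read_len = 76L, error_rate = 0.001,
      fragment_mean = 180, fragment_sd = 30, weight = 0.3,
      reference = list(n_genes = 6L,
                       exon_count_range = c(2L, 4L),
                       exon_len_range = c(120L, 200L),
                       intron_len_range = c(50L, 100L))),
    align = list(mismatch_cost = 2L, insertion_cost = 3L, deletion_cost = 3L,
                 length_fraction = 0.8, similarity_fraction = 0.8,
                 max_hits = 10L, min_unaligned = 15L,
                 max_pair_distance = 1000L),
    detect = list(max_exon_boundary_distance = 10L,
                  max_broken_pair_distance = 1000L,
                  gene_promiscuity_threshold = 7L,
                  min_junction_reads_fp_filter = 1L),
    filter = list(min_patients = 3L, use_external = FALSE,
                  external_evidence = NULL),
    peptides = list(k = 8L, min_orf_len_aa = 15L),
    rank = list(threshold = 500, thresholds = c(50, 500, 1000),
                binding_table = NULL, lower_bound = NULL),
    elispot = list(threshold = 20, alpha = 0.05, input = NULL),
    output = list(dir = NULL)
  )
}

merge_config <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown config key: %s", full))
      next
    }
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(d)) {
      if (!is.list(u)) {
        errors$msgs <- c(errors$msgs,
                         sprintf("config key %s must be a section", full))
      } else {
        defaults[[key]] <- merge_config(d, u, full, errors)
      }
    } else {
      if (!is.null(d) && is.numeric(d) && !is.numeric(u)) {
        errors$msgs <- c(errors$msgs,
                         sprintf("config key %s must be numeric (got %s)",
                                 full, class(u)[1]))
      } else {
        defaults[[key]] <- u
      }
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Unknown keys are rejected, defaults are filled in, and every problem is
#' reported at once.
#'
#' @param config Nested list (possibly empty) or path to a YAML file.
#' @return Normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config) %||% list()
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(default_config(), config, "", errors)
  check <- function(ok, msg) if (!ok) errors$msgs <- c(errors$msgs, msg)
  check(cfg$simulate$error_rate >= 0 && cfg$simulate$error_rate < 0.5,
        "simulate.error_rate must be in [0, 0.5)")
  check(cfg$simulate$n_pairs > 0, "simulate.n_pairs must be > 0")
  check(cfg$simulate$weight >= 0 && cfg$simulate$weight <= 1,
        "simulate.weight must be in [0, 1]")
  check(cfg$peptides$k >= 1, "peptides.k must be >= 1")
  check(cfg$filter$min_patients >= 1, "filter.min_patients must be >= 1")
  if (length(errors$msgs) > 0L) {
    stop(paste(c("invalid configuration:", errors$msgs), collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

default_fusion_defs <- function(reference, weight = 0.3) {
  n_ex <- function(g) max(gene_exons(reference, g)$exon_number)
  mk <- function(g5, g3) {
    planted_fusion(g5, max(1L, n_ex(g5) - 1L), g3, min(2L, n_ex(g3)),
                   expression_weight = weight)
  }
  list(f1 = mk("gene01", "gene02"), f2 = mk("gene03", "gene04"))
}

translate_to_stop <- function(seqx, pos0) {
  n <- nchar(seqx)
  n_cod <- (n - pos0) %/% 3L
  if (n_cod < 1L) return("")
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seqx, pos0 + 1L, pos0 + 3L * n_cod)),
    no.init.codon = TRUE))
  sub("\\*.*$", "", prot)
}

#' Run the whole pipeline on a synthetic cohort
#'
#' Simulates the cohort described by the configuration (six tumor samples,
#' two cancer-free controls, one recurrent planted fusion plus one fusion
#' planted in a control), runs alignment, detection, refinement and the
#' cohort filters, assembles the consensus junction and fusion cDNA of the
#' top retained fusion, enumerates its junction neopeptides, and (when
#' inputs are configured) ranks peptides against a binding table and scores
#' an ELISpot plate. Reruns with an identical configuration are
#' reproducible.
#'
#' @param config Nested configuration list or YAML path (see
#'   [default_config()]).
#' @param out_dir Output directory for report artifacts (overrides
#'   `config$output$dir`; `NULL` writes nothing).
#' @return A `fusionneo_run` summary list.
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  out_dir <- out_dir %||% cfg$output$dir
  log_lines <- character(0)
  logit <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  seed <- as.integer(cfg$seed)
  logit("seed: %d", seed)

  refp <- cfg$simulate$reference
  reference <- generate_reference(seed, n_genes = refp$n_genes,
                                  exon_count_range = refp$exon_count_range,
                                  exon_len_range = refp$exon_len_range,
                                  intron_len_range = refp$intron_len_range)
  fusion_defs <- default_fusion_defs(reference, cfg$simulate$weight)
  design <- cohort_design(n_pairs = cfg$simulate$n_pairs,
                          weight = cfg$simulate$weight)
  cohort <- simulate_cohort(reference, design, fusion_defs, seed = seed,
                            read_len = cfg$simulate$read_len,
                            fragment_mean = cfg$simulate$fragment_mean,
                            fragment_sd = cfg$simulate$fragment_sd,
                            error_rate = cfg$simulate$error_rate)
  logit("simulated %d samples x %d pairs", nrow(design), cfg$simulate$n_pairs)

  index <- transcript_index(reference)
  acfg <- do.call(align_config, cfg$align)
  dcfg <- do.call(detect_config, cfg$detect)
  calls <- list()
  stage_counts <- list()
  for (sid in names(cohort$samples)) {
    ev <- collect_sample_evidence(cohort$samples[[sid]], index, acfg)
    cand <- detect_fusions(ev, index, dcfg, acfg)
    cand <- refine_fusion_counts(cand, ev$unplaced, index, acfg)
    calls[[sid]] <- cand
    stage_counts[[sid]] <- data.frame(
      sample_id = sid,
      discordant = sum(ev$pairs$class == "discordant_two_genes"),
      half_mapped = sum(ev$pairs$class == "half_mapped"),
      split_reads = length(ev$splits),
      unplaced = nrow(ev$unplaced),
      candidates = nrow(cand),
      stringsAsFactors = FALSE)
    logit("%s: %d discordant pairs, %d split reads, %d candidate(s)",
          sid, stage_counts[[sid]]$discordant, stage_counts[[sid]]$split_reads,
          nrow(cand))
  }
  ext <- cfg$filter$external_evidence
  if (is.character(ext)) ext <- read_external_evidence(ext)
  callset <- cohort_callset(calls, cohort$meta, ext)
  n0 <- length(retained_pairs(callset))
  callset <- exclude_control_fusions(callset)
  n1 <- length(retained_pairs(callset))
  callset <- recurrence_filter(callset, cfg$filter$min_patients)
  n2 <- length(retained_pairs(callset))
  callset <- external_recurrence_filter(callset, cfg$filter$use_external)
  n3 <- length(retained_pairs(callset))
  logit("filters: %d pairs -> %d after control exclusion -> %d after recurrence -> %d after external",
        n0, n1, n2, n3)
  prevalence <- prevalence_report(callset)

  junction <- NULL; cdna <- NULL; peptides <- NULL; regions <- list()
  if (nrow(prevalence) > 0L) {
    top <- paste(prevalence$gene5[1], prevalence$gene3[1], sep = "|")
    splits <- list()
    for (sid in names(callset$calls)) {
      sp <- attr(callset$calls[[sid]], "splits")[[top]]
      if (!is.null(sp)) splits <- c(splits, sp)
    }
    junction <- build_consensus_junction(splits, dcfg$breakpoint_cluster_tol)
    junction <- map_exon_boundaries(junction, index,
                                    dcfg$max_exon_boundary_distance)
    cdna <- assemble_fusion_cdna(reference, junction$five_boundary,
                                 junction$three_boundary)
    logit("consensus junction %s|%s: exon %d | exon %d, motifs %s | %s, %d reads",
          junction$five_gene, junction$three_gene,
          junction$five_boundary$exon, junction$three_boundary$exon,
          junction$five_motif, junction$three_motif,
          junction$n_supporting_reads)

    orfs <- find_orfs(cdna$cdna, min_len_aa = cfg$peptides$min_orf_len_aa)
    j <- cdna$junction_offset_nt
    crossing <- orfs[orfs$nt_start < j & orfs$nt_end > j, , drop = FALSE]
    crossing <- head(crossing, 2L)
    tx5 <- index$seqs[[junction$five_gene]]
    tx3 <- index$seqs[[junction$three_gene]]
    bp3 <- junction$bp3
    pep_rows <- list()
    for (i in seq_len(nrow(crossing))) {
      orf <- crossing[i, ]
      wt5 <- translate_to_stop(tx5, orf$nt_start)
      start3 <- j + ((3L - ((j - orf$nt_start) %% 3L)) %% 3L)
      wt3 <- translate_to_stop(tx3, start3 - j + bp3)
      reg <- tryCatch(
        delineate_novel_region(orf$protein, wt5, wt3, cfg$peptides$k),
        error = function(e) NULL)
      if (is.null(reg)) next
      regions[[length(regions) + 1L]] <- reg
      pep_rows[[length(pep_rows) + 1L]] <-
        enumerate_neopeptides(reg, cfg$peptides$k)
    }
    peptides <- if (length(pep_rows) > 0L) do.call(rbind, pep_rows) else NULL
    logit("%d neopeptide region(s), %d peptide(s)",
          length(regions), if (is.null(peptides)) 0L else nrow(peptides))
  } else {
    logit("no fusion retained after filtering")
  }

  ranking <- NULL
  if (!is.null(cfg$rank$binding_table)) {
    records <- load_binding_table(cfg$rank$binding_table)
    ranking <- rank_and_distribution(records, cfg$rank$threshold,
                                     cfg$rank$thresholds, cfg$rank$lower_bound)
    logit("ranked %d peptides from binding table", nrow(ranking$ranking))
  }
  elispot_calls <- NULL
  if (!is.null(cfg$elispot$input)) {
    plate <- read_elispot_tsv(cfg$elispot$input)
    elispot_calls <- call_positive(plate, cfg$elispot$threshold,
                                   cfg$elispot$alpha)
    logit("ELISpot: %d/%d conditions positive",
          sum(elispot_calls$positive), nrow(elispot_calls))
  }

  summary <- list(
    seed = seed,
    config_hash = config_hash(cfg),
    n_samples = nrow(design),
    retained_pairs = retained_pairs(callset),
    n_retained = length(retained_pairs(callset)),
    stage_counts = do.call(rbind, stage_counts),
    prevalence = prevalence,
    junction = junction,
    fusion_cdna = cdna,
    peptides = peptides,
    ranking = ranking,
    elispot = elispot_calls,
    log = log_lines)
  hash_src <- summary[c("seed", "config_hash", "retained_pairs", "n_retained",
                        "prevalence", "peptides")]
  tmp <- tempfile()
  writeLines(deparse(hash_src), tmp)
  summary$hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(summary) <- "fusionneo_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(prevalence, file.path(out_dir, "prevalence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(junction)) {
      write_junction_report(junction, file.path(out_dir, "junction"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(cdna$cdna, "fusion_cdna")),
        file.path(out_dir, "fusion_cdna.fa"))
    }
    if (!is.null(peptides)) {
      write.table(peptides, file.path(out_dir, "peptides.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(ranking)) {
      write.table(ranking$ranking, file.path(out_dir, "ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(elispot_calls)) {
      write.table(elispot_calls, file.path(out_dir, "elispot_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    yaml::write_yaml(list(seed = seed, config_hash = summary$config_hash,
                          hash = summary$hash,
                          n_retained = summary$n_retained,
                          retained_pairs = summary$retained_pairs),
                     file.path(out_dir, "summary.yaml"))
  }
  summary
}

#' @export
print.fusionneo_run <- function(x, ...) {
  cat(sprintf("fusionneo run (seed %d): %d sample(s), %d fusion(s) retained\n",
              x$seed, x$n_samples, x$n_retained))
  if (x$n_retained > 0L) {
    cat("  retained:", paste(x$retained_pairs, collapse = ", "), "\n")
  }
  if (!is.null(x$peptides)) {
    cat(sprintf("  %d junction neopeptide(s)\n", nrow(x$peptides)))
  }
  invisible(x)
}
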