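# Cohort-level inclusion/exclusion logic. Two tissue baselines play
# different roles: cancer-free controls are exclusionary (anything called
# there is treated as a normal-tissue chimera and removed everywhere),
# while paired adjacent-normal tissue is *not* exclusionary — fusions seen
# there may mark pre-malignant clones and are retained in cases. The
# false-negative filter then keeps pairs supported by at least one junction
# read in a minimum number of independent patients, pooled across subtypes.

#' Bundle per-sample calls into a cohort call set
#'
#' @param calls Named list (by sample id) of candidate tables from
#'   [detect_fusions()] / [refine_fusion_counts()].
#' @param meta Data frame of [sample_meta()] rows covering every sample in
#'   `calls`.
#' @param external_evidence Optional data frame with `gene5`, `gene3`:
#'   ordered gene pairs seen in an independent dataset.
#' @return An object of class `cohort_callset`.
#' @export
cohort_callset <- function(calls, meta, external_evidence = NULL) {
  missing <- setdiff(names(calls), meta$sample_id)
  if (length(missing) > 0L) {
    stop(sprintf("samples without metadata: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(calls = calls, meta = meta,
                 external_evidence = external_evidence),
            class = "cohort_callset")
}

#' @export
print.cohort_callset <- function(x, ...) {
  n_calls <- sum(vapply(x$calls, nrow, 0L))
  cat(sprintf("cohort_callset: %d samples, %d candidate calls, %d pairs retained\n",
              length(x$calls), n_calls, length(retained_pairs(x))))
  invisible(x)
}

pair_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$gene5, df$gene3, sep = "|")
}

#' Gene pairs currently present in a call set
#' @param callset A `cohort_callset`.
#' @return Character vector of `gene5|gene3` keys.
#' @export
retained_pairs <- function(callset) {
  unique(unlist(lapply(callset$calls, pair_key), use.names = FALSE))
}

drop_pairs <- function(callset, keys) {
  callset$calls <- lapply(callset$calls, function(df) {
    df[!(pair_key(df) %in% keys), , drop = FALSE]
  })
  callset
}

#' Remove fusions called in cancer-free controls
#'
#' Any gene pair called in any `cancer_free_control` sample is removed from
#' every sample. Pairs present only in `adjacent_normal` samples are
#' retained in cases.
#'
#' @param callset A `cohort_callset`.
#' @return Filtered call set.
#' @export
exclude_control_fusions <- function(callset) {
  ctrl <- callset$meta$sample_id[callset$meta$group == "cancer_free_control"]
  if (length(ctrl) == 0L) {
    warning("no cancer-free control samples; control exclusion is a pass-through")
    return(callset)
  }
  ctrl_pairs <- unique(unlist(lapply(callset$calls[intersect(names(callset$calls), ctrl)],
                                     pair_key), use.names = FALSE))
  drop_pairs(callset, ctrl_pairs)
}

#' Recurrence (false-negative) filter
#'
#' Retains gene pairs supported by at least one junction-crossing read in at
#' least `min_patients` distinct case samples, pooled across subtypes.
#'
#' @param callset A `cohort_callset`.
#' @param min_patients Minimum number of distinct case samples.
#' @return Filtered call set.
#' @export
recurrence_filter <- function(callset, min_patients = 3L) {
  cases <- callset$meta$sample_id[callset$meta$is_case]
  counts <- list()
  for (sid in intersect(names(callset$calls), cases)) {
    df <- callset$calls[[sid]]
    keys <- pair_key(df)[df$junction_reads >= 1L]
    for (k in keys) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  keep <- names(counts)[unlist(counts) >= min_patients]
  all_pairs <- retained_pairs(callset)
  drop_pairs(callset, setdiff(all_pairs, keep))
}

#' External-dataset recurrence filter
#'
#' Retains only gene pairs present in the independent evidence table. With
#' no evidence loaded (or `use_external = FALSE`) the filter is a no-op.
#'
#' @param callset A `cohort_callset`.
#' @param use_external Apply the filter?
#' @return Filtered call set.
#' @export
external_recurrence_filter <- function(callset, use_external = TRUE) {
  ev <- callset$external_evidence
  if (!use_external || is.null(ev) || nrow(ev) == 0L) return(callset)
  keep <- paste(ev$gene5, ev$gene3, sep = "|")
  drop_pairs(callset, setdiff(retained_pairs(callset), keep))
}

#' Prevalence report (per gene pair, per subtype)
#'
#' For every retained gene pair and case group: the number of fusion-positive
#' samples and the mean junction-crossing read count over positive samples.
#' Averages are printed as integers (rounded half-up) unless
#' `full_precision = TRUE`. Rows are sorted by total positive samples,
#' descending.
#'
#' @param callset A `cohort_callset`.
#' @param full_precision Keep fractional averages?
#' @return Data frame, one row per gene pair.
#' @export
prevalence_report <- function(callset, full_precision = FALSE) {
  groups <- unique(callset$meta$group[callset$meta$is_case])
  pairs <- retained_pairs(callset)
  rows <- list()
  for (p in pairs) {
    parts <- strsplit(p, "|", fixed = TRUE)[[1]]
    row <- data.frame(gene5 = parts[1], gene3 = parts[2],
                      stringsAsFactors = FALSE)
    total <- 0L
    for (g in groups) {
      sids <- callset$meta$sample_id[callset$meta$group == g]
      jr <- numeric(0)
      for (sid in intersect(names(callset$calls), sids)) {
        df <- callset$calls[[sid]]
        hit <- pair_key(df) == p & df$junction_reads >= 1L
        if (any(hit)) jr <- c(jr, df$junction_reads[hit])
      }
      npos <- length(jr)
      avg <- if (npos > 0L) mean(jr) else 0
      if (!full_precision) avg <- round_half_up(avg)
      safe <- gsub("[^A-Za-z0-9]", "", g)
      row[[paste0("positive_", safe)]] <- npos
      row[[paste0("avg_junction_reads_", safe)]] <- avg
      total <- total + npos
    }
    row$total_positive <- total
    rows[[p]] <- row
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene5 = character(), gene3 = character(),
                      total_positive = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_positive, out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an external-evidence table
#' @param path TSV with columns `gene5`, `gene3`.
#' @return Data frame.
#' @export
read_external_evidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene5", "gene3") %in% names(ev))) {
    stop("external evidence needs columns gene5, gene3", call. = FALSE)
  }
  ev
}
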