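# ELISpot positivity and comparison statistics: background subtraction
# against the unstimulated (negative control) wells, the 20 SFU / 10^6
# cells minimum, Mann-Whitney comparison against the positive control, and
# fold-change reporting. No multiple-testing correction is applied, by
# design of the assay analysis.

#' Construct an ELISpot plate
#'
#' @param data Data frame with columns `condition` and `sfu` (spot-forming
#'   units per 10^6 cells), one row per replicate well.
#' @param negative_control,positive_control Condition labels of the
#'   unstimulated and positive-control wells.
#' @return An object of class `elispot_plate`.
#' @export
elispot_plate <- function(data, negative_control = "NC",
                          positive_control = "CMV") {
  if (!all(c("condition", "sfu") %in% names(data))) {
    stop("plate data needs columns condition, sfu", call. = FALSE)
  }
  if (any(data$sfu < 0)) stop("SFU counts must be >= 0", call. = FALSE)
  for (ctl in c(negative_control, positive_control)) {
    if (!ctl %in% data$condition) {
      stop(sprintf("control condition '%s' missing from plate", ctl),
           call. = FALSE)
    }
  }
  structure(list(data = data, negative_control = negative_control,
                 positive_control = positive_control),
            class = "elispot_plate")
}

#' Subtract the unstimulated background
#'
#' Every replicate (positive control included) has the mean negative-control
#' SFU subtracted. Adjusted values may be negative; they are clamped to zero
#' only for fold-change display.
#'
#' @param plate An `elispot_plate`.
#' @return The plate with an `adjusted` column added to `$data` and the
#'   `nc_mean` recorded.
#' @export
background_subtract <- function(plate) {
  nc <- plate$data$sfu[plate$data$condition == plate$negative_control]
  if (length(nc) == 0L) stop("negative control has no replicates", call. = FALSE)
  plate$data$adjusted <- plate$data$sfu - mean(nc)
  plate$nc_mean <- mean(nc)
  plate
}

#' Mann-Whitney U test
#'
#' Exact two-sided p for small untied samples, mid-rank normal approximation
#' otherwise. U is reported for the first sample.
#'
#' @param x,y Numeric replicate vectors (both non-empty).
#' @param alternative Passed through (`two.sided` default; sidedness is a
#'   documented analysis choice, not fixed by the assay).
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(U = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}

#' Fold change versus a reference condition
#'
#' Means are clamped at zero before forming the ratio; a zero (or negative)
#' reference mean makes the fold change undefined (`NA` with a warning).
#'
#' @param adjusted_condition_mean,adjusted_reference_mean Background-adjusted
#'   means.
#' @return Ratio, or `NA_real_` when undefined.
#' @export
fold_vs_reference <- function(adjusted_condition_mean, adjusted_reference_mean) {
  a <- max(0, adjusted_condition_mean)
  b <- max(0, adjusted_reference_mean)
  if (b == 0) {
    warning("reference mean is zero after clamping; fold change undefined")
    return(NA_real_)
  }
  a / b
}

#' Call positive ELISpot responses
#'
#' A condition is positive iff its background-adjusted mean is at least
#' `threshold` SFU / 10^6 cells *and* the Mann-Whitney p-value against the
#' positive control is at most `alpha`. P-values are not corrected for
#' multiple comparisons.
#'
#' @param plate An `elispot_plate` (background subtraction is applied if it
#'   has not been already).
#' @param threshold Minimum adjusted mean (default 20).
#' @param alpha Significance level (default 0.05).
#' @param alternative Sidedness of the Mann-Whitney test.
#' @return Data frame with one row per non-control condition: `condition`,
#'   `adjusted_mean`, `U`, `p_value`, `fold_vs_positive`, `positive`.
#' @export
call_positive <- function(plate, threshold = 20, alpha = 0.05,
                          alternative = "two.sided") {
  if (is.null(plate$data$adjusted)) plate <- background_subtract(plate)
  d <- plate$data
  ref <- d$adjusted[d$condition == plate$positive_control]
  ref_mean <- mean(ref)
  conds <- setdiff(unique(d$condition),
                   c(plate$negative_control, plate$positive_control))
  rows <- list()
  for (cond in conds) {
    x <- d$adjusted[d$condition == cond]
    if (length(x) < 1L || length(ref) < 1L) {
      warning(sprintf("condition '%s': too few replicates, test skipped", cond))
      next
    }
    mw <- mann_whitney(x, ref, alternative)
    am <- mean(x)
    rows[[cond]] <- data.frame(
      condition = cond, adjusted_mean = am, U = mw$U, p_value = mw$p_value,
      fold_vs_positive = suppressWarnings(fold_vs_reference(am, ref_mean)),
      positive = am >= threshold && mw$p_value <= alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition = character(), adjusted_mean = numeric(),
                      U = numeric(), p_value = numeric(),
                      fold_vs_positive = numeric(), positive = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read an ELISpot TSV
#' @param path TSV with columns `condition`, `sfu` (one row per replicate).
#' @param ... Passed to [elispot_plate()].
#' @return An `elispot_plate`.
#' @export
read_elispot_tsv <- function(path, ...) {
  elispot_plate(read.delim(path, stringsAsFactors = FALSE), ...)
}

#' Simulate an ELISpot plate
#'
#' Poisson well counts around a background rate; responder peptides get an
#' additive effect. Three replicates per condition by default.
#'
#' @param peptides Condition labels for the test wells.
#' @param responders Subset of `peptides` with a true response.
#' @param seed RNG seed.
#' @param n_replicates Wells per condition.
#' @param background_rate,effect,positive_effect Mean SFU of background,
#'   responder increment, and positive-control increment.
#' @return An `elispot_plate`.
#' @export
simulate_elispot_plate <- function(peptides, responders = character(0),
                                   seed = 1L, n_replicates = 3L,
                                   background_rate = 10, effect = 60,
                                   positive_effect = 40) {
  with_seed(seed, {
    rows <- list()
    add <- function(cond, lambda) {
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = cond, sfu = rpois(n_replicates, lambda),
        stringsAsFactors = FALSE)
    }
    add("NC", background_rate)
    add("CMV", background_rate + positive_effect)
    for (p in peptides) {
      add(p, background_rate + if (p %in% responders) effect else 2)
    }
    elispot_plate(do.call(rbind, rows))
  })
}
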