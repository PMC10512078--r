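# Cohort-level filters: control exclusion, the recurrence (false-negative)
# filter, external recurrence, and the prevalence report.

mk_call <- function(gene5, gene3, jr = 5L, sp = 3L) {
  n <- length(gene5)
  data.frame(gene5 = gene5, gene3 = gene3,
             bp5 = rep(100L, n), bp3 = rep(50L, n),
             exon5 = rep(2L, n), exon3 = rep(2L, n),
             dist5 = rep(0L, n), dist3 = rep(0L, n),
             junction_reads = rep(jr, length.out = n),
             spanning_pairs = rep(sp, length.out = n),
             stringsAsFactors = FALSE)
}

mk_meta <- function(ids, groups) {
  do.call(rbind, Map(sample_meta, ids, groups))
}

toy_callset <- function() {
  calls <- list(
    c1 = rbind(mk_call("gA", "gB", 10L), mk_call("gC", "gD", 4L)),
    c2 = rbind(mk_call("gA", "gB", 20L), mk_call("gC", "gD", 2L)),
    c3 = mk_call("gA", "gB", 7L),
    c4 = mk_call("gE", "gF", 9L),
    an1 = mk_call("gE", "gF", 3L),
    ctrl1 = mk_call("gC", "gD", 6L),
    ctrl2 = empty_call())
  meta <- mk_meta(c("c1", "c2", "c3", "c4", "an1", "ctrl1", "ctrl2"),
                  c("TNBC", "HER2+", "HR+", "HR+", "adjacent_normal",
                    "cancer_free_control", "cancer_free_control"))
  cohort_callset(calls, meta)
}

empty_call <- function() mk_call(character(0), character(0), integer(0), integer(0))

test_that("control-called fusions are excluded everywhere, adjacent-normal ones kept", {
  cs <- toy_callset()
  out <- exclude_control_fusions(cs)
  # gC|gD was called in ctrl1 and three case samples: removed everywhere
  expect_false("gC|gD" %in% retained_pairs(out))
  # gE|gF is in an adjacent normal + a case: retained
  expect_true("gE|gF" %in% retained_pairs(out))
  expect_true("gA|gB" %in% retained_pairs(out))

  # no controls: warning + pass-through
  cs2 <- cohort_callset(list(c1 = mk_call("gA", "gB")),
                        mk_meta("c1", "TNBC"))
  expect_warning(out2 <- exclude_control_fusions(cs2), "control")
  expect_equal(retained_pairs(out2), "gA|gB")

  # empty callset stays empty
  cs3 <- cohort_callset(list(c1 = empty_call(), ctrl1 = empty_call()),
                        mk_meta(c("c1", "ctrl1"), c("TNBC", "cancer_free_control")))
  expect_equal(length(retained_pairs(exclude_control_fusions(cs3))), 0L)
})

test_that("recurrence filter enforces the three-patient minimum, pooled", {
  cs <- toy_callset()
  out <- recurrence_filter(cs, min_patients = 3)
  expect_true("gA|gB" %in% retained_pairs(out))    # 3 cases
  expect_false("gC|gD" %in% retained_pairs(out))   # 2 cases (+1 control, not counted)
  expect_false("gE|gF" %in% retained_pairs(out))   # 1 case + adjacent normal

  # boundary: exactly 3 cases with 1 read each retained, 2 cases removed
  calls <- list(a = mk_call("gX", "gY", 1L), b = mk_call("gX", "gY", 1L),
                c = mk_call("gX", "gY", 1L), d = mk_call("gP", "gQ", 1L),
                e = mk_call("gP", "gQ", 1L))
  meta <- mk_meta(letters[1:5], rep("TNBC", 5))
  cs2 <- cohort_callset(calls, meta)
  out2 <- recurrence_filter(cs2, 3)
  expect_equal(retained_pairs(out2), "gX|gY")

  # retained-set size is monotone non-increasing in min_patients
  sizes <- vapply(1:5, function(m) length(retained_pairs(recurrence_filter(cs, m))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("external recurrence filter retains listed pairs and honors the no-op flag", {
  ev <- data.frame(gene5 = "gA", gene3 = "gB", stringsAsFactors = FALSE)
  cs <- toy_callset()
  cs$external_evidence <- ev
  out <- external_recurrence_filter(cs)
  expect_equal(retained_pairs(out), "gA|gB")
  out2 <- external_recurrence_filter(cs, use_external = FALSE)
  expect_setequal(retained_pairs(out2), retained_pairs(cs))
  cs$external_evidence <- NULL
  expect_setequal(retained_pairs(external_recurrence_filter(cs)), retained_pairs(cs))
})

test_that("prevalence report counts positives and averages junction reads", {
  calls <- list(t1 = mk_call("gA", "gB", 10L), t2 = mk_call("gA", "gB", 20L),
                t3 = empty_call(), t4 = empty_call(), t5 = empty_call(),
                h1 = mk_call("gA", "gB", 7L))
  meta <- mk_meta(c("t1", "t2", "t3", "t4", "t5", "h1"),
                  c(rep("TNBC", 5), "HR+"))
  cs <- cohort_callset(calls, meta)
  rep <- prevalence_report(cs)
  expect_equal(rep$positive_TNBC, 2L)
  expect_equal(rep$avg_junction_reads_TNBC, 15)
  expect_equal(rep$positive_HR, 1L)
  expect_equal(rep$total_positive, 3L)

  # a group with no positives reports 0 / 0
  meta2 <- rbind(meta, sample_meta("x1", "HER2+"))
  cs2 <- cohort_callset(c(calls, list(x1 = empty_call())), meta2)
  rep2 <- prevalence_report(cs2)
  expect_equal(rep2$positive_HER2, 0L)
  expect_equal(rep2$avg_junction_reads_HER2, 0)

  # integer averages round half-up; full precision on request
  calls3 <- list(a = mk_call("gA", "gB", 1L), b = mk_call("gA", "gB", 2L))
  cs3 <- cohort_callset(calls3, mk_meta(c("a", "b"), c("TNBC", "TNBC")))
  expect_equal(prevalence_report(cs3)$avg_junction_reads_TNBC, 2)  # 1.5 -> 2
  expect_equal(prevalence_report(cs3, full_precision = TRUE)$avg_junction_reads_TNBC, 1.5)
})

test_that("filters are per-pair predicates: order and relabeling do not matter", {
  cs <- toy_callset()
  a <- recurrence_filter(exclude_control_fusions(cs), 3)
  b <- exclude_control_fusions(recurrence_filter(cs, 3))
  expect_setequal(retained_pairs(a), retained_pairs(b))

  # permutation invariance under sample relabeling
  perm <- rev(names(cs$calls))
  cs_perm <- cohort_callset(setNames(cs$calls[perm], paste0("s_", perm)),
                            within(cs$meta[match(perm, cs$meta$sample_id), ],
                                   sample_id <- paste0("s_", perm)))
  a2 <- recurrence_filter(exclude_control_fusions(cs_perm), 3)
  expect_setequal(retained_pairs(a2), retained_pairs(a))

  # brute-force predicate oracle: every retained pair satisfies both
  # predicates; every removed pair fails at least one
  ctrl_ids <- cs$meta$sample_id[cs$meta$group == "cancer_free_control"]
  case_ids <- cs$meta$sample_id[cs$meta$is_case]
  all_pairs <- retained_pairs(cs)
  oracle_keep <- Filter(function(p) {
    in_ctrl <- any(vapply(ctrl_ids, function(s) {
      df <- cs$calls[[s]]; !is.null(df) && p %in% paste(df$gene5, df$gene3, sep = "|")
    }, TRUE))
    n_case <- sum(vapply(case_ids, function(s) {
      df <- cs$calls[[s]]
      !is.null(df) && p %in% paste(df$gene5, df$gene3, sep = "|")[df$junction_reads >= 1]
    }, TRUE))
    !in_ctrl && n_case >= 3
  }, all_pairs)
  expect_setequal(retained_pairs(a), oracle_keep)
})
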