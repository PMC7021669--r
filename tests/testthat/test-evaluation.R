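# One small hand-built result set used across several blocks: a single
# query with a true compound at quotient 1.0 and two decoys.
one_query <- function() {
  out <- tibble::tibble(
    query_id = "Q1", mixture_id = "M1", true_compound_id = "true",
    compound_id = c("true", "d1", "d2"),
    aggregate_score = c(2.0, 0.8, 0.1),
    rank = 1:3, percentile = c(100, 50, 0),
    quotient = c(1.0, 0.4, 0.05),
    is_true = c(TRUE, FALSE, FALSE), n_candidates = 3L)
  attr(out, "queries") <- tibble::tibble(
    query_id = "Q1", mixture_id = "M1", spectrum_ids = "s1",
    true_compound_id = "true", n_candidates = 3L, true_retrieved = TRUE)
  out
}

test_that("classification at a quotient cutoff follows the retention rule", {
  r <- one_query()
  got <- classify_at_cutoff(r, 0.13, "quotient")
  expect_equal(got$tp, 1L); expect_equal(got$fp, 1L)
  expect_equal(got$tn, 1L); expect_equal(got$fn, 0L)

  # cutoff 0 retains everything
  all_in <- classify_at_cutoff(r, 0, "quotient")
  expect_equal(all_in$fn, 0L); expect_equal(all_in$tn, 0L)
  expect_equal(all_in$tpr, 1)

  # cutoff above every value retains nothing
  none <- classify_at_cutoff(r, 1.5, "quotient")
  expect_equal(none$tp, 0L); expect_equal(none$fp, 0L)
})

test_that("a true compound never retrieved counts as FN at every cutoff", {
  r <- one_query()
  q <- attr(r, "queries")
  attr(r, "queries") <- dplyr::bind_rows(q, tibble::tibble(
    query_id = "Q2", mixture_id = "M1", spectrum_ids = "s2",
    true_compound_id = "ghost", n_candidates = 0L, true_retrieved = FALSE))
  for (cut in c(0, 0.5, 1)) {
    cc <- classify_at_cutoff(r, cut, "quotient")
    expect_equal(cc$tp + cc$fn, 2L)  # one scored true + one missed
  }
  expect_equal(classify_at_cutoff(r, 0, "quotient")$tpr, 0.5)
})

test_that("ROC sweep uses the 101-point grid and the printed equations", {
  r <- one_query()
  for (metric in c("percentile", "quotient")) {
    curve <- roc_sweep(r, metric)
    expect_equal(nrow(curve), 101L)
    expect_equal(curve$cutoff[1], 0)
    expect_equal(max(curve$cutoff), if (metric == "percentile") 100 else 1)
    expect_equal(curve$tpr, curve$tp / (curve$tp + curve$fn))
    expect_equal(curve$fpr, curve$fp / (curve$fp + curve$tn))
    # single candidate = true with quotient 1 -> TPR 1 for all cutoffs
    expect_true(all(curve$tpr[curve$cutoff <= 1] >= 0))
  }
  # true compound at quotient 1.0 -> TPR 1 along the whole quotient grid
  expect_true(all(roc_sweep(r, "quotient")$tpr == 1))
})

test_that("ROC sweep equals a brute-force per-cutoff recount", {
  set.seed(909)
  r <- random_results(n_queries = 20, max_candidates = 10)
  for (metric in c("percentile", "quotient")) {
    curve <- roc_sweep(r, metric)
    for (i in sample(101, 15)) {   # spot-check a random subset of the grid
      want <- oracle_confusion(r, curve$cutoff[i], metric)
      expect_equal(unlist(curve[i, c("tp", "fp", "tn", "fn")]),
                   want[c("tp", "fp", "tn", "fn")],
                   ignore_attr = TRUE)
    }
    expect_true(all(diff(curve$tpr) <= 1e-12))
    expect_true(all(diff(curve$fpr) <= 1e-12))
  }
})

test_that("global cutoff selection takes the most stringent qualifying point", {
  curve <- tibble::tibble(cutoff = c(0, 10, 20),
                          tp = c(20, 19, 17), fn = c(0, 1, 3),
                          fp = c(50, 20, 5), tn = c(0, 30, 45),
                          tpr = c(1.0, 0.95, 0.88),
                          fpr = c(1.0, 0.4, 0.1))
  expect_equal(select_global_cutoff(curve, 0.90)$cutoff, 10)
  expect_equal(select_global_cutoff(curve, 1.0)$cutoff, 0)
  expect_error(select_global_cutoff(dplyr::filter(curve, cutoff > 0), 1.0),
               "maximum attainable TPR is 0.950")
})

test_that("selected cutoffs equal an exhaustive-scan oracle", {
  set.seed(417)
  for (rep in 1:25) {
    # all trues retrieved, so cutoff 0 always qualifies
    r <- random_results(n_queries = 10, p_unretrieved = 0)
    metric <- sample(c("percentile", "quotient"), 1)
    curve <- roc_sweep(r, metric)
    sel <- select_global_cutoff(curve, 0.90)
    # oracle: scan every grid point, keep the largest qualifying cutoff
    best <- -Inf
    for (i in seq_len(nrow(curve))) {
      if (!is.na(curve$tpr[i]) && curve$tpr[i] >= 0.90 &&
          curve$cutoff[i] > best) best <- curve$cutoff[i]
    }
    expect_equal(sel$cutoff, best)
  }
})

test_that("per-mixture metrics are additive and bracket the global rate", {
  set.seed(2024)
  r <- random_results(n_queries = 12, p_unretrieved = 0)
  cut <- 0.2
  per <- per_group_metrics(r, cut, "quotient")
  glob <- classify_at_cutoff(r, cut, "quotient")
  # pooled counts equal the elementwise sum of group counts
  expect_equal(sum(per$tp), glob$tp)
  expect_equal(sum(per$fp), glob$fp)
  expect_equal(sum(per$tn), glob$tn)
  expect_equal(sum(per$fn), glob$fn)
  # the global TPR is a weighted mean of group TPRs, so it is bracketed
  ok <- !is.na(per$tpr)
  expect_gte(glob$tpr, min(per$tpr[ok]))
  expect_lte(glob$tpr, max(per$tpr[ok]))
  # one group identical to the global set -> identical rates
  single <- per_group_metrics(one_query(), 0.13, "quotient")
  expect_equal(nrow(single), 1L)
  expect_equal(single$tpr, classify_at_cutoff(one_query(), 0.13,
                                              "quotient")$tpr)
  expect_equal(single$fpr, classify_at_cutoff(one_query(), 0.13,
                                              "quotient")$fpr)
})

test_that("groups with no true compounds report TPR as NA, not 0", {
  r <- one_query()
  extra <- dplyr::mutate(r, query_id = "Q2", mixture_id = "M2",
                         true_compound_id = NA_character_, is_true = FALSE)
  both <- dplyr::bind_rows(r, extra)
  attr(both, "queries") <- dplyr::bind_rows(
    attr(r, "queries"),
    tibble::tibble(query_id = "Q2", mixture_id = "M2", spectrum_ids = "s2",
                   true_compound_id = NA_character_, n_candidates = 3L,
                   true_retrieved = FALSE))
  per <- per_group_metrics(both, 0.5, "quotient")
  expect_true(is.na(per$tpr[per$mixture_id == "M2"]))
  expect_false(is.na(per$fpr[per$mixture_id == "M2"]))
})

test_that("top-k summaries count ranks and round percentages half-up", {
  mk <- function(ranks) {
    rows <- purrr::map_dfr(seq_along(ranks), function(i) {
      n <- max(ranks[i], 30)
      tibble::tibble(query_id = sprintf("Q%d", i), mixture_id = "M1",
                     true_compound_id = "t", compound_id =
                       ifelse(seq_len(n) == ranks[i], "t",
                              sprintf("d%d", seq_len(n))),
                     aggregate_score = 1, rank = seq_len(n),
                     percentile = 100 * (n - seq_len(n)) / (n - 1),
                     quotient = seq(1, 0.01, length.out = n),
                     is_true = seq_len(n) == ranks[i], n_candidates = n)
    })
    rows
  }
  s <- topk_summary(mk(c(1, 3, 25)))
  expect_equal(s$n_scored, 3L)
  expect_equal(s$hits_1, 1L)
  expect_equal(s$hits_5, 2L)
  expect_equal(s$hits_20, 2L)
  expect_equal(s$pct_5, 67)  # 66.7 rounds half-up to 67

  # random rank vectors equal a brute-force recount
  set.seed(3)
  for (rep in 1:10) {
    ranks <- sample(1:40, sample(3:12, 1), replace = TRUE)
    s <- topk_summary(mk(ranks))
    for (k in c(1, 5, 20)) {
      expect_equal(s[[paste0("hits_", k)]], sum(ranks <= k))
      expect_equal(s[[paste0("pct_", k)]],
                   floor(100 * sum(ranks <= k) / length(ranks) + 0.5))
    }
  }
})

test_that("round-half-up differs from banker's rounding where it should", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)   # base round() gives 2
  expect_equal(round_half_up(-0.4), 0)
  expect_equal(round_half_up(35.5), 36)
  expect_equal(pct_round(1, 3), 33)
  expect_equal(pct_round(2, 3), 67)
})

test_that("overlap report partitions the truth set", {
  out <- overlap_report(c("A", "B", "C"), ref_identified = c("A", "B"),
                        insilico_identified = c("B", "C"))
  expect_equal(out$count[out$category == "reference_only"], 1L)
  expect_equal(out$count[out$category == "both"], 1L)
  expect_equal(out$count[out$category == "insilico_only"], 1L)
  expect_equal(out$count[out$category == "neither"], 0L)

  none <- overlap_report(c("A", "B"), character(0), character(0))
  expect_equal(none$count[none$category == "neither"], 2L)

  expect_error(overlap_report(c("A"), c("Z"), character(0)), "Z")

  # random sets always partition the truth set
  set.seed(10)
  for (rep in 1:20) {
    truth <- sprintf("t%02d", 1:sample(5:30, 1))
    ref <- sample(truth, sample(0:length(truth), 1))
    sil <- sample(truth, sample(0:length(truth), 1))
    out <- overlap_report(truth, ref, sil)
    expect_equal(sum(out$count), length(truth))
  }
})

test_that("overlap eligibility tallies count reference/MS2 coverage", {
  el <- tibble::tibble(compound_id = c("A", "B", "C"),
                       in_reference_library = c(TRUE, TRUE, FALSE),
                       has_ms2 = c(TRUE, FALSE, TRUE))
  out <- overlap_report(c("A", "B", "C"), "A", "C", eligibility = el)
  tal <- attr(out, "eligibility")
  expect_equal(tal$n_truth, 3L)
  expect_equal(tal$n_in_reference, 2L)
  expect_equal(tal$n_with_ms2, 2L)
  expect_equal(tal$n_both, 1L)
})

test_that("tidy, glance and autoplot work on a calibration", {
  r <- random_results(n_queries = 8, p_unretrieved = 0)
  cal <- calibrate_cutoff(r, "quotient", min_tpr = 0.9)
  td <- generics::tidy(cal)
  expect_equal(nrow(td), 101L)
  gl <- generics::glance(cal)
  expect_equal(nrow(gl), 1L)
  expect_gte(gl$tpr, 0.9)
  expect_s3_class(ggplot2::autoplot(cal), "ggplot")
  expect_s3_class(plot_metric_distributions(r), "ggplot")
})
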