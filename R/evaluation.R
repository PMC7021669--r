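# Confusion counting, ROC sweeps, cutoff calibration, and summary reports.
#
# Each query contributes one true compound (the spiked substance) and a set
# of other candidates. At a cutoff on the percentile or quotient scale, a
# candidate is retained when its value is >= the cutoff (so cutoff 0
# retains everything): the true compound retained is a TP, dropped an FN;
# any other candidate retained is an FP, dropped a TN. A true compound the
# mass window never retrieved counts as FN at every cutoff.

metric_values <- function(results, metric) {
  metric <- match.arg(metric, c("percentile", "quotient"))
  v <- results[[metric]]
  if (is.null(v) || anyNA(v)) {
    stop("metric '", metric, "' missing or NA in results")
  }
  v
}

n_unretrieved_true <- function(results) {
  queries <- attr(results, "queries")
  if (!is.null(queries)) {
    sum(!is.na(queries$true_compound_id) & !queries$true_retrieved)
  } else {
    # Fallback for plain tables: queries whose candidate rows contain no
    # true compound. Queries with zero candidates are invisible here.
    tibble::as_tibble(results) |>
      dplyr::group_by(.data$query_id) |>
      dplyr::summarise(miss = !any(.data$is_true) &&
                         !all(is.na(.data$true_compound_id)),
                       .groups = "drop") |>
      dplyr::pull("miss") |>
      sum()
  }
}

#' Confusion counts at one cutoff
#'
#' @param results Candidate table from [match_spectra()] (or an equivalent
#'   data frame with `is_true` plus the metric column).
#' @param cutoff Retention threshold; candidates with metric value `>=`
#'   cutoff are retained.
#' @param metric `"percentile"` (0–100 scale) or `"quotient"` (0–1 scale).
#' @return One-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`.
#'   Rates with a zero denominator are `NA`.
#' @export
classify_at_cutoff <- function(results, cutoff,
                               metric = c("percentile", "quotient")) {
  metric <- match.arg(metric)
  v <- metric_values(results, metric)
  retained <- v >= cutoff
  is_true <- results$is_true
  tp <- sum(is_true & retained)
  fn <- sum(is_true & !retained) + n_unretrieved_true(results)
  fp <- sum(!is_true & retained)
  tn <- sum(!is_true & !retained)
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
}

#' Sweep cutoffs over the full metric range
#'
#' Evaluates [classify_at_cutoff()] on the standard 101-point grid —
#' percentile cutoffs 0, 1, 2, ..., 100 or quotient cutoffs 0, 0.01,
#' 0.02, ..., 1 — pooling counts over all queries. TPR and FPR are
#' non-increasing in the cutoff.
#'
#' @inheritParams classify_at_cutoff
#' @return Tibble of 101 rows (class `roc_curve`) with columns `cutoff`,
#'   `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`; the metric is kept in the
#'   `"metric"` attribute.
#' @export
roc_sweep <- function(results, metric = c("percentile", "quotient")) {
  metric <- match.arg(metric)
  grid <- if (metric == "percentile") seq(0, 100, by = 1) else
    seq(0, 1, by = 0.01)
  v <- metric_values(results, metric)
  vt <- v[results$is_true]
  vf <- v[!results$is_true]
  miss <- n_unretrieved_true(results)
  tp <- colSums(outer(vt, grid, ">="))
  fp <- colSums(outer(vf, grid, ">="))
  fn <- length(vt) - tp + miss
  tn <- length(vf) - fp
  curve <- tibble::tibble(
    cutoff = grid, tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    fpr = ifelse(fp + tn > 0, fp / (fp + tn), NA_real_)
  )
  attr(curve, "metric") <- metric
  class(curve) <- c("roc_curve", class(curve))
  curve
}

#' Most stringent cutoff meeting a TPR floor
#'
#' Picks the ROC point with the largest cutoff whose TPR is at least
#' `min_tpr` — the most stringent filter that still retains the required
#' fraction of true compounds.
#'
#' @param curve ROC tibble from [roc_sweep()].
#' @param min_tpr TPR floor in (0, 1] (default 0.90).
#' @return The selected one-row ROC tibble.
#' @export
select_global_cutoff <- function(curve, min_tpr = 0.90) {
  stopifnot(min_tpr > 0, min_tpr <= 1)
  ok <- !is.na(curve$tpr) & curve$tpr >= min_tpr
  if (!any(ok)) {
    stop(sprintf(
      "no cutoff reaches TPR %.3f (maximum attainable TPR is %.3f)",
      min_tpr, max(curve$tpr, na.rm = TRUE)))
  }
  sel <- curve[ok, , drop = FALSE]
  tibble::as_tibble(sel[which.max(sel$cutoff), , drop = FALSE])
}

#' FPR of an ROC curve at a given TPR level
#'
#' Reads the curve at the point where it crosses `tpr0`, linearly
#' interpolating in (FPR, TPR) between the bracketing cutoff grid points.
#' This is the curve-level quantity "FPR at TPR = x" independent of the
#' cutoff grid's quantization.
#'
#' @param curve ROC tibble from [roc_sweep()].
#' @param tpr0 TPR level to read the curve at (default 0.90).
#' @return Interpolated FPR in \[0, 1\].
#' @export
fpr_at_tpr <- function(curve, tpr0 = 0.90) {
  ok <- !is.na(curve$tpr) & !is.na(curve$fpr)
  tpr <- curve$tpr[ok]; fpr <- curve$fpr[ok]
  if (max(tpr) < tpr0) {
    stop(sprintf("curve never reaches TPR %.3f (max %.3f)", tpr0, max(tpr)))
  }
  if (min(tpr) >= tpr0) return(min(fpr[tpr >= tpr0]))
  # tpr is non-increasing in cutoff; walk to the crossing
  above <- which(tpr >= tpr0)
  i <- max(above)          # last grid point at or above the level
  j <- i + 1L              # first point below it
  if (tpr[i] == tpr0) return(fpr[i])
  w <- (tpr[i] - tpr0) / (tpr[i] - tpr[j])
  fpr[i] + w * (fpr[j] - fpr[i])
}

#' Calibrate a global cutoff from matching results
#'
#' Convenience wrapper: sweeps the ROC grid and selects the most stringent
#' cutoff with TPR at or above `min_tpr`. The returned object supports
#' [generics::tidy()] (the full curve), [generics::glance()] (the selected
#' operating point) and [ggplot2::autoplot()].
#'
#' @inheritParams classify_at_cutoff
#' @inheritParams select_global_cutoff
#' @return An object of class `roc_calibration`.
#' @export
calibrate_cutoff <- function(results, metric = c("percentile", "quotient"),
                             min_tpr = 0.90) {
  metric <- match.arg(metric)
  curve <- roc_sweep(results, metric)
  structure(
    list(curve = curve, selected = select_global_cutoff(curve, min_tpr),
         metric = metric, min_tpr = min_tpr),
    class = "roc_calibration"
  )
}

#' @export
print.roc_calibration <- function(x, ...) {
  cat("<roc_calibration> metric =", x$metric,
      sprintf("| cutoff %.3g at TPR %.3f (floor %.2f), FPR %.3f\n",
              x$selected$cutoff, x$selected$tpr, x$min_tpr, x$selected$fpr))
  invisible(x)
}

#' Per-mixture TPR and FPR at a fixed cutoff
#'
#' Applies a (typically globally calibrated) cutoff to each mixture's
#' queries separately. Rates with zero denominators (e.g. a mixture with
#' no true compounds) are `NA`, never 0.
#'
#' @inheritParams classify_at_cutoff
#' @return Tibble with one row per `mixture_id` and columns `tp`, `fp`,
#'   `tn`, `fn`, `tpr`, `fpr`.
#' @export
per_group_metrics <- function(results, cutoff,
                              metric = c("percentile", "quotient")) {
  metric <- match.arg(metric)
  queries <- attr(results, "queries")
  groups <- unique(results$mixture_id)
  if (!is.null(queries)) groups <- unique(c(groups, queries$mixture_id))
  purrr::map_dfr(sort(groups), function(g) {
    sub <- results[results$mixture_id == g, , drop = FALSE]
    if (!is.null(queries)) {
      attr(sub, "queries") <- queries[queries$mixture_id == g, , drop = FALSE]
    }
    dplyr::mutate(classify_at_cutoff(sub, cutoff, metric),
                  mixture_id = g, .before = 1)
  })
}

#' Top-k identification summary
#'
#' Counts queries whose true compound ranked within the top k candidates,
#' with integer percentages of the number of queries scored (round
#' half-up), plus the mean percentile and quotient of the true compounds.
#' Queries whose true compound was never retrieved are excluded from
#' `n_scored`.
#'
#' @param results Candidate table from [match_spectra()].
#' @param ks Integer vector of k values (default `c(1, 5, 20)`).
#' @return One-row tibble: `n_scored`, then `hits_<k>` and `pct_<k>` per
#'   k, `mean_percentile`, `mean_quotient`.
#' @export
topk_summary <- function(results, ks = c(1, 5, 20)) {
  qs <- query_summary(results)
  scored <- qs[!is.na(qs$true_rank), , drop = FALSE]
  n_scored <- nrow(scored)
  out <- tibble::tibble(n_scored = n_scored)
  for (k in ks) {
    hits <- sum(scored$true_rank <= k)
    out[[paste0("hits_", k)]] <- hits
    out[[paste0("pct_", k)]] <- if (n_scored > 0) pct_round(hits, n_scored)
      else NA_real_
  }
  out$mean_percentile <- if (n_scored > 0) mean(scored$true_percentile)
    else NA_real_
  out$mean_quotient <- if (n_scored > 0) mean(scored$true_quotient)
    else NA_real_
  out
}

#' Overlap between reference-library and in-silico identifications
#'
#' Partitions a de-duplicated set of truth compounds by which matching
#' route identified them as the top hit: reference library only, both,
#' in-silico only, or neither. Percentages are of the truth-set size,
#' rounded half-up. Optional per-compound eligibility flags are tallied
#' alongside (how many truth compounds are in the reference library, have
#' acquired MS2 data, or both).
#'
#' @param truth Character vector of truth compound ids (de-duplicated).
#' @param ref_identified,insilico_identified Character vectors of ids
#'   identified by each route; must be subsets of `truth`.
#' @param eligibility Optional data frame with columns `compound_id`,
#'   `in_reference_library`, `has_ms2` (logical).
#' @return Tibble with columns `category` (`reference_only`, `both`,
#'   `insilico_only`, `neither`), `count`, `pct`; eligibility tallies, when
#'   supplied, are in the `"eligibility"` attribute.
#' @export
overlap_report <- function(truth, ref_identified, insilico_identified,
                           eligibility = NULL) {
  truth <- unique(as.character(truth))
  ref_identified <- unique(as.character(ref_identified))
  insilico_identified <- unique(as.character(insilico_identified))
  stray <- setdiff(union(ref_identified, insilico_identified), truth)
  if (length(stray)) {
    stop("identified compounds outside the truth set: ",
         paste(stray, collapse = ", "))
  }
  in_ref <- truth %in% ref_identified
  in_sil <- truth %in% insilico_identified
  counts <- c(reference_only = sum(in_ref & !in_sil),
              both = sum(in_ref & in_sil),
              insilico_only = sum(!in_ref & in_sil),
              neither = sum(!in_ref & !in_sil))
  out <- tibble::tibble(category = names(counts),
                        count = as.integer(unname(counts)),
                        pct = unname(pct_round(counts, length(truth))))
  if (!is.null(eligibility)) {
    stopifnot(all(c("compound_id", "in_reference_library", "has_ms2") %in%
                    names(eligibility)))
    el <- eligibility[eligibility$compound_id %in% truth, , drop = FALSE]
    attr(out, "eligibility") <- tibble::tibble(
      n_truth = length(truth),
      n_in_reference = sum(el$in_reference_library),
      n_with_ms2 = sum(el$has_ms2),
      n_both = sum(el$in_reference_library & el$has_ms2)
    )
  }
  out
}
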