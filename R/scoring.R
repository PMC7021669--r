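# Dot-product spectral similarity and collision-energy score aggregation.
#
# Scoring follows the screening workflow: each experimental spectrum is
# compared to every candidate's predicted spectra (one per collision
# energy) with a cosine over greedily matched peak pairs inside a fixed
# fragment mass window, and per-CE scores are combined by one of three
# aggregation approaches before ranking.

#' Pair peaks of two spectra within a fragment mass window
#'
#' One-to-one greedy pairing: all cross pairs with `|mz_a - mz_b| <= window`
#' are considered in order of increasing absolute m/z difference (ties by
#' smaller index in `a`, then in `b`) and accepted when neither peak is
#' already used. Indices are 1-based.
#'
#' @param a,b Peak data frames (`mz`, `intensity`) sorted ascending by m/z.
#' @param window Fragment mass window in Da (default 0.02).
#' @return Tibble with columns `index_a`, `index_b`, `delta_mz`.
#' @export
match_peaks <- function(a, b, window = 0.02) {
  stopifnot(window > 0)
  na <- nrow(a); nb <- nrow(b)
  empty <- tibble::tibble(index_a = integer(0), index_b = integer(0),
                          delta_mz = numeric(0))
  if (na == 0L || nb == 0L) return(empty)
  d <- abs(outer(a$mz, b$mz, "-"))
  idx <- which(d <= window, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  delta <- d[idx]
  ord <- order(delta, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  delta <- delta[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(length(delta))
  for (k in seq_along(delta)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[k] <- TRUE
    }
  }
  tibble::tibble(index_a = as.integer(idx[keep, 1]),
                 index_b = as.integer(idx[keep, 2]),
                 delta_mz = delta[keep])
}

#' Dot-product similarity of two spectra
#'
#' Normalized dot product (cosine) over the matched peak pairs from
#' [match_peaks()], with the norms taken over *all* peaks of each spectrum
#' so unexplained peaks on either side lower the score:
#' \deqn{S = \frac{\sum_{(i,j)\,\mathrm{matched}} w_i^{(a)} w_j^{(b)}}
#'                {\sqrt{\sum_i (w_i^{(a)})^2}\,\sqrt{\sum_j (w_j^{(b)})^2}}}
#' with peak weights \eqn{w = I^{p}\, (m/z)^{q}}. The default weights
#' `(p = 1, q = 0)` give the plain cosine on raw intensities; the classic
#' `(0.6, 3)` weighting is available via the arguments. The score is
#' symmetric and lies in \[0, 1\].
#'
#' @inheritParams match_peaks
#' @param intensity_power,mz_power Peak weighting exponents (defaults 1, 0).
#' @return A similarity score in \[0, 1\]; 0 when no peaks match.
#' @examples
#' a <- tibble::tibble(mz = c(100, 200), intensity = c(3, 4))
#' b <- tibble::tibble(mz = c(100, 250), intensity = c(4, 3))
#' dot_product_score(a, b) # 12 / 25
#' @export
dot_product_score <- function(a, b, window = 0.02,
                              intensity_power = 1, mz_power = 0) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  wa <- a$intensity^intensity_power * a$mz^mz_power
  wb <- b$intensity^intensity_power * b$mz^mz_power
  norm_a <- sqrt(sum(wa^2)); norm_b <- sqrt(sum(wb^2))
  if (norm_a == 0 || norm_b == 0) {
    stop("spectrum with all-zero intensities cannot be scored")
  }
  pairs <- match_peaks(a, b, window)
  if (nrow(pairs) == 0L) return(0)
  sum(wa[pairs$index_a] * wb[pairs$index_b]) / (norm_a * norm_b)
}

#' Score one experimental spectrum against candidate compounds
#'
#' For every candidate, computes the dot-product score against each of its
#' predicted spectra (one per collision energy present in the library).
#' Collision energies with no library entry yield no row — absence, not a
#' zero score. Candidates with no predicted spectrum at any collision
#' energy are excluded and listed in the `"unscored"` attribute.
#'
#' @param query One spectrum: either a one-row spectra tibble or a peaks
#'   data frame.
#' @param candidates Compound tibble (e.g. from [candidates_by_mass()]).
#' @param library A `spectral_library`.
#' @inheritParams dot_product_score
#' @return Tibble with columns `compound_id`, `ce_insilico`, `score`;
#'   attribute `unscored` holds compound ids with no library spectra.
#' @export
score_candidates <- function(query, candidates, library, window = 0.02,
                             intensity_power = 1, mz_power = 0) {
  peaks <- if (is.data.frame(query) && "peaks" %in% names(query)) {
    stopifnot(nrow(query) == 1L)
    query$peaks[[1]]
  } else {
    query
  }
  entries <- library$entries[
    library$entries$compound_id %in% candidates$compound_id, , drop = FALSE]
  unscored <- setdiff(candidates$compound_id, entries$compound_id)
  if (length(unscored)) {
    rlang::inform(paste0("excluded from ranking (no predicted spectra): ",
                         paste(unscored, collapse = ", ")))
  }
  scores <- vapply(entries$peaks, function(p) {
    dot_product_score(peaks, p, window, intensity_power, mz_power)
  }, numeric(1))
  out <- tibble::tibble(
    compound_id = entries$compound_id,
    ce_insilico = entries$collision_energy,
    score = if (length(scores)) scores else numeric(0)
  )
  attr(out, "unscored") <- unscored
  out
}

#' Aggregate per-collision-energy scores
#'
#' Three aggregation approaches for combining the grid of
#' experimental-by-predicted collision-energy scores into one score per
#' candidate:
#' * **1** — keep only the score where the predicted CE equals the
#'   experimental CE (`ce_experimental`); candidates with no score at that
#'   CE are dropped (flagged absent, not scored 0).
#' * **2** — sum scores over all predicted CE levels for one experimental
#'   spectrum.
#' * **3** — sum over predicted CE levels, then over the experimental CE
#'   spectra of the same precursor (requires a `ce_experimental` column in
#'   `scores` spanning the acquisitions).
#' Absent grid cells contribute 0 to the sums of approaches 2 and 3.
#'
#' @param scores Tibble with columns `compound_id`, `ce_insilico`, `score`,
#'   and (for approach 3, or disambiguation in approach 1) a
#'   `ce_experimental` column.
#' @param approach 1, 2 or 3.
#' @param ce_experimental Experimental collision energy in volts; required
#'   for approach 1.
#' @return Tibble with columns `compound_id`, `aggregate_score`.
#' @export
aggregate_scores <- function(scores, approach, ce_experimental = NULL) {
  stopifnot(approach %in% 1:3)
  if (approach == 1) {
    if (is.null(ce_experimental)) {
      stop("approach 1 requires ce_experimental")
    }
    sel <- scores$ce_insilico == ce_experimental
    if ("ce_experimental" %in% names(scores)) {
      sel <- sel & scores$ce_experimental == ce_experimental
    }
    scores <- scores[sel, , drop = FALSE]
  }
  scores |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(aggregate_score = sum(.data$score), .groups = "drop")
}

#' Rank candidates and derive percentile and quotient
#'
#' Candidates are ranked by descending aggregate score (ties broken by
#' ascending `compound_id`). The quotient is each score divided by the
#' maximum score in the candidate set (all 0 when the maximum is 0); the
#' percentile is the linear rank position
#' `100 * (N - rank) / (N - 1)` (100 for a single candidate), which is
#' uniform over the candidate list by construction.
#'
#' @param scores Tibble with columns `compound_id`, `aggregate_score`.
#' @return Tibble ordered by rank with columns `compound_id`,
#'   `aggregate_score`, `rank`, `percentile`, `quotient`.
#' @export
rank_and_normalize <- function(scores) {
  stopifnot(nrow(scores) > 0)
  out <- scores[order(-scores$aggregate_score, scores$compound_id), ,
                drop = FALSE]
  n <- nrow(out)
  max_score <- out$aggregate_score[1]
  out$rank <- seq_len(n)
  out$percentile <- if (n == 1L) 100 else 100 * (n - out$rank) / (n - 1)
  out$quotient <- if (max_score > 0) out$aggregate_score / max_score else
    rep(0, n)
  tibble::as_tibble(out)
}
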