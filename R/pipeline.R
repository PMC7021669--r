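# End-to-end matching: experimental spectra in, ranked candidate tables out.

#' Match experimental spectra against a predicted-spectra library
#'
#' Runs the full screening chain for each query: neutral-mass candidate
#' retrieval in a ppm window (optionally restricted to the true compound's
#' molecular formula when a truth table is supplied), per-collision-energy
#' dot-product scoring, aggregation by the chosen approach, and
#' rank/percentile/quotient normalization.
#'
#' For approaches 1 and 2 every spectrum is its own query. For approach 3
#' the spectra of one precursor acquired at different collision energies
#' are combined into a single query: spectra are grouped within
#' `mixture_id` by precursor m/z (single linkage, `precursor_group_tol`).
#'
#' @param spectra A spectra tibble (see [read_mgf()]).
#' @param library A `spectral_library`.
#' @param approach Score aggregation approach, 1, 2 or 3 (default 3).
#' @param ppm_tol Candidate retrieval window in ppm (default 10).
#' @param formula_filter If `TRUE`, candidates are additionally required to
#'   share the true compound's molecular formula; requires `truth`.
#' @param truth Optional truth table with columns `spectrum_id`,
#'   `compound_id` (and optionally `mixture_id`) naming the spiked compound
#'   behind each spectrum.
#' @param window Fragment mass window in Da for peak matching (default
#'   0.02).
#' @param precursor_group_tol Precursor grouping tolerance in Da for
#'   approach 3 (default 0.01).
#' @param intensity_power,mz_power Peak weighting exponents passed to
#'   [dot_product_score()].
#' @return A tibble of scored candidates, one row per (query, candidate):
#'   `query_id`, `mixture_id`, `true_compound_id`, `compound_id`,
#'   `aggregate_score`, `rank`, `percentile`, `quotient`, `is_true`,
#'   `n_candidates`. The `"queries"` attribute tabulates every query,
#'   including those whose true compound was not retrieved by the mass
#'   window (counted as misses downstream).
#' @export
match_spectra <- function(spectra, library, approach = 3, ppm_tol = 10,
                          formula_filter = FALSE, truth = NULL,
                          window = 0.02, precursor_group_tol = 0.01,
                          intensity_power = 1, mz_power = 0) {
  stopifnot(approach %in% 1:3)
  if (formula_filter && is.null(truth)) {
    stop("formula_filter requires a truth table naming each true compound")
  }
  if (!is.null(truth)) {
    stopifnot(all(c("spectrum_id", "compound_id") %in% names(truth)))
    truth_map <- stats::setNames(as.character(truth$compound_id),
                                 truth$spectrum_id)
  } else {
    truth_map <- NULL
  }

  # Assemble queries: sets of spectrum indices scored together.
  if (approach == 3) {
    grp <- spectra |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$mixture_id) |>
      dplyr::mutate(.pg = single_linkage_groups(.data$precursor_mz,
                                                precursor_group_tol)) |>
      dplyr::ungroup()
    queries <- split(grp$.row,
                     paste0(grp$mixture_id, "/g",
                            formatC(grp$.pg, width = 4, flag = "0")))
  } else {
    queries <- split(seq_len(nrow(spectra)), spectra$spectrum_id)
  }

  res_rows <- vector("list", length(queries))
  q_rows <- vector("list", length(queries))
  qids <- names(queries)
  for (qi in seq_along(queries)) {
    rows <- queries[[qi]]
    sub <- spectra[rows, , drop = FALSE]
    true_id <- if (!is.null(truth_map)) {
      tid <- unique(stats::na.omit(truth_map[sub$spectrum_id]))
      if (length(tid) > 1L) {
        stop("query ", qids[qi], " maps to several true compounds: ",
             paste(tid, collapse = ", "))
      }
      if (length(tid)) tid else NA_character_
    } else {
      NA_character_
    }

    neutral <- mean(neutral_mass_from_precursor(sub$precursor_mz,
                                                sub$polarity))
    cands <- candidates_by_mass(library, neutral, ppm_tol)
    if (formula_filter && !is.na(true_id) &&
        true_id %in% library$compounds$compound_id) {
      target <- library$compounds$formula[
        library$compounds$compound_id == true_id]
      cands <- filter_by_formula(cands, target)
    }

    q_info <- tibble::tibble(
      query_id = qids[qi],
      mixture_id = sub$mixture_id[1],
      spectrum_ids = paste(sub$spectrum_id, collapse = ";"),
      true_compound_id = true_id,
      n_candidates = nrow(cands),
      true_retrieved = !is.na(true_id) && true_id %in% cands$compound_id
    )

    if (nrow(cands) > 0L) {
      per_ce <- purrr::map_dfr(seq_len(nrow(sub)), function(si) {
        sc <- score_candidates(sub[si, ], cands, library, window,
                               intensity_power, mz_power)
        sc$ce_experimental <- sub$collision_energy[si]
        sc
      })
      agg <- aggregate_scores(per_ce, approach,
                              ce_experimental = if (approach == 1)
                                sub$collision_energy[1] else NULL)
      if (nrow(agg) > 0L) {
        ranked <- rank_and_normalize(agg)
        res_rows[[qi]] <- dplyr::mutate(
          ranked,
          query_id = qids[qi],
          mixture_id = q_info$mixture_id,
          true_compound_id = true_id,
          is_true = !is.na(true_id) & .data$compound_id == true_id,
          n_candidates = nrow(ranked),
          .before = 1
        ) |> dplyr::relocate("compound_id", .after = "true_compound_id")
      }
      q_info$true_retrieved <- q_info$true_retrieved &&
        (!is.na(true_id) && true_id %in% agg$compound_id)
    }
    q_rows[[qi]] <- q_info
  }

  out <- dplyr::bind_rows(res_rows)
  attr(out, "queries") <- dplyr::bind_rows(q_rows)
  attr(out, "approach") <- approach
  class(out) <- c("ntamatch_results", class(out))
  out
}

#' Per-query summary of the true compound's outcome
#'
#' Collapses a candidate table to one row per query, with the true
#' compound's rank, percentile and quotient (`NA` when the true compound
#' was not retrieved or not scored).
#'
#' @param results Candidate table from [match_spectra()], or an equivalent
#'   data frame with the same columns.
#' @return Tibble with one row per query: `query_id`, `mixture_id`,
#'   `true_compound_id`, `n_candidates`, `true_rank`, `true_percentile`,
#'   `true_quotient`.
#' @export
query_summary <- function(results) {
  queries <- attr(results, "queries")
  per_q <- tibble::as_tibble(results) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      mixture_id = dplyr::first(.data$mixture_id),
      true_compound_id = dplyr::first(.data$true_compound_id),
      n_candidates = dplyr::first(.data$n_candidates),
      true_rank = if (any(.data$is_true)) .data$rank[.data$is_true][1]
        else NA_integer_,
      true_percentile = if (any(.data$is_true))
        .data$percentile[.data$is_true][1] else NA_real_,
      true_quotient = if (any(.data$is_true))
        .data$quotient[.data$is_true][1] else NA_real_,
      .groups = "drop"
    )
  if (!is.null(queries)) {
    missing_q <- queries[!queries$query_id %in% per_q$query_id, , drop = FALSE]
    if (nrow(missing_q)) {
      per_q <- dplyr::bind_rows(
        per_q,
        tibble::tibble(query_id = missing_q$query_id,
                       mixture_id = missing_q$mixture_id,
                       true_compound_id = missing_q$true_compound_id,
                       n_candidates = missing_q$n_candidates,
                       true_rank = NA_integer_,
                       true_percentile = NA_real_,
                       true_quotient = NA_real_)
      )
    }
  }
  dplyr::arrange(per_q, .data$query_id)
}
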