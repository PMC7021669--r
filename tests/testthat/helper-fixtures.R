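# Shared fixture builders and independent oracles. Oracles deliberately use
# naive, loop-based code paths distinct from the package internals.

pk <- function(mz, intensity = rep(1, length(mz))) {
  tibble::tibble(mz = mz, intensity = intensity)
}

# Write MGF text to a temp file and return its path.
mgf_file <- function(...) {
  path <- withr::local_tempfile(fileext = ".mgf",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

# A small hand-built library: three compounds, full CE coverage for A and
# B, compound "C_nolib" has a record but no spectra.
tiny_library <- function() {
  compounds <- tibble::tibble(
    compound_id = c("A", "B", "C_nolib"),
    formula = c("C10H12N2O", "C9H8N4O", "C10H12N2O"),
    monoisotopic_mass = c(300.1338, 300.1400, 310.0),
    name = NA_character_
  )
  entries <- tidyr::expand_grid(compound_id = c("A", "B"),
                                collision_energy = c(10, 20, 40))
  set.seed(42)
  entries$peaks <- lapply(seq_len(nrow(entries)), function(i) {
    pk(sort(runif(5, 50, 280)), runif(5, 10, 1000))
  })
  spectral_library(compounds, entries)
}

# Random candidate-result fixture for evaluation tests: n_queries queries,
# each with its own candidate list, percentile/quotient computed by
# rank_and_normalize. Some queries optionally miss their true compound.
random_results <- function(n_queries = 5, max_candidates = 8,
                           p_unretrieved = 0.15) {
  qrows <- list()
  rows <- list()
  for (q in seq_len(n_queries)) {
    n <- sample(seq_len(max_candidates), 1)
    scores <- tibble::tibble(
      compound_id = sprintf("q%d_c%d", q, seq_len(n)),
      aggregate_score = round(runif(n, 0, 3), 3)
    )
    ranked <- rank_and_normalize(scores)
    unret <- runif(1) < p_unretrieved
    true_id <- if (unret) sprintf("q%d_missing", q) else
      sample(ranked$compound_id, 1)
    qid <- sprintf("Q%03d", q)
    mix <- sprintf("M%d", 1 + (q %% 3))
    rows[[q]] <- dplyr::mutate(
      ranked, query_id = qid, mixture_id = mix, true_compound_id = true_id,
      is_true = .data$compound_id == true_id, n_candidates = n, .before = 1)
    qrows[[q]] <- tibble::tibble(
      query_id = qid, mixture_id = mix, spectrum_ids = qid,
      true_compound_id = true_id, n_candidates = n, true_retrieved = !unret)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "queries") <- dplyr::bind_rows(qrows)
  out
}

# Independent confusion recount: plain loops, no package code.
oracle_confusion <- function(results, cutoff, metric) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(results))) {
    retained <- results[[metric]][i] >= cutoff
    if (results$is_true[i]) {
      if (retained) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (retained) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  q <- attr(results, "queries")
  fn <- fn + sum(!q$true_retrieved)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Independent greedy-minimal matching oracle: repeatedly take the smallest
# in-window |delta| from the full pair matrix (ties: smaller row, then
# column), masking used rows/columns. Exhaustive over all pairs at every
# step.
oracle_match <- function(a, b, window) {
  d <- abs(outer(a$mz, b$mz, "-"))
  d[d > window] <- Inf
  out <- NULL
  while (any(is.finite(d))) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
      if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    }
    out <- rbind(out, c(bi, bj))
    d[bi, ] <- Inf
    d[, bj] <- Inf
  }
  out
}

# Independent cosine oracle built on the matching oracle.
oracle_cosine <- function(a, b, window) {
  m <- oracle_match(a, b, window)
  num <- if (is.null(m)) 0 else
    sum(a$intensity[m[, 1]] * b$intensity[m[, 2]])
  num / (sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2)))
}
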