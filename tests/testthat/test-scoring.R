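test_that("peak pairing is one-to-one, in-window, greedy by |delta|", {
  a <- pk(c(100.00, 200.00))
  b <- pk(c(100.01, 300.00))
  m <- match_peaks(a, b, 0.02)
  expect_equal(m$index_a, 1L)
  expect_equal(m$index_b, 1L)

  # identical lists -> full diagonal
  x <- pk(c(50, 60, 70))
  expect_equal(match_peaks(x, x, 0.02)$index_a, 1:3)
  expect_equal(match_peaks(x, x, 0.02)$index_b, 1:3)

  # the closer of two competing peaks wins
  a2 <- pk(c(100.000, 100.015))
  b2 <- pk(100.010)
  m2 <- match_peaks(a2, b2, 0.02)
  expect_equal(m2$index_a, 2L)
  expect_equal(m2$index_b, 1L)

  # no pairs outside the window
  expect_equal(nrow(match_peaks(pk(100), pk(100.05), 0.02)), 0L)
})

test_that("peak pairing equals the exhaustive greedy oracle (<= 6 peaks)", {
  set.seed(123)
  for (rep in 1:300) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    # cramped m/z range so windows overlap and compete
    a <- normalize_peaks(pk(runif(na, 100, 100.08), runif(na, 1, 10)))
    b <- normalize_peaks(pk(runif(nb, 100, 100.08), runif(nb, 1, 10)))
    if (nrow(a) == 0 || nrow(b) == 0) next
    got <- match_peaks(a, b, 0.02)
    want <- oracle_match(a, b, 0.02)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want[, 1]), , drop = FALSE]
      ord <- order(got$index_a)
      expect_equal(got$index_a[ord], want[, 1])
      expect_equal(got$index_b[ord], want[, 2])
    }
  }
})

test_that("dot product matches hand-computed cosines", {
  a <- pk(c(100, 200), c(3, 4))
  b <- pk(c(100, 250), c(4, 3))
  expect_equal(dot_product_score(a, b), 0.48, tolerance = 1e-12)
  expect_equal(dot_product_score(b, a), 0.48, tolerance = 1e-12)

  expect_equal(dot_product_score(a, a), 1.0, tolerance = 1e-12)
  expect_equal(dot_product_score(pk(100, 5), pk(300, 5)), 0)
  # proportional intensities across a full pairing -> exactly 1
  expect_equal(dot_product_score(pk(c(50, 60, 70), c(1, 2, 2)),
                                 pk(c(50, 60, 70), c(2, 4, 4))), 1,
               tolerance = 1e-12)
  expect_error(dot_product_score(pk(100, 5),
                                 tibble::tibble(mz = 100, intensity = 0)),
               "all-zero")
})

test_that("unmatched peaks penalize the score through the norms", {
  a <- pk(c(100, 200), c(1, 1))
  b3 <- pk(c(100, 200, 300), c(1, 1, 1))
  expect_equal(dot_product_score(a, b3), 2 / sqrt(6), tolerance = 1e-12)
  b2 <- pk(c(100, 200), c(1, 1))
  expect_gt(dot_product_score(a, b2), dot_product_score(a, b3))
})

test_that("scores agree with an independent cosine oracle on random pairs", {
  set.seed(321)
  for (rep in 1:100) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- normalize_peaks(pk(runif(na, 100, 100.1), runif(na, 1, 100)))
    b <- normalize_peaks(pk(runif(nb, 100, 100.1), runif(nb, 1, 100)))
    if (nrow(a) == 0 || nrow(b) == 0) next
    s <- dot_product_score(a, b, 0.02)
    expect_equal(s, oracle_cosine(a, b, 0.02), tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
    expect_equal(s, dot_product_score(b, a, 0.02), tolerance = 1e-12)
  }
})

test_that("shrinking the window never increases the matched-pair count", {
  set.seed(55)
  for (rep in 1:40) {
    a <- normalize_peaks(pk(runif(6, 100, 100.1), runif(6, 1, 10)))
    b <- normalize_peaks(pk(runif(6, 100, 100.1), runif(6, 1, 10)))
    counts <- vapply(c(0.05, 0.02, 0.01, 0.005, 0.001),
                     function(w) nrow(match_peaks(a, b, w)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("score_candidates scores every library CE and flags absences", {
  lib <- tiny_library()
  query <- spectra_tibble("q1", 301.141076, "positive", 20,
                          list(lib$entries$peaks[[2]]))
  cands <- lib$compounds
  expect_message(sc <- score_candidates(query, cands, lib), "C_nolib")
  expect_equal(sort(unique(sc$compound_id)), c("A", "B"))
  expect_equal(nrow(sc), 6L)  # 2 compounds x 3 CEs
  expect_equal(attr(sc, "unscored"), "C_nolib")
  # values equal individual dot products
  for (i in seq_len(nrow(sc))) {
    expect_equal(
      sc$score[i],
      dot_product_score(query$peaks[[1]],
                        library_spectrum(lib, sc$compound_id[i],
                                         sc$ce_insilico[i])),
      tolerance = 1e-12)
  }
})

test_that("aggregation selects or sums per approach", {
  grid <- tibble::tibble(compound_id = "A",
                         ce_insilico = c(10, 20, 40),
                         score = c(0.2, 0.5, 0.1))
  expect_equal(aggregate_scores(grid, 1, 20)$aggregate_score, 0.5)
  expect_equal(aggregate_scores(grid, 2)$aggregate_score, 0.8)
  # approach 1 with no matching-CE score -> candidate absent, not zero
  expect_equal(nrow(aggregate_scores(grid[grid$ce_insilico != 20, ], 1, 20)),
               0L)
  # approach 3: per-experimental-CE sums 0.8/0.6/0.3 -> 1.7
  g3 <- tibble::tibble(
    compound_id = "A",
    ce_experimental = rep(c(10, 20, 40), each = 3),
    ce_insilico = rep(c(10, 20, 40), 3),
    score = c(0.5, 0.2, 0.1, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1))
  expect_equal(aggregate_scores(g3, 3)$aggregate_score, 1.7)
})

test_that("approach algebra holds on random full 3x3 grids", {
  set.seed(88)
  ces <- c(10, 20, 40)
  for (rep in 1:50) {
    n_cand <- sample(1:6, 1)
    grid <- tidyr::expand_grid(compound_id = sprintf("c%d", seq_len(n_cand)),
                               ce_experimental = ces, ce_insilico = ces)
    grid$score <- runif(nrow(grid))
    # approach 2 = sum of approach-1 selections over CE_in_silico
    for (ce in ces) {
      sub <- grid[grid$ce_experimental == ce, ]
      # approach 1 picks exactly the matching-CE cell
      a1 <- aggregate_scores(sub, 1, ce)
      cell <- sub[sub$ce_insilico == ce, ]
      expect_equal(a1$aggregate_score[order(a1$compound_id)],
                   cell$score[order(cell$compound_id)], tolerance = 1e-12)
      a2 <- aggregate_scores(sub, 2)
      a1_sum <- purrr::map_dfr(ces, function(cei) {
        dplyr::mutate(aggregate_scores(
          sub[sub$ce_insilico == cei, ], 2), ce = cei)
      }) |>
        dplyr::group_by(compound_id) |>
        dplyr::summarise(s = sum(aggregate_score))
      expect_equal(a2$aggregate_score,
                   a1_sum$s[match(a2$compound_id, a1_sum$compound_id)],
                   tolerance = 1e-12)
    }
    # approach 3 = sum of approach-2 aggregates over CE_experimental
    a3 <- aggregate_scores(grid, 3)
    a2_sum <- purrr::map_dfr(ces, function(ce) {
      aggregate_scores(grid[grid$ce_experimental == ce, ], 2)
    }) |>
      dplyr::group_by(compound_id) |>
      dplyr::summarise(s = sum(aggregate_score))
    expect_equal(a3$aggregate_score,
                 a2_sum$s[match(a3$compound_id, a2_sum$compound_id)],
                 tolerance = 1e-12)
  }
})

test_that("ranking, quotient and percentile follow their definitions", {
  r <- rank_and_normalize(tibble::tibble(compound_id = c("A", "B"),
                                         aggregate_score = c(0.5, 0.25)))
  expect_equal(r$rank, c(1L, 2L))
  expect_equal(r$quotient, c(1, 0.5))
  expect_equal(r$percentile, c(100, 0))

  single <- rank_and_normalize(tibble::tibble(compound_id = "A",
                                              aggregate_score = 0.2))
  expect_equal(single$rank, 1L)
  expect_equal(single$quotient, 1)
  expect_equal(single$percentile, 100)

  # all-zero scores -> all quotients 0, ties broken by id
  zeros <- rank_and_normalize(tibble::tibble(compound_id = c("b", "a"),
                                             aggregate_score = c(0, 0)))
  expect_equal(zeros$compound_id, c("a", "b"))
  expect_equal(zeros$quotient, c(0, 0))
})

test_that("percentiles match a brute-force sort oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    scores <- tibble::tibble(compound_id = sprintf("c%02d", sample(n)),
                             aggregate_score = round(runif(n), 3))
    r <- rank_and_normalize(scores)
    # oracle: position in a (score desc, id asc) sort
    ord <- order(-scores$aggregate_score, scores$compound_id)
    oracle_rank <- match(r$compound_id, scores$compound_id[ord])
    expect_equal(r$rank, oracle_rank)
    expect_equal(r$percentile, 100 * (n - oracle_rank) / (n - 1),
                 tolerance = 1e-12)
    expect_equal(r$quotient[1], ifelse(r$aggregate_score[1] > 0, 1, 0))
  }
})

test_that("quotients are invariant to scaling the experimental spectrum", {
  lib <- tiny_library()
  set.seed(61)
  base <- pk(sort(runif(8, 50, 280)), runif(8, 10, 1000))
  scaled <- dplyr::mutate(base, intensity = intensity * 37.5)
  score_one <- function(peaks) {
    sc <- suppressMessages(
      score_candidates(peaks, lib$compounds[1:2, ], lib))
    rank_and_normalize(aggregate_scores(sc, 2))
  }
  r1 <- score_one(base)
  r2 <- score_one(scaled)
  expect_equal(r1$quotient, r2$quotient, tolerance = 1e-12)
  expect_equal(r1$rank, r2$rank)
})
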