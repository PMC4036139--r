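test_that("run collapsing produces differing adjacent tokens with exact spans", {
  tok <- collapse_runs(c(2, 2, 7, 7, 7, 2))
  expect_equal(tok$token, c(2, 7, 2))
  expect_equal(tok$start, c(1L, 3L, 6L))
  expect_equal(tok$end, c(2L, 5L, 6L))

  expect_equal(nrow(collapse_runs(rep(4, 9))), 1L)

  # lossless round trip on random sequences
  withr::with_seed(201, {
    for (rep in 1:5) {
      lab <- sample(1:4, 150, TRUE)
      tok <- collapse_runs(lab)
      back <- unlist(mapply(function(t, s, e) rep(t, e - s + 1),
                            tok$token, tok$start, tok$end))
      expect_equal(back, lab)
      expect_true(all(diff(tok$token) != 0 | diff(tok$segment) != 0))
    }
  })
})

test_that("transition probabilities match hand counts and normalize", {
  m <- transition_matrix(list(c(1, 2, 1, 2, 1)))
  expect_equal(m$P["1", "2"], 1)
  expect_equal(m$P["2", "1"], 1)
  expect_equal(unname(m$stationary), c(3, 2) / 5)

  m2 <- transition_matrix(list(c(1, 2, 1, 3)))
  expect_equal(m2$P["1", "2"], 0.5)
  expect_equal(m2$P["1", "3"], 0.5)
  expect_true("3" %in% m2$dangling)

  withr::with_seed(202, {
    tok <- collapse_runs(sample(1:5, 400, TRUE))
    m3 <- transition_matrix(tok)
    rs <- rowSums(m3$P)
    expect_equal(unname(rs[is.finite(rs)]), rep(1, sum(is.finite(rs))))
    expect_equal(sum(m3$stationary), 1)
  })
})

test_that("best-first SPM enumeration equals exhaustive enumeration", {
  # deterministic cycle: the unrolled cycle is the single top sequence
  cyc <- transition_matrix(list(rep(c(1, 2, 3), 20)))
  top <- enumerate_top_spms(cyc, n_transitions = 5, top_n = 5)
  expect_equal(top$sequence[1], "1-2-3-1-2-3")
  expect_equal(top$probability[1], unname(cyc$stationary["1"]), tolerance = 1e-12)

  withr::with_seed(203, {
    for (m_size in c(3, 4, 6)) {
      lab <- sample(seq_len(m_size), 600, TRUE)
      model <- transition_matrix(collapse_runs(lab))
      for (nt in 2:3) {
        got <- enumerate_top_spms(model, n_transitions = nt, top_n = 5)
        want <- oracle_spms(model, nt)
        expect_equal(got$sequence, head(want$sequence, 5))
        expect_equal(got$probability, head(want$probability, 5),
                     tolerance = 1e-12)
        expect_true(all(got$probability <= 1))
      }
    }
  })

  # default parameters: five transitions means six tokens
  lab <- withr::with_seed(204, sample(1:6, 2000, TRUE))
  model <- transition_matrix(collapse_runs(lab))
  top <- enumerate_top_spms(model)
  expect_equal(lengths(top$tokens), rep(6L, nrow(top)))
  expect_equal(nrow(top), 100L)
  expect_error(enumerate_top_spms(model, n_transitions = 0), "n_transitions")
})

test_that("mirror and composition merging conserve probability", {
  seqs <- data.frame(rank = 1:3,
                     sequence = c("2-7-2-7-2-7", "2-8-2-8-2-8", "2-7-2-8-2-7"),
                     probability = c(0.3, 0.2, 0.1))
  seqs$tokens <- list(c(2, 7, 2, 7, 2, 7), c(2, 8, 2, 8, 2, 8),
                      c(2, 7, 2, 8, 2, 7))
  class(seqs) <- c("spm_sequences", "data.frame")
  cat <- reduce_spms(seqs, cbind(pm_a = 7, pm_b = 8))
  expect_equal(nrow(cat), 1L)  # identical after mirror collapse + composition
  expect_equal(cat$probability, 0.6)
  expect_equal(cat$canonical, "2-7/8-2-7/8-2-7/8")
  expect_equal(cat$n_members, 3L)

  # same composition, different fine structure: merged
  s2 <- data.frame(rank = 1:2, sequence = c("1-1-1-2-1-1", "1-1-2-1-1-1"),
                   probability = c(0.05, 0.04))
  s2$tokens <- list(c(1, 1, 1, 2, 1, 1), c(1, 1, 2, 1, 1, 1))
  class(s2) <- c("spm_sequences", "data.frame")
  cat2 <- reduce_spms(s2, NULL)
  expect_equal(nrow(cat2), 1L)
  expect_equal(cat2$canonical, "1-1-1-2-1-1")  # highest-probability member

  # different multisets stay separate
  s3 <- data.frame(rank = 1:2, sequence = c("1-2-1-2", "2-1-1-1"),
                   probability = c(0.05, 0.04))
  s3$tokens <- list(c(1, 2, 1, 2), c(2, 1, 1, 1))
  class(s3) <- c("spm_sequences", "data.frame")
  expect_equal(nrow(reduce_spms(s3, NULL)), 2L)
})

test_that("occurrence matching agrees with a brute-force window scan", {
  entry <- list(canonical_tokens = c("2", "7/8", "2"))
  pairs <- cbind(pm_a = 7, pm_b = 8)

  lab <- c(1, 2, 7, 2, 2, 1, 2, 8, 2)
  occ <- match_occurrences(lab, entry, pairs)
  expect_equal(occ$start, c(2L, 7L))
  expect_equal(occ$end, c(5L, 9L))

  expect_equal(nrow(match_occurrences(c(1, 2, 1, 2), entry, pairs)), 0L)

  withr::with_seed(205, {
    lab <- sample(c(1, 2, 7, 8), 300, TRUE)
    occ <- match_occurrences(lab, entry, pairs)
    # oracle: regex-style scan over the collapsed pooled token string
    tok <- collapse_runs(lab)
    pooled <- ifelse(tok$token %in% c(7, 8), "7/8", as.character(tok$token))
    hits <- which(vapply(seq_len(length(pooled) - 2), function(w)
      all(pooled[w:(w + 2)] == entry$canonical_tokens), logical(1)))
    expect_equal(occ$start, tok$start[hits])
    expect_equal(occ$end, tok$end[hits + 2])
  })
})

test_that("condition contrasts are zero for identical data and signed otherwise", {
  entry_cat <- data.frame(entry = 1L, canonical = "2-7/8-2")
  entry_cat$canonical_tokens <- list(c("2", "7/8", "2"))
  pairs <- cbind(pm_a = 7, pm_b = 8)

  lab <- withr::with_seed(206, sample(c(1, 2, 7, 8), 400, TRUE))
  cc <- condition_contrast(entry_cat, lab, lab, pairs)
  expect_equal(cc$diff, 0)

  only_b <- rep(1, 400)
  cc2 <- condition_contrast(entry_cat, lab, only_b, pairs)
  expect_equal(cc2$diff, cc2$freq_a)
  expect_gt(cc2$freq_a, 0)

  expect_error(condition_contrast(entry_cat, lab, integer(0), pairs), "empty")
})
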