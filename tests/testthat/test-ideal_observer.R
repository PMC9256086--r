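test_that("posterior-predictive probabilities follow the add-one rule", {
  s0 <- dirichlet_counts(3)
  expect_equal(predictive_distribution(s0), rep(1 / 3, 3))
  expect_equal(predictive_distribution(dirichlet_counts(3, counts = c(1, 0, 0))),
               c(1 / 2, 1 / 4, 1 / 4))
  expect_equal(predictive_distribution(dirichlet_counts(3, counts = c(2, 1, 0))),
               c(1 / 2, 1 / 3, 1 / 6))
  expect_error(dirichlet_counts(3, alpha = 0), "alpha")
  expect_error(dirichlet_counts(3, counts = c(-1, 0, 0)), "counts")
})

test_that("update has value semantics and composes by induction", {
  s0 <- dirichlet_counts(3)
  s1 <- update_counts(s0, 1)
  expect_equal(s1$counts, c(0L, 1L, 0L))
  expect_equal(s0$counts, c(0L, 0L, 0L))  # original untouched
  s <- s0
  for (i in 1:7) s <- update_counts(s, 0)
  expect_equal(s$counts, c(7L, 0L, 0L))
  expect_error(update_counts(s0, 3), "observed")
})

test_that("unigram surprisal matches hand-counted prefixes", {
  # first event: flat prior over 3 objects
  expect_equal(unigram_surprisal_trace(0L, n_objects = 3)$surprisal_bits,
               log2(3))
  expect_equal(unigram_surprisal_trace(c(0, 0), n_objects = 3)$surprisal_bits[2],
               1.0)
  # A A B C, hand-counted: 1/3, 2/4, 1/5, 1/6
  expect_equal(unigram_surprisal_trace(c(0, 0, 1, 2),
                                       n_objects = 3)$surprisal_bits,
               -log2(c(1 / 3, 2 / 4, 1 / 5, 1 / 6)))
  expect_equal(oracle_unigram(c(0, 0, 1, 2)),
               -log2(c(1 / 3, 2 / 4, 1 / 5, 1 / 6)))
})

test_that("transitional surprisal conditions on the preceding event", {
  tr <- transitional_surprisal_trace(c(0, 1, 0, 1), n_objects = 3)
  expect_equal(tr$surprisal_bits[1], log2(3))   # no predecessor: flat prior
  expect_equal(tr$surprisal_bits[4], 1.0)       # one 0->1 transition seen
  # an all-A sequence: p(event t) = (t-2+1)/(t-2+3), strictly decreasing
  n <- 12
  tr2 <- transitional_surprisal_trace(rep(0L, n), n_objects = 3)
  t_idx <- 2:n
  expect_equal(tr2$surprisal_bits[t_idx],
               -log2((t_idx - 2 + 1) / (t_idx - 2 + 3)))
  expect_true(all(diff(tr2$surprisal_bits[t_idx]) < 0))
})

test_that("sequential traces equal the brute-force prefix-recount oracle", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      ids <- sample(0:2, n, replace = TRUE)
      expect_equal(unigram_surprisal_trace(ids, n_objects = 3)$surprisal_bits,
                   oracle_unigram(ids), tolerance = 1e-12)
      expect_equal(
        transitional_surprisal_trace(ids, n_objects = 3)$surprisal_bits,
        oracle_transitional(ids), tolerance = 1e-12)
    }
  })
})

test_that("predictive distributions stay normalized along any sequence", {
  withr::with_seed(8, {
    s <- dirichlet_counts(3)
    for (i in 1:200) {
      expect_lt(abs(sum(predictive_distribution(s)) - 1), 1e-12)
      expect_true(all(predictive_distribution(s) > 0))
      s <- update_counts(s, sample(0:2, 1))
    }
  })
})

test_that("observing an object strictly raises its predictive probability", {
  # familiarity monotonicity: each observation of object o strictly
  # increases p(o) relative to the state that scored it, for any history
  withr::with_seed(13, {
    for (i in 1:20) {
      ids <- sample(0:2, 40, replace = TRUE)
      st <- dirichlet_counts(3)
      for (o in ids) {
        p_before <- predictive_distribution(st)[o + 1]
        st <- update_counts(st, o)
        expect_gt(predictive_distribution(st)[o + 1], p_before)
      }
    }
  })
  # and in an uninterrupted run of one object, surprisal strictly falls
  run <- unigram_surprisal_trace(rep(0L, 10), n_objects = 3)$surprisal_bits
  expect_true(all(diff(run) < 0))
})

test_that("unigram surprisal is exchangeable in the prefix", {
  withr::with_seed(17, {
    for (i in 1:20) {
      ids <- sample(0:2, 25, replace = TRUE)
      perm <- c(sample(1:24), 25)     # permute the prefix of the last event
      s_orig <- unigram_surprisal_trace(ids, n_objects = 3)$surprisal_bits
      s_perm <- unigram_surprisal_trace(ids[perm],
                                        n_objects = 3)$surprisal_bits
      expect_equal(s_perm[25], s_orig[25], tolerance = 1e-12)
    }
  })
})

test_that("mean unigram surprisal approaches the source cross-entropy", {
  q <- c(0.5, 0.3, 0.2)
  s <- random_sequence(5000, seed = 23, weights = q)
  m <- mean(unigram_surprisal_trace(s)$surprisal_bits)
  expect_lt(abs(m - (-sum(q * log2(q)))), 0.05)
})

test_that("score_sequence_set scores every sequence independently", {
  set <- generate_sequence_set(n_sequences = 6, length = 10,
                               pool_size = 15, seed = 3)
  tr <- score_sequence_set(set)
  expect_equal(nrow(tr), 60)
  expect_setequal(unique(tr$sequence_id),
                  vapply(set$sequences, function(s) s$sequence_id, ""))
  # purity: same input, same trace; and per-sequence traces match the
  # standalone per-event computation
  tr2 <- score_sequence_set(set)
  expect_identical(tr, tr2)
  one <- tr[tr$sequence_id == "seq003", ]
  expect_equal(one$unigram_surprisal_bits,
               unigram_surprisal_trace(set$sequences[[3]])$surprisal_bits)
  expect_equal(one$transitional_surprisal_bits,
               transitional_surprisal_trace(set$sequences[[3]])$surprisal_bits)
  # surprisal = -log2(p) for every entry
  expect_equal(one$unigram_surprisal_bits, -log2(one$unigram_p))
})

test_that("surprisal CSV export round-trips", {
  set <- generate_sequence_set(n_sequences = 3, length = 8,
                               pool_size = 6, seed = 4)
  tr <- score_sequence_set(set)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surprisal(tr, path)
  back <- read_surprisal(path)
  expect_equal(back$unigram_surprisal_bits, tr$unigram_surprisal_bits)
  expect_equal(back$sequence_id, tr$sequence_id)
})
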