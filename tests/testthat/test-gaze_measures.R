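g <- fixed_geometry()
# object k sits at box k (identity binding): 0 -> (400,300),
# 1 -> (1400,300), 2 -> (900,850); filler (400,850) is outside every AOI
seq6 <- make_sequence(c(0, 1, 2, 0, 1, 2), g, id = "fix6")

test_that("in_aoi is boundary-inclusive and ignores invalid samples", {
  expect_true(in_aoi(400, 300, TRUE, c(400, 300), 150))
  expect_true(in_aoi(550, 300, TRUE, c(400, 300), 150))   # exactly r away
  expect_false(in_aoi(551, 300, TRUE, c(400, 300), 150))
  expect_false(in_aoi(400, 300, FALSE, c(400, 300), 150)) # track loss
})

test_that("compute_rt returns latency to first AOI entry in the window", {
  # gaze jumps to object 0's box 230 ms after its pop-up at t = 0
  tr <- fixture_trial(seq6, list(list(t = c(230, 700), x = 400, y = 300)))
  expect_equal(compute_rt(tr, 0), 230)
  expect_true(is.na(compute_rt(tr, 1)))      # never fixates object 1
  # already inside the AOI at onset: RT = 0
  tr0 <- fixture_trial(seq6, list(list(t = c(1400, 1600), x = 1400, y = 300)))
  expect_equal(compute_rt(tr0, 1), 0)
  # entries outside the event window don't count
  trx <- fixture_trial(seq6, list(list(t = c(1600, 1700), x = 400, y = 300)))
  expect_true(is.na(compute_rt(trx, 0)))
  expect_error(compute_rt(tr, 6), "outside")
  expect_error(compute_rt(tr, -1), "outside")
})

test_that("compute_rt can demand a minimum dwell", {
  tr <- fixture_trial(seq6, list(
    list(t = c(100, 104), x = 400, y = 300),    # 5 ms flicker
    list(t = c(400, 520), x = 400, y = 300)))   # real fixation
  expect_equal(compute_rt(tr, 0), 100)
  expect_equal(compute_rt(tr, 0, min_dwell_ms = 50), 400)
})

test_that("predictive looking is defined only on first appearances after event 0", {
  # event 2 is object 2's first appearance; gaze is on its box at onset-1
  tr <- fixture_trial(seq6, list(list(t = c(2900, 2999), x = 900, y = 850)))
  expect_true(compute_predictive_look(tr, 2))
  expect_true(is.na(compute_predictive_look(tr, 5)))  # repeat appearance
  expect_true(is.na(compute_predictive_look(tr, 0)))  # no pre-onset sample
  # gaze elsewhere (filler) in the pre-onset window -> FALSE
  tr2 <- fixture_trial(seq6)
  expect_false(compute_predictive_look(tr2, 2))
  # track loss in the pre-onset window -> not looking at the box
  tr3 <- fixture_trial(seq6, list(list(t = c(2900, 2999), x = 900, y = 850,
                                       valid = FALSE)))
  expect_false(compute_predictive_look(tr3, 2))
})

test_that("compute_look_away finds the first >= 750 ms off-screen run", {
  # 800 ms off-screen run starting 100 ms into event 5
  tr <- fixture_trial(seq6, list(list(t = c(7600, 8400), x = -50, y = -50)))
  expect_equal(compute_look_away(tr), 5)
  # 600 ms run: below threshold
  tr2 <- fixture_trial(seq6, list(list(t = c(7600, 8199), x = -50, y = -50)))
  expect_true(is.na(compute_look_away(tr2)))
  # two qualifying runs (events 3 and 5): the first wins
  tr3 <- fixture_trial(seq6, list(
    list(t = c(4600, 5400), x = -50, y = -50),
    list(t = c(7700, 8500), x = 2500, y = 500)))
  expect_equal(compute_look_away(tr3), 3)
  # invalid samples count as off-screen by default, not when disabled
  tr4 <- fixture_trial(seq6, list(list(t = c(1600, 2500), valid = FALSE)))
  expect_equal(compute_look_away(tr4), 1)
  expect_true(is.na(compute_look_away(tr4, count_invalid = FALSE)))
})

test_that("build_event_table joins measures with surprisal and censors", {
  set <- generate_sequence_set(n_sequences = 4, length = 10,
                               pool_size = 8, seed = 21)
  traces <- score_sequence_set(set)
  truth <- simulate_event_outcomes(set, agent_params(), n_subjects = 2,
                                   traces = traces, seed = 22)
  trials <- render_gaze_streams(truth, set, seed = 23)
  tab <- build_event_table(trials, traces)
  expect_equal(nrow(tab), 2 * 4 * 10)      # subjects x sequences x events
  # join integrity: surprisal matches a direct recomputation bit-for-bit
  for (q in 1:4) {
    s <- set$sequences[[q]]
    direct <- unigram_surprisal_trace(s)$surprisal_bits
    got <- tab$unigram_surprisal_bits[tab$sequence_id == s$sequence_id &
                                        tab$subject_id == "s01"]
    expect_identical(got, direct)
  }
  # censoring: in any trial with a look-away, all later rows are excluded
  # and carry no outcomes
  for (id in unique(tab$trial_id)) {
    rows <- tab[tab$trial_id == id, ]
    la <- which(!is.na(rows$look_away) & rows$look_away)
    expect_lte(length(la), 1)
    if (length(la) == 1 && la < nrow(rows)) {
      after <- rows[(la + 1):nrow(rows), ]
      expect_false(any(after$included))
      expect_true(all(is.na(after$rt_ms)))
      expect_true(all(is.na(after$predictive_look)))
    }
  }
  # idempotence
  expect_identical(tab, build_event_table(trials, traces))
  # missing traces are reported by sequence id
  expect_error(build_event_table(trials, traces[traces$sequence_id != "seq002", ]),
               "seq002")
})

test_that("vectorized trial measurement agrees with per-event functions", {
  set <- generate_sequence_set(n_sequences = 3, length = 12,
                               pool_size = 6, seed = 31)
  traces <- score_sequence_set(set)
  truth <- simulate_event_outcomes(set, agent_params(), n_subjects = 1,
                                   traces = traces, seed = 32)
  trials <- render_gaze_streams(truth, set, seed = 33)
  tab <- build_event_table(trials, traces)
  for (tr in trials) {
    n <- length(tr$sequence$object_ids)
    rows <- tab[tab$trial_id == tr$trial_id, ]
    la <- compute_look_away(tr)
    for (e in seq_len(n) - 1L) {
      included <- is.na(la) || e <= la
      if (included) {
        expect_identical(rows$rt_ms[e + 1], compute_rt(tr, e))
        expect_identical(rows$predictive_look[e + 1],
                         compute_predictive_look(tr, e))
      } else {
        expect_true(is.na(rows$rt_ms[e + 1]))
      }
    }
    # the look-away event's RT is excluded by the simulator's design
    if (!is.na(la)) expect_identical(rows$look_away[la + 1], TRUE)
  }
})

test_that("no sample can sit inside two AOIs at once", {
  set <- generate_sequence_set(n_sequences = 6, length = 8,
                               pool_size = 10, seed = 41)
  traces <- score_sequence_set(set)
  truth <- simulate_event_outcomes(set, agent_params(), n_subjects = 1,
                                   traces = traces, seed = 42)
  trials <- render_gaze_streams(truth, set, seed = 43)
  for (tr in trials) {
    ctr <- tr$sequence$geometry$box_centers
    r <- tr$sequence$geometry$aoi_radius
    n_in <- rowSums(vapply(seq_len(nrow(ctr)), function(b) {
      in_aoi(tr$samples$x_px, tr$samples$y_px, tr$samples$valid,
             ctr[b, ], r)
    }, logical(nrow(tr$samples))))
    expect_lte(max(n_in), 1)
  }
})

test_that("gaze CSV export reconstructs identical trials", {
  set <- generate_sequence_set(n_sequences = 2, length = 6,
                               pool_size = 4, seed = 51)
  traces <- score_sequence_set(set)
  truth <- simulate_event_outcomes(set, agent_params(), n_subjects = 1,
                                   traces = traces, seed = 52)
  trials <- render_gaze_streams(truth, set, seed = 53)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze(trials, path)
  back <- read_gaze(path, set)
  expect_equal(length(back), length(trials))
  tab1 <- build_event_table(trials, traces)
  tab2 <- build_event_table(back, traces)
  expect_identical(tab1[order(tab1$trial_id, tab1$event_index), ],
                   tab2[order(tab2$trial_id, tab2$event_index), ])
})
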