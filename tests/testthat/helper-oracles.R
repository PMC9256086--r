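# Independent brute-force oracles and hand-built fixtures used across the
# suite. The oracles recount the full prefix at every event instead of
# keeping running state, so they share no code path with the package's
# sequential implementation.

# Unigram oracle: event t's probability from a fresh count of events
# 1..t-1 at every step.
oracle_unigram <- function(ids, K = 3, alpha = 1) {
  n <- length(ids)
  vapply(seq_len(n), function(t) {
    prefix <- ids[seq_len(t - 1L)]
    cnt <- vapply(0:(K - 1L), function(o) sum(prefix == o), numeric(1))
    p <- (cnt[ids[t] + 1L] + alpha) / (sum(cnt) + K * alpha)
    -log2(p)
  }, numeric(1))
}

# Transitional oracle: event t >= 2 scored from a fresh count of all
# transitions in the prefix whose source is object_(t-1); event 1 from the
# flat prior.
oracle_transitional <- function(ids, K = 3, alpha = 1) {
  n <- length(ids)
  vapply(seq_len(n), function(t) {
    if (t == 1L) return(-log2(alpha / (K * alpha)))
    src <- ids[t - 1L]
    from_src <- which(ids[seq_len(t - 2L)] == src)  # transitions i -> i+1
    dests <- ids[from_src + 1L]
    cnt <- vapply(0:(K - 1L), function(o) sum(dests == o), numeric(1))
    p <- (cnt[ids[t] + 1L] + alpha) / (sum(cnt) + K * alpha)
    -log2(p)
  }, numeric(1))
}

# Deterministic, well-separated test geometry (no RNG involved).
fixed_geometry <- function(aoi_radius = 150) {
  structure(
    list(box_centers = matrix(c(400L, 1400L, 900L, 300L, 300L, 850L),
                              ncol = 2,
                              dimnames = list(NULL, c("x", "y"))),
         screen_bounds = c(xmin = 0, ymin = 0, xmax = 1920, ymax = 1080),
         aoi_radius = aoi_radius,
         filler = c(x = 400L, y = 850L)),
    class = "box_geometry")
}

# A gaze trial whose samples sit at `default_xy` except where overridden.
# `spans` is a list of list(t = c(from, to), x =, y =, valid =) blocks.
fixture_trial <- function(seq, spans = list(), default_xy = c(400, 850),
                          subject = "s01", trial = "t01", number = 1L) {
  n_ms <- length(seq$object_ids) * seq$duration_ms
  x <- rep(default_xy[1], n_ms)
  y <- rep(default_xy[2], n_ms)
  valid <- rep(TRUE, n_ms)
  for (sp in spans) {
    i <- (sp$t[1] + 1L):(sp$t[2] + 1L)     # t is 0-based ms
    if (!is.null(sp$x)) x[i] <- sp$x
    if (!is.null(sp$y)) y[i] <- sp$y
    if (!is.null(sp$valid)) valid[i] <- sp$valid
  }
  gaze_trial(subject, trial, number, seq,
             tibble::tibble(t_ms = 0:(n_ms - 1L), x_px = x, y_px = y,
                            valid = valid))
}

# Small benchmark-style simulation shared by several tests.
small_sim <- function(seed = 101, n_subjects = 2L, n_sequences = 12L,
                      length = 20L, params = agent_params(),
                      render = FALSE) {
  make_benchmark_dataset(n_subjects = n_subjects,
                         n_sequences = n_sequences, length = length,
                         params = params, seed = seed, render = render)
}
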