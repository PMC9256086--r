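#' Ground-truth parameters of a simulated gaze agent
#'
#' The agent's behaviour depends on standardized surprisal z through three
#' linear predictors, each with a shared per-subject random intercept
#' u_s ~ N(0, subject_sd):
#'
#' * log RT ~ Normal(a0 + u_s + a1 z + a2 z^2, sigma_rt)
#' * look-away hazard: Bernoulli(logistic(b0 + u_s + b1 z + b2 z^2)) per
#'   event, the trial censored after the first success
#' * predictive looking (first appearances): Bernoulli(logistic(c0 + u_s +
#'   c1 z))
#'
#' Defaults qualitatively mimic the U-shaped attention regime: negative
#' linear and positive quadratic terms for RT and look-away (attention is
#' strongest -- RT fastest, look-away rarest -- at intermediate surprisal),
#' and a negative linear term for predictive looking.
#'
#' @param rt c(a0, a1, a2) on the log-ms scale.
#' @param sigma_rt residual SD of log RT (> 0).
#' @param lookaway c(b0, b1, b2) on the logit scale.
#' @param predictive c(c0, c1) on the logit scale.
#' @param subject_sd SD of the per-subject random intercept (>= 0).
#' @return object of class `agent_params`.
#' @export
agent_params <- function(rt = c(5.5, -0.05, 0.04), sigma_rt = 0.25,
                         lookaway = c(-2.2, -0.6, 0.35),
                         predictive = c(-1.0, -0.5), subject_sd = 0.3) {
  stopifnot(length(rt) == 3L, length(lookaway) == 3L,
            length(predictive) == 2L)
  if (!is.finite(sigma_rt) || sigma_rt <= 0) {
    stop("validation error: sigma_rt must be positive")
  }
  if (!is.finite(subject_sd) || subject_sd < 0) {
    stop("validation error: subject_sd must be non-negative")
  }
  structure(list(rt = as.numeric(rt), sigma_rt = as.numeric(sigma_rt),
                 lookaway = as.numeric(lookaway),
                 predictive = as.numeric(predictive),
                 subject_sd = as.numeric(subject_sd)),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n",
      "  log RT:    a = (", paste(x$rt, collapse = ", "),
      "), sigma_rt = ", x$sigma_rt, "\n",
      "  look-away: b = (", paste(x$lookaway, collapse = ", "), ")\n",
      "  predictive: c = (", paste(x$predictive, collapse = ", "), ")\n",
      "  subject_sd = ", x$subject_sd, "\n", sep = "")
  invisible(x)
}

#' Simulate per-event behavioural outcomes for a cohort of agents
#'
#' Draws RT, look-away and predictive-look outcomes for every subject x
#' sequence x event under the generative model of [agent_params()].
#' Surprisal is standardized over the full event pool of the sequence set
#' (the stimulus-side scale; identical to the default analysis-side
#' standardization). Every subject sees every sequence, in an independent
#' random order (`trial_number`). Trials are censored after the first drawn
#' look-away: later events have `included = FALSE` and carry no outcomes,
#' and the look-away event's own RT is `NA` (the agent is disengaging).
#' Drawn RTs that would land inside the reserved pre-onset slot at the end
#' of the event window (>= duration - 100 ms, a many-sigma tail under the
#' defaults) are recorded as "never fixated" (`NA`).
#'
#' @param set a `sequence_set`.
#' @param params an `agent_params`.
#' @param n_subjects number of simulated subjects (>= 1).
#' @param model which surprisal drives behaviour: "unigram" or
#'   "transitional".
#' @param traces optional precomputed [score_sequence_set()] table.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param alpha Dirichlet pseudo-count when traces are computed here.
#' @return event truth table: tibble with the analysis columns
#'   (subject_id, trial_id, trial_number, sequence_id, event_index,
#'   object_id, rt_ms, predictive_look, look_away, included, is_repeat,
#'   distance_px, unigram_surprisal_bits, transitional_surprisal_bits) plus
#'   latent truth columns prefixed `truth_` (z, linear predictors, the
#'   uncensored look-away draw, subject intercepts).
#' @export
simulate_event_outcomes <- function(set, params, n_subjects = 5L,
                                    model = c("unigram", "transitional"),
                                    traces = NULL, seed = NULL, alpha = 1) {
  stopifnot(inherits(set, "sequence_set"), inherits(params, "agent_params"))
  model <- match.arg(model)
  if (n_subjects < 1L) stop("validation error: n_subjects must be >= 1")
  if (is.null(traces)) traces <- score_sequence_set(set, alpha = alpha)
  run <- function() {
    simulate_outcomes_impl(set, params, n_subjects, model, traces)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_outcomes_impl <- function(set, params, n_subjects, model, traces) {
  scol <- paste0(model, "_surprisal_bits")
  if (!is.finite(stats::sd(traces[[scol]])) ||
      stats::sd(traces[[scol]]) == 0) {
    stop("validation error: surprisal has zero variance")
  }
  n_seq <- length(set$sequences)
  seq_ids <- vapply(set$sequences, function(s) s$sequence_id, "")
  # flat per-event pool in set order (one block per sequence)
  pool <- do.call(rbind, lapply(seq_along(set$sequences), function(q) {
    s <- set$sequences[[q]]
    ec <- event_centers(s)
    n <- length(s$object_ids)
    data.frame(
      seq_idx = q, sequence_id = s$sequence_id,
      event_index = seq_len(n) - 1L, object_id = s$object_ids,
      duration = s$duration_ms,
      is_repeat = c(FALSE, s$object_ids[-1] == s$object_ids[-n]),
      distance_px = c(NA_real_,
                      sqrt(rowSums((ec[-1, , drop = FALSE] -
                                      ec[-n, , drop = FALSE])^2))),
      first_app = !duplicated(s$object_ids))
  }))
  key_tr <- paste(traces$sequence_id, traces$event_index)
  idx <- match(paste(pool$sequence_id, pool$event_index), key_tr)
  pool$unigram_surprisal_bits <- traces$unigram_surprisal_bits[idx]
  pool$transitional_surprisal_bits <- traces$transitional_surprisal_bits[idx]
  pool$z <- as.numeric(scale(pool[[scol]]))
  m <- nrow(pool)
  total <- m * n_subjects
  row_of <- rep(seq_len(m), times = n_subjects)
  subj_i <- rep(seq_len(n_subjects), each = m)
  u <- stats::rnorm(n_subjects, 0, params$subject_sd)
  # independent randomized presentation order per subject
  orders <- t(vapply(seq_len(n_subjects), function(i) sample.int(n_seq),
                     integer(n_seq)))
  z <- pool$z[row_of]
  u_row <- u[subj_i]
  eta_rt <- params$rt[1] + u_row + params$rt[2] * z + params$rt[3] * z^2
  rt <- as.integer(round(exp(eta_rt +
                               stats::rnorm(total, 0, params$sigma_rt))))
  rt[rt >= pool$duration[row_of] - 100L] <- NA_integer_
  p_la <- stats::plogis(params$lookaway[1] + u_row +
                          params$lookaway[2] * z +
                          params$lookaway[3] * z^2)
  la_draw <- stats::runif(total) < p_la
  p_pred <- stats::plogis(params$predictive[1] + u_row +
                            params$predictive[2] * z)
  pred_draw <- stats::runif(total) < p_pred
  # censoring: rows are contiguous per (subject, sequence) trial
  trial_idx <- (subj_i - 1L) * n_seq + pool$seq_idx[row_of]
  cum <- stats::ave(as.numeric(la_draw), trial_idx, FUN = cumsum)
  included <- (cum - la_draw) == 0          # at or before the first success
  look_away <- ifelse(included, la_draw & included, NA)
  rt[!included | (la_draw & included)] <- NA_integer_
  pred <- ifelse(pool$first_app[row_of] & pool$event_index[row_of] >= 1L &
                   included, pred_draw, NA)
  res <- tibble::tibble(
    subject_id = sprintf("s%02d", subj_i),
    trial_id = paste0(sprintf("s%02d", subj_i), "_",
                      seq_ids[pool$seq_idx[row_of]]),
    trial_number = orders[cbind(subj_i, pool$seq_idx[row_of])],
    sequence_id = pool$sequence_id[row_of],
    event_index = pool$event_index[row_of],
    object_id = pool$object_id[row_of],
    rt_ms = rt,
    predictive_look = pred,
    look_away = look_away,
    included = included,
    is_repeat = pool$is_repeat[row_of],
    distance_px = pool$distance_px[row_of],
    unigram_surprisal_bits = pool$unigram_surprisal_bits[row_of],
    transitional_surprisal_bits = pool$transitional_surprisal_bits[row_of],
    truth_z = z,
    truth_p_lookaway = p_la,
    truth_lookaway_draw = la_draw,
    truth_u_subject = u_row)
  attr(res, "params") <- params
  attr(res, "model") <- model
  res
}

#' Render 1000 Hz gaze streams realizing drawn outcomes
#'
#' The inverse of the measure-extraction stage: emits per-trial sample
#' streams from which [build_event_table()] recovers the drawn outcomes
#' exactly. For each event with a drawn RT, gaze enters the event's AOI at
#' onset + RT and dwells there until the reserved 100 ms pre-onset slot at
#' the end of the window; a drawn predictive look fills that slot with
#' gaze in the upcoming box's AOI; from 50 ms into a drawn look-away event
#' the stream goes (and stays) off-screen, creating one >= 750 ms
#' off-screen run that starts in that event's window; all remaining
#' samples sit at the trial's neutral filler point. Small integer jitter
#' (clamped to +/- 20 px) keeps samples trivially inside/outside the
#' relevant AOIs.
#'
#' @param truth event truth table from [simulate_event_outcomes()].
#' @param set the `sequence_set` the truth table references.
#' @param seed integer seed for the jitter; `NULL` uses the ambient stream.
#' @param jitter_sd Gaussian jitter SD in px.
#' @return list of `gaze_trial` objects, one per (subject, sequence).
#' @export
render_gaze_streams <- function(truth, set, seed = NULL, jitter_sd = 4) {
  stopifnot(inherits(set, "sequence_set"))
  run <- function() render_streams_impl(truth, set, jitter_sd)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

render_streams_impl <- function(truth, set, jitter_sd) {
  seqs <- stats::setNames(set$sequences,
                          vapply(set$sequences,
                                 function(s) s$sequence_id, ""))
  jit <- function(n) {
    as.integer(pmax(-20, pmin(20, round(stats::rnorm(n, 0, jitter_sd)))))
  }
  pre_ms <- 100L
  trial_keys <- unique(truth$trial_id)
  trials <- vector("list", length(trial_keys))
  for (i in seq_along(trial_keys)) {
    rows <- truth[truth$trial_id == trial_keys[i], ]
    rows <- rows[order(rows$event_index), ]
    sq <- seqs[[rows$sequence_id[1]]]
    if (is.null(sq)) {
      stop("validation error: unknown sequence_id ", rows$sequence_id[1])
    }
    d <- sq$duration_ms
    n <- length(sq$object_ids)
    if (any(!is.na(rows$rt_ms) & rows$rt_ms >= d - pre_ms)) {
      stop("validation error: drawn RT reaches the reserved pre-onset slot")
    }
    N <- n * d
    centers <- event_centers(sq)
    filler <- sq$geometry$filler
    x <- filler[1] + jit(N)
    y <- filler[2] + jit(N)
    for (e in seq_len(n) - 1L) {
      onset <- e * d
      rt <- rows$rt_ms[e + 1L]
      if (!is.na(rt)) {
        span <- (onset + rt + 1L):(onset + d - pre_ms)  # 1-based indices
        x[span] <- centers[e + 1L, 1] + jit(length(span))
        y[span] <- centers[e + 1L, 2] + jit(length(span))
      }
      pl <- rows$predictive_look[e + 1L]
      if (!is.na(pl) && pl) {
        span <- (onset - pre_ms + 1L):onset
        x[span] <- centers[e + 1L, 1] + jit(length(span))
        y[span] <- centers[e + 1L, 2] + jit(length(span))
      }
    }
    la <- which(!is.na(rows$look_away) & rows$look_away) - 1L
    if (length(la)) {
      span <- (la[1] * d + 50L + 1L):N
      x[span] <- -200L
      y[span] <- -200L
    }
    trials[[i]] <- gaze_trial(
      rows$subject_id[1], rows$trial_id[1], rows$trial_number[1], sq,
      tibble::tibble(t_ms = 0:(N - 1L), x_px = x, y_px = y,
                     valid = TRUE))
  }
  trials
}

#' Compose a full benchmark simulation
#'
#' Generates a sequence set, scores it under both observers, simulates
#' agent outcomes, and (optionally) renders the gaze streams. The default
#' scale -- 5 subjects, 80 sequences of 30 events each, every sequence
#' shown to every subject in an independent random order -- mirrors the
#' study design the package targets. Bit-for-bit reproducible given `seed`.
#'
#' @param n_subjects number of subjects (default 5).
#' @param n_sequences number of sequences (default 80).
#' @param length events per sequence (default 30).
#' @param params ground-truth `agent_params`.
#' @param seed integer seed for everything.
#' @param model surprisal model driving behaviour.
#' @param render render gaze streams (default TRUE; set FALSE when only the
#'   outcome table is needed, e.g. for fast replicate studies).
#' @param alpha Dirichlet pseudo-count.
#' @return object of class `simulated_dataset`: list with `sequences`,
#'   `traces`, `truth`, `trials` (NULL when not rendered), `params`,
#'   `model`, `seed`.
#' @export
make_benchmark_dataset <- function(n_subjects = 5L, n_sequences = 80L,
                                   length = 30L, params = agent_params(),
                                   seed = 1L,
                                   model = c("unigram", "transitional"),
                                   render = TRUE, alpha = 1) {
  model <- match.arg(model)
  withr::with_seed(seed, {
    set_seed_val <- sample.int(1e9, 1L)
    set <- generate_sequence_set(n_sequences = n_sequences, length = length,
                                 seed = set_seed_val, alpha = alpha)
    traces <- score_sequence_set(set, alpha = alpha)
    truth <- simulate_event_outcomes(set, params, n_subjects = n_subjects,
                                     model = model, traces = traces,
                                     seed = NULL)
    trials <- if (render) render_gaze_streams(truth, set, seed = NULL)
    structure(list(sequences = set, traces = traces, truth = truth,
                   trials = trials, params = params, model = model,
                   seed = as.integer(seed)),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", base::length(unique(x$truth$subject_id)),
      " subjects x ", base::length(x$sequences$sequences),
      " sequences (seed ", x$seed, ", ", x$model, " model",
      if (is.null(x$trials)) ", outcomes only" else ", gaze rendered",
      ")\n", sep = "")
  invisible(x)
}
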