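#' Dirichlet-multinomial belief state
#'
#' The ideal observer's belief over which of K objects pops up next is a
#' Dirichlet-multinomial: a symmetric (or user-supplied) Dirichlet prior
#' `alpha` plus the counts of events observed so far. The prior defaults to
#' the uninformative add-one choice, alpha = 1 for every object, encoding
#' the implicit beliefs of a learner before any observation.
#'
#' @param n_objects number of categories K.
#' @param alpha scalar or length-K vector of positive pseudo-counts.
#' @param counts optional non-negative integer counts (default all zero).
#' @return object of class `dirichlet_counts`.
#' @export
dirichlet_counts <- function(n_objects = 3L, alpha = 1, counts = NULL) {
  alpha <- rep_len(as.numeric(alpha), n_objects)
  if (any(alpha <= 0)) stop("validation error: alpha must be positive")
  if (is.null(counts)) counts <- integer(n_objects)
  counts <- as.integer(counts)
  if (length(counts) != n_objects || any(counts < 0)) {
    stop("validation error: counts must be ", n_objects,
         " non-negative integers")
  }
  structure(list(alpha = alpha, counts = counts,
                 n_objects = as.integer(n_objects)),
            class = "dirichlet_counts")
}

#' Posterior-predictive distribution of a belief state
#'
#' The closed-form Dirichlet-multinomial posterior predictive:
#' `p_i = (counts_i + alpha_i) / (sum(counts) + sum(alpha))`. Always a
#' proper distribution with every `p_i > 0`.
#'
#' @param state a `dirichlet_counts`.
#' @return numeric vector of K probabilities summing to 1.
#' @export
predictive_distribution <- function(state) {
  stopifnot(inherits(state, "dirichlet_counts"))
  num <- state$counts + state$alpha
  num / sum(num)
}

#' Incorporate one observation into a belief state
#'
#' Value semantics: returns a new state with `counts[observed]` incremented;
#' the input state is not modified.
#'
#' @param state a `dirichlet_counts`.
#' @param observed 0-based object index of the observed event.
#' @return updated `dirichlet_counts`.
#' @export
update_counts <- function(state, observed) {
  stopifnot(inherits(state, "dirichlet_counts"))
  observed <- as.integer(observed)
  if (length(observed) != 1L || is.na(observed) || observed < 0L ||
      observed >= state$n_objects) {
    stop("validation error: observed must lie in [0, ", state$n_objects, ")")
  }
  state$counts[observed + 1L] <- state$counts[observed + 1L] + 1L
  state
}

#' Per-event unigram surprisal of a sequence
#'
#' The unigram observer treats events as exchangeable draws: before event t
#' it holds Dirichlet-multinomial beliefs over the K objects based on the
#' counts of events 1..t-1, scores event t with surprisal
#' `-log2 p(object_t)` under the posterior predictive, then updates. The
#' first event of any sequence therefore costs `log2 K` bits under the
#' uniform prior.
#'
#' @param seq a `sequence_spec` (or a bare 0-based integer vector of object
#'   ids, in which case `n_objects` must be supplied).
#' @param alpha Dirichlet pseudo-count(s), default 1 (Laplace).
#' @param n_objects K; taken from `seq` when it is a `sequence_spec`.
#' @return tibble with `event_index` (0-based), `object_id`, `p`
#'   (posterior-predictive probability in (0, 1]) and `surprisal_bits`
#'   (`= -log2(p)`, non-negative).
#' @export
unigram_surprisal_trace <- function(seq, alpha = 1, n_objects = NULL) {
  ids <- resolve_ids(seq, n_objects)
  K <- attr(ids, "K")
  state <- dirichlet_counts(K, alpha = alpha)
  n <- length(ids)
  p <- numeric(n)
  for (t in seq_len(n)) {
    p[t] <- predictive_distribution(state)[ids[t] + 1L]
    state <- update_counts(state, ids[t])
  }
  tibble::tibble(event_index = seq_len(n) - 1L, object_id = ids,
                 p = p, surprisal_bits = -log2(p))
}

#' Per-event transitional (bigram) surprisal of a sequence
#'
#' The transitional observer conditions on the immediately preceding event:
#' it keeps a K x K Dirichlet-multinomial transition-count matrix and scores
#' event t (t >= 2) with the posterior-predictive row of object_(t-1). The
#' first event, which has no predecessor, is scored by the marginal
#' (unigram-style) prior. Counts update after each event is scored.
#'
#' @inheritParams unigram_surprisal_trace
#' @return tibble as in [unigram_surprisal_trace()].
#' @export
transitional_surprisal_trace <- function(seq, alpha = 1, n_objects = NULL) {
  ids <- resolve_ids(seq, n_objects)
  K <- attr(ids, "K")
  marginal <- dirichlet_counts(K, alpha = alpha)
  rows <- lapply(seq_len(K), function(i) dirichlet_counts(K, alpha = alpha))
  n <- length(ids)
  p <- numeric(n)
  p[1] <- predictive_distribution(marginal)[ids[1] + 1L]
  if (n >= 2L) {
    for (t in 2:n) {
      prev <- ids[t - 1L] + 1L
      p[t] <- predictive_distribution(rows[[prev]])[ids[t] + 1L]
      rows[[prev]] <- update_counts(rows[[prev]], ids[t])
    }
  }
  tibble::tibble(event_index = seq_len(n) - 1L, object_id = ids,
                 p = p, surprisal_bits = -log2(p))
}

# Accept either a sequence_spec or a bare 0-based id vector.
resolve_ids <- function(seq, n_objects) {
  if (inherits(seq, "sequence_spec")) {
    ids <- seq$object_ids
    K <- seq$n_objects
  } else {
    ids <- as.integer(seq)
    if (is.null(n_objects)) {
      stop("validation error: n_objects required for a bare id vector")
    }
    K <- as.integer(n_objects)
  }
  if (length(ids) < 1L) stop("validation error: empty sequence")
  if (any(ids < 0L) || any(ids >= K)) {
    stop("validation error: object ids must lie in [0, ", K, ")")
  }
  attr(ids, "K") <- K
  ids
}

#' Score every sequence of a set under both observers
#'
#' Belief state is reset at each sequence boundary: objects are unique
#' within a trial and drawn fresh across trials, so counts never carry over.
#'
#' @param set a `sequence_set`.
#' @param alpha Dirichlet pseudo-count(s).
#' @return tibble with one row per (sequence, event): `sequence_id`,
#'   `event_index`, `object_id`, `unigram_p`, `transitional_p`,
#'   `unigram_surprisal_bits`, `transitional_surprisal_bits`.
#' @export
score_sequence_set <- function(set, alpha = 1) {
  stopifnot(inherits(set, "sequence_set"))
  traces <- lapply(set$sequences, function(s) {
    u <- unigram_surprisal_trace(s, alpha = alpha)
    b <- transitional_surprisal_trace(s, alpha = alpha)
    tibble::tibble(
      sequence_id = s$sequence_id,
      event_index = u$event_index,
      object_id   = u$object_id,
      unigram_p   = u$p,
      transitional_p = b$p,
      unigram_surprisal_bits      = u$surprisal_bits,
      transitional_surprisal_bits = b$surprisal_bits)
  })
  do.call(rbind, traces)
}

#' Write surprisal traces as CSV
#'
#' Columns: sequence_id, event_index, object_id, unigram_surprisal_bits,
#' transitional_surprisal_bits, unigram_p, transitional_p.
#'
#' @param traces output of [score_sequence_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surprisal <- function(traces, path) {
  cols <- c("sequence_id", "event_index", "object_id",
            "unigram_surprisal_bits", "transitional_surprisal_bits",
            "unigram_p", "transitional_p")
  utils::write.csv(as.data.frame(traces)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surprisal
#' @export
read_surprisal <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
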