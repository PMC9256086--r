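#' Construct a gaze trial
#'
#' One subject x trial stream of timestamped gaze samples, tied to the
#' sequence that was displayed. Samples are expected at nominal 1 ms
#' spacing (1000 Hz), strictly increasing in time, covering the trial.
#'
#' @param subject_id,trial_id identifiers.
#' @param trial_number ordinal position of the trial in the session.
#' @param sequence the displayed `sequence_spec`.
#' @param samples tibble/data.frame with columns `t_ms`, `x_px`, `y_px`,
#'   `valid` (FALSE = track loss).
#' @return object of class `gaze_trial`.
#' @export
gaze_trial <- function(subject_id, trial_id, trial_number, sequence,
                       samples) {
  stopifnot(inherits(sequence, "sequence_spec"))
  samples <- tibble::as_tibble(samples)
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(samples))) {
    stop("validation error: samples need columns ",
         paste(need, collapse = ", "))
  }
  if (is.unsorted(samples$t_ms, strictly = TRUE)) {
    stop("validation error: sample times must be strictly increasing")
  }
  b <- sequence$geometry$screen_bounds
  if (b["xmax"] <= b["xmin"] || b["ymax"] <= b["ymin"]) {
    stop("validation error: degenerate screen bounds")
  }
  structure(list(subject_id   = as.character(subject_id),
                 trial_id     = as.character(trial_id),
                 trial_number = as.integer(trial_number),
                 sequence     = sequence,
                 samples      = samples),
            class = "gaze_trial")
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat("<gaze_trial> subject ", x$subject_id, ", trial ", x$trial_id,
      " (", x$sequence$sequence_id, "): ", nrow(x$samples), " samples\n",
      sep = "")
  invisible(x)
}

#' Is a gaze sample inside a circular AOI?
#'
#' Boundary inclusive: a sample exactly at distance `radius` counts as
#' inside. Invalid (track-loss) samples are never inside any AOI.
#'
#' @param x,y sample coordinates (vectorized).
#' @param valid logical validity flags.
#' @param center length-2 AOI center (x, y).
#' @param radius AOI radius in px (> 0).
#' @return logical vector.
#' @export
in_aoi <- function(x, y, valid, center, radius) {
  stopifnot(radius > 0)
  valid & ((x - center[1])^2 + (y - center[2])^2) <= radius^2
}

# TRUE where a sample counts as off-screen: outside the bounds or invalid.
# Track loss during a head turn away from the screen is behaviourally
# off-screen; controllable via `count_invalid`.
offscreen <- function(samples, bounds, count_invalid = TRUE) {
  off <- samples$x_px < bounds["xmin"] | samples$x_px > bounds["xmax"] |
    samples$y_px < bounds["ymin"] | samples$y_px > bounds["ymax"]
  if (count_invalid) off <- off | !samples$valid
  off
}

check_event_index <- function(trial, event_index) {
  n <- length(trial$sequence$object_ids)
  event_index <- as.integer(event_index)
  if (length(event_index) != 1L || is.na(event_index) ||
      event_index < 0L || event_index >= n) {
    stop("validation error: event ", event_index,
         " is outside the trial's sequence (", n, " events)")
  }
  event_index
}

#' Reaction time to fixate the active object
#'
#' Latency from the event's pop-up onset to the first gaze sample inside
#' the event's AOI, within the event window `[onset, onset + duration)`.
#' Gaze already inside the AOI at onset gives RT = 0; `NA` if the AOI is
#' never entered during the event.
#'
#' @param trial a `gaze_trial`.
#' @param event_index 0-based event index.
#' @param min_dwell_ms require the gaze to remain in the AOI at least this
#'   long for the entry to count (default 0: first sample counts).
#' @return latency in ms, or `NA`.
#' @export
compute_rt <- function(trial, event_index, min_dwell_ms = 0) {
  e <- check_event_index(trial, event_index)
  sq <- trial$sequence
  onset <- e * sq$duration_ms
  centers <- event_centers(sq)
  s <- trial$samples
  win <- s$t_ms >= onset & s$t_ms < onset + sq$duration_ms
  if (!any(win)) return(NA_integer_)
  inside <- in_aoi(s$x_px[win], s$y_px[win], s$valid[win],
                   centers[e + 1L, ], sq$geometry$aoi_radius)
  tw <- s$t_ms[win]
  if (min_dwell_ms > 0) {
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & (tw[ends] - tw[starts] + 1L) >= min_dwell_ms
    if (!any(ok)) return(NA_integer_)
    return(as.integer(tw[starts[which(ok)[1]]] - onset))
  }
  if (!any(inside)) return(NA_integer_)
  as.integer(tw[which(inside)[1]] - onset)
}

#' Predictive looking at an object's first appearance
#'
#' Whether the subject was already fixating the to-be-active box just
#' before the object popped up. Defined only on the first appearance of an
#' event's object; `NA` for later appearances and for the very first event
#' of a trial (no pre-onset sample exists). TRUE iff every sample in the
#' pre-onset window `[onset - window_ms, onset - 1]` lies in the event's
#' AOI (default window 1 ms: the last pre-onset sample).
#'
#' @inheritParams compute_rt
#' @param window_ms pre-onset window length in ms (default 1).
#' @return logical, or `NA` where undefined.
#' @export
compute_predictive_look <- function(trial, event_index, window_ms = 1) {
  e <- check_event_index(trial, event_index)
  sq <- trial$sequence
  first_app <- match(sq$object_ids[e + 1L], sq$object_ids) - 1L
  if (first_app != e || e == 0L) return(NA)
  onset <- e * sq$duration_ms
  s <- trial$samples
  win <- s$t_ms >= onset - window_ms & s$t_ms < onset
  if (!any(win)) return(FALSE)
  centers <- event_centers(sq)
  all(in_aoi(s$x_px[win], s$y_px[win], s$valid[win],
             centers[e + 1L, ], sq$geometry$aoi_radius))
}

#' First qualifying look-away of a trial
#'
#' Scans the samples in time order for the first maximal run of at least
#' `threshold_ms` consecutive milliseconds that are off-screen (outside the
#' screen bounds, or track-loss if `count_invalid`). Returns the 0-based
#' index of the event whose window contains the run's start, or `NA` if no
#' run qualifies. The default threshold, 750 ms, is 50% of the 1.5 s pop-up
#' event duration.
#'
#' @param trial a `gaze_trial`.
#' @param threshold_ms minimum off-screen run length in ms.
#' @param count_invalid treat invalid samples as off-screen (default TRUE).
#' @return 0-based event index, or `NA`.
#' @export
compute_look_away <- function(trial, threshold_ms = 750,
                              count_invalid = TRUE) {
  sq <- trial$sequence
  s <- trial$samples
  off <- offscreen(s, sq$geometry$screen_bounds, count_invalid)
  r <- rle(off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- s$t_ms[ends] - s$t_ms[starts] + 1L
  ok <- r$values & dur >= threshold_ms
  if (!any(ok)) return(NA_integer_)
  start_t <- s$t_ms[starts[which(ok)[1]]]
  ev <- start_t %/% sq$duration_ms
  as.integer(min(ev, length(sq$object_ids) - 1L))
}

# All three measures for one trial, vectorized over samples. Returns one
# row per event; used by build_event_table. Per-event compute_rt /
# compute_predictive_look / compute_look_away are the reference semantics.
measure_trial <- function(trial, threshold_ms = 750, window_ms = 1,
                          min_dwell_ms = 0, count_invalid = TRUE) {
  sq <- trial$sequence
  n <- length(sq$object_ids)
  d <- sq$duration_ms
  centers <- event_centers(sq)
  s <- trial$samples
  ev <- s$t_ms %/% d                       # event window of each sample
  keep <- ev >= 0L & ev < n
  # each sample is tested against the AOI of its own event's pop-up box
  cx <- centers[pmin(pmax(ev, 0L), n - 1L) + 1L, 1]
  cy <- centers[pmin(pmax(ev, 0L), n - 1L) + 1L, 2]
  inside <- keep & s$valid &
    ((s$x_px - cx)^2 + (s$y_px - cy)^2) <= sq$geometry$aoi_radius^2
  if (min_dwell_ms > 0) {
    rt <- vapply(seq_len(n) - 1L, function(e) {
      compute_rt(trial, e, min_dwell_ms = min_dwell_ms)
    }, integer(1))
  } else {
    rt <- rep(NA_integer_, n)
    idx <- which(inside)
    if (length(idx)) {
      first_t <- tapply(s$t_ms[idx], ev[idx], min)
      e_hit <- as.integer(names(first_t))
      rt[e_hit + 1L] <- as.integer(first_t - e_hit * d)
    }
  }
  # predictive looking, first appearances with index >= 1 only
  pred <- rep(NA, n)
  firsts <- match(unique(sq$object_ids), sq$object_ids) - 1L
  for (e in setdiff(firsts, 0L)) {
    pred[e + 1L] <- compute_predictive_look(trial, e, window_ms = window_ms)
  }
  la <- compute_look_away(trial, threshold_ms = threshold_ms,
                          count_invalid = count_invalid)
  look_away <- rep(FALSE, n)
  included <- rep(TRUE, n)
  if (!is.na(la)) {
    look_away[la + 1L] <- TRUE
    if (la + 2L <= n) {
      included[(la + 2L):n] <- FALSE
      look_away[(la + 2L):n] <- NA
    }
  }
  rt[!included] <- NA_integer_
  pred[!included] <- NA
  ec <- centers
  dist_px <- c(NA_real_, sqrt(rowSums((ec[-1, , drop = FALSE] -
                                         ec[-n, , drop = FALSE])^2)))
  tibble::tibble(
    subject_id   = trial$subject_id,
    trial_id     = trial$trial_id,
    trial_number = trial$trial_number,
    sequence_id  = sq$sequence_id,
    event_index  = seq_len(n) - 1L,
    object_id    = sq$object_ids,
    rt_ms        = rt,
    predictive_look = pred,
    look_away    = look_away,
    included     = included,
    is_repeat    = c(FALSE, sq$object_ids[-1] == sq$object_ids[-n]),
    distance_px  = dist_px)
}

#' Build the per-event analysis table
#'
#' Reduces every trial to one row per event -- reaction time, predictive
#' looking, look-away, inclusion flag, covariates (repeat status, distance
#' between consecutive pop-up boxes, trial number) -- and joins the
#' per-event surprisal of both observer models. Rows after a trial's first
#' qualifying look-away are flagged `included = FALSE` and carry no
#' RT/predictive outcomes (the look-away terminates the trial's analysis
#' window, as in the infant habituation convention).
#'
#' @param trials list of `gaze_trial` objects.
#' @param traces surprisal table from [score_sequence_set()], covering every
#'   sequence referenced by the trials.
#' @param threshold_ms look-away threshold in ms (default 750).
#' @param window_ms predictive-look pre-onset window in ms (default 1).
#' @param min_dwell_ms minimum AOI dwell for RT entries (default 0).
#' @param count_invalid treat track loss as off-screen (default TRUE).
#' @return tibble, one row per (trial, event).
#' @export
build_event_table <- function(trials, traces, threshold_ms = 750,
                              window_ms = 1, min_dwell_ms = 0,
                              count_invalid = TRUE) {
  stopifnot(length(trials) >= 1L)
  need <- unique(vapply(trials, function(tr) tr$sequence$sequence_id, ""))
  missing <- setdiff(need, unique(traces$sequence_id))
  if (length(missing)) {
    stop("validation error: no surprisal trace for sequence(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(trials, measure_trial, threshold_ms = threshold_ms,
                 window_ms = window_ms, min_dwell_ms = min_dwell_ms,
                 count_invalid = count_invalid)
  tab <- do.call(rbind, rows)
  key_tab <- paste(tab$sequence_id, tab$event_index)
  key_tr <- paste(traces$sequence_id, traces$event_index)
  idx <- match(key_tab, key_tr)
  if (anyNA(idx)) {
    stop("validation error: surprisal trace misses events for sequence(s): ",
         paste(unique(tab$sequence_id[is.na(idx)]), collapse = ", "))
  }
  tab$unigram_surprisal_bits <- traces$unigram_surprisal_bits[idx]
  tab$transitional_surprisal_bits <- traces$transitional_surprisal_bits[idx]
  tab
}

#' Write / read gaze trials as CSV
#'
#' Long format, one row per sample: subject_id, trial_id, trial_number,
#' sequence_id, t_ms, x_px, y_px, valid.
#'
#' @param trials list of `gaze_trial`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    cbind(data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
                     trial_number = tr$trial_number,
                     sequence_id = tr$sequence$sequence_id),
          as.data.frame(tr$samples))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @param set the `sequence_set` the trials reference (provides geometry).
#' @export
read_gaze <- function(path, set) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seqs <- stats::setNames(set$sequences,
                          vapply(set$sequences,
                                 function(s) s$sequence_id, ""))
  key <- paste(df$subject_id, df$trial_id, sep = "\r")
  split_idx <- split(seq_len(nrow(df)), key)
  lapply(unname(split_idx), function(i) {
    h <- df[i[1], ]
    sq <- seqs[[h$sequence_id]]
    if (is.null(sq)) {
      stop("validation error: unknown sequence_id ", h$sequence_id)
    }
    gaze_trial(h$subject_id, h$trial_id, h$trial_number, sq,
               df[i, c("t_ms", "x_px", "y_px", "valid")])
  })
}
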