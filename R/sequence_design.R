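#' Random box geometry for a three-box display
#'
#' Places `n_boxes` box centers on a 3x3 virtual grid over the screen, with
#' uniform integer jitter, enforcing a minimum pairwise separation of
#' `2 * aoi_radius + 1` px so circular AOIs (boundary inclusive) can never
#' overlap. Also records a neutral "filler" point -- the free grid cell
#' farthest from all boxes -- used by the simulator for between-fixation gaze.
#'
#' Coordinates are screen pixels, origin top-left, x rightward, y downward.
#'
#' @param n_boxes number of boxes (locations); default 3.
#' @param screen_px c(width, height) in pixels.
#' @param aoi_radius circular AOI radius in px around each box center.
#' @param jitter_px maximum absolute uniform jitter applied to each grid cell.
#' @return object of class `box_geometry`: list with `box_centers`
#'   (n_boxes x 2 integer matrix, row i = location i), `screen_bounds`
#'   (xmin, ymin, xmax, ymax), `aoi_radius`, `filler` (x, y).
#' @export
random_box_geometry <- function(n_boxes = 3L, screen_px = c(1920L, 1080L),
                                aoi_radius = 150, jitter_px = 30L) {
  stopifnot(n_boxes >= 1L, aoi_radius > 0)
  gx <- round(screen_px[1] * c(0.1875, 0.5, 0.8125))  # 360, 960, 1560 @1920
  gy <- round(screen_px[2] * c(2 / 9, 0.5, 7 / 9))    # 240, 540, 840 @1080
  cells <- as.matrix(expand.grid(x = gx, y = gy))
  if (nrow(cells) < n_boxes + 1L) {
    stop("geometry error: grid too small for ", n_boxes, " boxes plus filler")
  }
  min_sep <- 2 * aoi_radius + 1
  for (iter in seq_len(10000L)) {
    pick <- sample.int(nrow(cells), n_boxes)
    centers <- cells[pick, , drop = FALSE] +
      matrix(sample.int(2L * jitter_px + 1L, 2L * n_boxes, replace = TRUE) -
               jitter_px - 1L, ncol = 2)
    if (n_boxes == 1L || min(stats::dist(centers)) >= min_sep) {
      free <- cells[-pick, , drop = FALSE]
      d_min <- apply(free, 1, function(p) {
        min(sqrt(colSums((t(centers) - p)^2)))
      })
      filler <- free[which.max(d_min), ]
      out <- list(
        box_centers   = matrix(as.integer(centers), ncol = 2,
                               dimnames = list(NULL, c("x", "y"))),
        screen_bounds = c(xmin = 0, ymin = 0,
                          xmax = screen_px[1], ymax = screen_px[2]),
        aoi_radius    = aoi_radius,
        filler        = c(x = as.integer(filler[1]), y = as.integer(filler[2]))
      )
      class(out) <- "box_geometry"
      return(out)
    }
  }
  stop("geometry error: could not satisfy minimum box separation of ",
       min_sep, " px")
}

#' Construct a pop-up event sequence
#'
#' A sequence is an ordered list of pop-up events: at each event one of `K`
#' unique objects pops out from behind its box (750 ms up, 750 ms down by
#' default) with no overlap or delay, so onsets are 0, d, 2d, ... The
#' object-to-box binding is a bijection fixed for the whole sequence.
#'
#' @param object_ids integer vector of 0-based object indices, one per event.
#' @param geometry a `box_geometry` (see [random_box_geometry()]).
#' @param duration_ms event duration in ms (default 1500 = 750 up + 750 down).
#' @param id sequence identifier string.
#' @param n_objects number of distinct objects K (default 3; must equal the
#'   number of box locations in the default design).
#' @param loc_of_obj integer vector of length `n_objects`: 1-based box
#'   location bound to each object. Must be a permutation. Default identity.
#' @return object of class `sequence_spec`.
#' @export
make_sequence <- function(object_ids, geometry, duration_ms = 1500,
                          id = "seq", n_objects = 3L, loc_of_obj = NULL) {
  object_ids <- as.integer(object_ids)
  if (length(object_ids) < 1L) {
    stop("validation error: a sequence needs at least 1 event")
  }
  if (anyNA(object_ids) || any(object_ids < 0L) ||
      any(object_ids >= n_objects)) {
    stop("validation error: object ids must lie in [0, ", n_objects, ")")
  }
  if (!inherits(geometry, "box_geometry")) {
    stop("geometry error: `geometry` must be a box_geometry")
  }
  L <- nrow(geometry$box_centers)
  if (L < n_objects) {
    stop("geometry error: need at least ", n_objects, " distinct box centers")
  }
  if (anyDuplicated(geometry$box_centers)) {
    stop("geometry error: box centers must be distinct")
  }
  if (is.null(loc_of_obj)) loc_of_obj <- seq_len(n_objects)
  if (length(loc_of_obj) != n_objects ||
      !setequal(loc_of_obj, seq_len(n_objects))) {
    stop("validation error: loc_of_obj must be a permutation of 1..K")
  }
  stopifnot(duration_ms > 0)
  structure(
    list(sequence_id = as.character(id),
         n_objects   = as.integer(n_objects),
         n_locations = as.integer(L),
         object_ids  = object_ids,
         loc_of_obj  = as.integer(loc_of_obj),
         duration_ms = as.integer(duration_ms),
         geometry    = geometry),
    class = "sequence_spec")
}

#' Event table of a sequence
#'
#' @param seq a `sequence_spec`.
#' @return tibble with 0-based `index`, `object_id`, `location_id`,
#'   `onset_ms`, `duration_ms`; onsets are consecutive multiples of the
#'   event duration (events tile the trial exactly).
#' @export
sequence_events <- function(seq) {
  stopifnot(inherits(seq, "sequence_spec"))
  n <- length(seq$object_ids)
  tibble::tibble(
    index       = seq_len(n) - 1L,
    object_id   = seq$object_ids,
    location_id = seq$loc_of_obj[seq$object_ids + 1L] - 1L,
    onset_ms    = (seq_len(n) - 1L) * seq$duration_ms,
    duration_ms = seq$duration_ms)
}

#' Box center of each event's pop-up location
#' @param seq a `sequence_spec`.
#' @return n_events x 2 matrix of pixel coordinates.
#' @export
event_centers <- function(seq) {
  loc <- seq$loc_of_obj[seq$object_ids + 1L]
  seq$geometry$box_centers[loc, , drop = FALSE]
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("<sequence_spec> ", x$sequence_id, ": ", length(x$object_ids),
      " events, K = ", x$n_objects, ", duration ", x$duration_ms,
      " ms/event\n", sep = "")
  invisible(x)
}

#' Draw a random sequence of pop-up events
#'
#' Events are drawn i.i.d. from a categorical distribution over the K
#' objects (uniform unless `weights` is given); geometry and the
#' object-to-box binding are drawn fresh. Fully reproducible given `seed`.
#'
#' @param length number of events (>= 1).
#' @param n_objects number of distinct objects K.
#' @param seed integer seed; if `NULL` the ambient RNG stream is used.
#' @param weights optional non-negative per-object weights (not all zero).
#' @param duration_ms event duration in ms.
#' @param id sequence id.
#' @param aoi_radius AOI radius passed to [random_box_geometry()].
#' @return a `sequence_spec`.
#' @export
random_sequence <- function(length, n_objects = 3L, seed = NULL,
                            weights = NULL, duration_ms = 1500,
                            id = "seq", aoi_radius = 150) {
  stopifnot(length >= 1L)
  if (!is.null(weights)) {
    if (base::length(weights) != n_objects || any(weights < 0) ||
        sum(weights) == 0) {
      stop("validation error: weights must be non-negative, not all zero")
    }
  }
  draw <- function() {
    geometry <- random_box_geometry(n_boxes = n_objects,
                                    aoi_radius = aoi_radius)
    ids <- sample.int(n_objects, length, replace = TRUE, prob = weights) - 1L
    make_sequence(ids, geometry, duration_ms = duration_ms, id = id,
                  n_objects = n_objects,
                  loc_of_obj = sample.int(n_objects))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# (mean, SD, max) of a sequence's unigram surprisal trace -- the summary
# vector the maximin selection and the dispersion score operate on.
surprisal_summary <- function(seq, alpha = 1) {
  s <- unigram_surprisal_trace(seq, alpha = alpha)$surprisal_bits
  c(mean = mean(s), sd = stats::sd(s), max = max(s))
}

# Mean pairwise Euclidean distance between rows of a summary matrix.
summary_dispersion <- function(summaries) {
  if (nrow(summaries) < 2L) return(0)
  mean(stats::dist(summaries))
}

#' Generate a sequence set that maximizes surprisal spread
#'
#' Draws `pool_size` uniform random candidate sequences, summarizes each as
#' the (mean, SD, max) of its unigram surprisal trace, and greedily selects
#' `n_sequences` of them by maximin: starting from the first candidate, each
#' step adds the candidate with the largest minimum Euclidean distance to
#' the already-selected summaries (ties broken by lowest candidate index).
#' This concretely implements "spread the sequences' theoretical information
#' properties as far apart as possible", so that pop-up probabilities differ
#' markedly across sequences. The set's `dispersion_score` is the mean
#' pairwise distance between selected summary vectors.
#'
#' @param n_sequences number of sequences to return (default 80).
#' @param length events per sequence (default 30).
#' @param pool_size candidate pool size (>= n_sequences).
#' @param seed integer seed controlling all randomness of the call.
#' @param alpha Dirichlet pseudo-count used by the unigram scorer.
#' @param n_objects K (default 3).
#' @param duration_ms event duration in ms.
#' @param aoi_radius AOI radius for the per-sequence geometry.
#' @return object of class `sequence_set`: list with `sequences`,
#'   `generation_seed`, `dispersion_score`, and `pool_summaries` (the full
#'   candidate pool's summary matrix, kept for dispersion diagnostics).
#' @export
generate_sequence_set <- function(n_sequences = 80L, length = 30L,
                                  pool_size = 2L * n_sequences, seed = 1L,
                                  alpha = 1, n_objects = 3L,
                                  duration_ms = 1500, aoi_radius = 150) {
  if (pool_size < n_sequences) {
    stop("validation error: candidate pool (", pool_size,
         ") smaller than requested set (", n_sequences, ")")
  }
  withr::with_seed(seed, {
    pool <- lapply(seq_len(pool_size), function(i) {
      random_sequence(length, n_objects = n_objects, seed = NULL,
                      duration_ms = duration_ms,
                      id = sprintf("cand%03d", i), aoi_radius = aoi_radius)
    })
    summaries <- t(vapply(pool, surprisal_summary, numeric(3), alpha = alpha))
    sel <- select_maximin(summaries, n_sequences)
    sequences <- pool[sel]
    for (i in seq_along(sequences)) {
      sequences[[i]]$sequence_id <- sprintf("seq%03d", i)
    }
    structure(
      list(sequences        = sequences,
           generation_seed  = as.integer(seed),
           dispersion_score = summary_dispersion(summaries[sel, ,
                                                           drop = FALSE]),
           pool_summaries   = summaries),
      class = "sequence_set")
  })
}

# Greedy maximin subset selection on rows of `summaries`; deterministic,
# ties broken by lowest index. Returns selected row indices in pick order.
select_maximin <- function(summaries, n) {
  m <- nrow(summaries)
  stopifnot(n >= 1L, n <= m)
  selected <- 1L
  if (n == 1L) return(selected)
  # min distance from each candidate to the selected set, updated greedily
  d_min <- sqrt(colSums((t(summaries) - summaries[1L, ])^2))
  d_min[1L] <- -Inf
  for (k in 2L:n) {
    nxt <- which.max(d_min)  # which.max takes the first (lowest-index) tie
    selected <- c(selected, nxt)
    d_new <- sqrt(colSums((t(summaries) - summaries[nxt, ])^2))
    d_min <- pmin(d_min, d_new)
    d_min[nxt] <- -Inf
  }
  selected
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", length(x$sequences), " sequences, seed ",
      x$generation_seed, ", dispersion ",
      format(x$dispersion_score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write / read a sequence set as JSON
#'
#' The on-disk format is one object per file:
#' `{sequences: [{sequence_id, box_centers, events: [{index, object_id,
#' location_id, onset_ms, duration_ms}]}], generation_seed}` with 0-based
#' object and location ids.
#'
#' @param set a `sequence_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(set, path) {
  stopifnot(inherits(set, "sequence_set"))
  payload <- list(
    sequences = lapply(set$sequences, function(s) {
      list(sequence_id  = s$sequence_id,
           n_objects    = s$n_objects,
           box_centers  = apply(s$geometry$box_centers, 1, as.list),
           screen_bounds = as.list(s$geometry$screen_bounds),
           aoi_radius   = s$geometry$aoi_radius,
           filler       = as.list(s$geometry$filler),
           loc_of_obj   = s$loc_of_obj,
           events       = sequence_events(s))
    }),
    generation_seed  = set$generation_seed,
    dispersion_score = set$dispersion_score)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  sequences <- lapply(seq_len(nrow(raw$sequences)), function(i) {
    r <- raw$sequences[i, ]
    bc <- r$box_centers[[1]]
    centers <- if (is.data.frame(bc)) {
      m <- as.matrix(bc[, c("x", "y")])
      dimnames(m) <- list(NULL, c("x", "y"))
      m
    } else {
      matrix(unlist(bc), ncol = 2, byrow = TRUE,
             dimnames = list(NULL, c("x", "y")))
    }
    geometry <- structure(
      list(box_centers   = centers,
           screen_bounds = unlist(r$screen_bounds[[1]]),
           aoi_radius    = r$aoi_radius,
           filler        = unlist(r$filler[[1]])),
      class = "box_geometry")
    ev <- r$events[[1]]
    make_sequence(ev$object_id, geometry,
                  duration_ms = ev$duration_ms[1],
                  id = r$sequence_id, n_objects = r$n_objects,
                  loc_of_obj = unlist(r$loc_of_obj))
  })
  structure(list(sequences        = sequences,
                 generation_seed  = raw$generation_seed,
                 dispersion_score = raw$dispersion_score),
            class = "sequence_set")
}
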