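#' Default pipeline configuration
#'
#' All defaults mirror the target study design where one exists: 80
#' sequences of 3-box/3-object events, 1500 ms per event (750 ms up +
#' 750 ms down), 1000 Hz gaze sampling, a look-away threshold of 50% of
#' the event duration (750 ms), 5 subjects, uninformative (add-one)
#' Dirichlet prior. The look-away threshold is recomputed from the event
#' duration when left `NULL`.
#'
#' @param seed master seed for every source of randomness.
#' @param out_dir directory for pipeline artifacts.
#' @param ... overrides for any config entry.
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("gazeobserver_"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_subjects = 5L,
    n_sequences = 80L,
    length = 30L,
    duration_ms = 1500L,
    alpha = 1,
    aoi_radius = 150,
    lookaway_threshold_ms = NULL,   # NULL = duration_ms / 2
    predictive_window_ms = 1,
    min_dwell_ms = 0,
    model = "unigram",
    params = agent_params(),
    gaze_csv = NULL,                # path to real gaze data; NULL = simulate
    write_gaze = FALSE,             # gaze CSVs are large; opt in
    gams = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$lookaway_threshold_ms)) {
    cfg$lookaway_threshold_ms <- cfg$duration_ms / 2
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_md5 <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  plain <- cfg
  plain$params <- unclass(plain$params)
  jsonlite::write_json(unclass(plain), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}

#' Run the full pipeline end-to-end
#'
#' Stages: generate sequences -> score surprisal -> simulate agents (or
#' ingest a gaze CSV) -> extract measures -> fit regressions and GAMs ->
#' write artifacts. Every artifact is listed, with its md5, in a
#' `manifest.json` sidecar that also records the config and its hash and
#' the master seed, so any output can be traced to the exact invocation.
#' A failing stage aborts with a stage-labelled error; artifacts already
#' written are retained.
#'
#' @param config a `pipeline_config` from [default_config()].
#' @return invisibly, a list with the `analysis_bundle`, the event table,
#'   and the artifact paths.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  withr::with_seed(config$seed, {
    set <- stage("generate-sequences", {
      generate_sequence_set(
        n_sequences = config$n_sequences, length = config$length,
        seed = sample.int(1e9, 1L), alpha = config$alpha,
        duration_ms = config$duration_ms, aoi_radius = config$aoi_radius)
    })
    paths$sequences <- file.path(config$out_dir, "sequences.json")
    write_sequences(set, paths$sequences)

    traces <- stage("surprisal", score_sequence_set(set,
                                                    alpha = config$alpha))
    paths$surprisal <- file.path(config$out_dir, "surprisal.csv")
    write_surprisal(traces, paths$surprisal)

    if (is.null(config$gaze_csv)) {
      truth <- stage("simulate", {
        simulate_event_outcomes(set, config$params,
                                n_subjects = config$n_subjects,
                                model = config$model, traces = traces)
      })
      trials <- stage("simulate", render_gaze_streams(truth, set))
      paths$truth <- file.path(config$out_dir, "truth.csv")
      utils::write.csv(as.data.frame(truth), paths$truth,
                       row.names = FALSE)
    } else {
      trials <- stage("ingest-gaze", {
        if (!file.exists(config$gaze_csv)) {
          stop("gaze file not found: ", config$gaze_csv)
        }
        read_gaze(config$gaze_csv, set)
      })
    }
    if (isTRUE(config$write_gaze)) {
      paths$gaze <- file.path(config$out_dir, "gaze.csv")
      write_gaze(trials, paths$gaze)
    }

    events <- stage("measures", {
      build_event_table(trials, traces,
                        threshold_ms = config$lookaway_threshold_ms,
                        window_ms = config$predictive_window_ms,
                        min_dwell_ms = config$min_dwell_ms)
    })
    paths$events <- file.path(config$out_dir, "events.csv")
    utils::write.csv(as.data.frame(events), paths$events,
                     row.names = FALSE)

    bundle <- stage("fit", run_analysis(events, gams = config$gams))
    paths$coefficients <- file.path(config$out_dir, "coefficients.csv")
    utils::write.csv(as.data.frame(bundle$coefficients),
                     paths$coefficients, row.names = FALSE)

    manifest <- list(
      config = {
        p <- unclass(config)
        p$params <- unclass(p$params)
        p
      },
      config_md5 = config_md5(config),
      seed = config$seed,
      artifacts = lapply(paths, function(p) {
        list(path = basename(p), md5 = unname(tools::md5sum(p)))
      }))
    paths$manifest <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(list(bundle = bundle, events = events, set = set,
                   paths = paths))
  })
}
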