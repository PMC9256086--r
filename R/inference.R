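#' Add standardized surprisal terms to an event table
#'
#' Adds `surprisal_bits` (the chosen model's surprisal), `z` (standardized
#' to mean 0, SD 1) and `z2` (= z^2). By default standardization pools over
#' ALL event rows: sequences are always displayed in full, so the surprisal
#' scale is a property of the stimulus set, not of which rows survive the
#' look-away censoring; this also keeps the analysis-side z identical to
#' the simulator's generative z. `scope = "included"` restricts the
#' standardization pool to `included` rows instead.
#'
#' Standardization is affine, so the downstream coefficients are invariant
#' to the surprisal log base.
#'
#' @param event_table tibble from [build_event_table()] or
#'   [simulate_event_outcomes()].
#' @param model "unigram" or "transitional".
#' @param scope standardization pool: "all" (default) or "included".
#' @return the table with `surprisal_bits`, `z`, `z2` columns added.
#' @export
standardize_surprisal <- function(event_table,
                                  model = c("unigram", "transitional"),
                                  scope = c("all", "included")) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  s <- event_table[[paste0(model, "_surprisal_bits")]]
  if (is.null(s)) stop("validation error: missing surprisal column")
  pool <- if (scope == "included") s[event_table$included] else s
  if (length(pool) < 2L) {
    stop("validation error: not enough rows to standardize")
  }
  mu <- mean(pool)
  sdev <- stats::sd(pool)
  if (!is.finite(sdev) || sdev == 0) {
    stop("validation error: surprisal has zero variance")
  }
  event_table$surprisal_bits <- s
  event_table$z <- (s - mu) / sdev
  event_table$z2 <- event_table$z^2
  event_table
}

# Standardize the controlled-model covariates over the supplied rows:
# is_repeat as 0/1, distance and trial number z-scored for comparability
# of coefficient scales.
add_covariates <- function(tbl) {
  tbl$repeat01 <- as.numeric(tbl$is_repeat)
  tbl$distance_z <- as.numeric(scale(tbl$distance_px))
  tbl$trial_z <- as.numeric(scale(tbl$trial_number))
  tbl
}

# Select analysis rows for one outcome. RT rows need a positive RT (RT = 0
# means the gaze was already on the box at onset -- predictive rather than
# reactive -- and the log transform is undefined there); look-away rows are
# all included events; predictive rows are the defined first-appearance
# events. Controlled fits additionally need the distance covariate, absent
# at event 0.
analysis_rows <- function(tbl, outcome, controlled) {
  keep <- tbl$included
  if (outcome == "rt") {
    keep <- keep & !is.na(tbl$rt_ms) & tbl$rt_ms > 0
  } else if (outcome == "predictive") {
    keep <- keep & !is.na(tbl$predictive_look)
  }
  if (controlled) keep <- keep & !is.na(tbl$distance_px)
  tbl[keep, , drop = FALSE]
}

new_fit_result <- function(outcome, model, controlled, method,
                           coefficients, ri_var, n_obs, n_groups,
                           converged, message = NA_character_) {
  structure(list(outcome = outcome, model = model, controlled = controlled,
                 method = method, coefficients = coefficients,
                 random_intercept_variance = ri_var, n_obs = n_obs,
                 n_groups = n_groups, converged = converged,
                 message = message),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat("<model_fit_result> ", x$outcome, " ~ ", x$model,
      if (x$controlled) " (controlled)" else " (raw)",
      "  [", x$method, if (!x$converged) ", NOT converged", "]\n",
      sep = "")
  if (!is.null(x$coefficients)) {
    print(as.data.frame(x$coefficients), digits = 4)
    cat("random-intercept variance ",
        format(x$random_intercept_variance, digits = 4),
        ";  n = ", x$n_obs, ", groups = ", x$n_groups, "\n", sep = "")
  } else {
    cat("no estimates: ", x$message, "\n", sep = "")
  }
  invisible(x)
}

fit_formula <- function(lhs, quadratic, controlled, re = TRUE,
                        repeat_cov = TRUE) {
  # repeat status is structurally constant (FALSE) on first-appearance
  # rows, so predictive models omit it
  rhs <- c("z", if (quadratic) "z2",
           if (controlled) c(if (repeat_cov) "repeat01",
                             "distance_z", "trial_z"),
           if (re) "(1 | subject_id)")
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

lme4_converged <- function(m) {
  isTRUE(m@optinfo$conv$opt == 0) &&
    length(m@optinfo$conv$lme4$messages) == 0L
}

#' Mixed-effects linear regression of log RT on surprisal
#'
#' Fits `log RT ~ z + z^2 (+ covariates) + (1 | subject)` by maximum
#' likelihood on the included, positive-RT rows. p-values use the normal
#' approximation to the t statistic (consistent with large-sample reporting
#' of t's without degrees of freedom).
#'
#' @param event_table standardized event table (see
#'   [standardize_surprisal()]).
#' @param controlled include repeat/distance/trial-number covariates.
#' @param model surprisal model label carried into the result.
#' @return a `model_fit_result`.
#' @export
fit_mixed_linear <- function(event_table, controlled = FALSE,
                             model = "unigram") {
  if (is.null(event_table$z)) {
    stop("validation error: run standardize_surprisal() first")
  }
  dat <- analysis_rows(event_table, "rt", controlled)
  if (nrow(dat) < 10L) stop("validation error: too few RT rows")
  dat <- add_covariates(dat)
  dat$log_rt <- log(dat$rt_ms)
  m <- lme4::lmer(fit_formula("log_rt", TRUE, controlled), data = dat,
                  REML = FALSE)
  co <- as.data.frame(summary(m)$coefficients)
  coef_tab <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    se = co[, "Std. Error"], statistic = co[, "t value"],
    p = 2 * stats::pnorm(-abs(co[, "t value"])))
  vc <- as.data.frame(lme4::VarCorr(m))
  new_fit_result("rt", model, controlled, "lmer", coef_tab,
                 ri_var = vc$vcov[vc$grp == "subject_id"][1],
                 n_obs = nrow(dat),
                 n_groups = length(unique(dat$subject_id)),
                 converged = lme4_converged(m))
}

#' Mixed-effects logistic regression of look-away / predictive looking
#'
#' Look-away: `logit P(look-away) ~ z + z^2 (+ covariates) + (1 | subject)`
#' over one row per included event (outcome TRUE exactly at the trial's
#' look-away event), i.e. a discrete-time hazard model. Predictive looking:
#' `logit P(predictive) ~ z (+ covariates) + (1 | subject)` over defined
#' first-appearance rows -- linear surprisal term only.
#'
#' Fitted by Laplace-approximate ML ([lme4::glmer()]); if that errors, the
#' function falls back to an ordinary logistic fit with cluster-robust
#' (by-subject) standard errors and flags `converged = FALSE`. A degenerate
#' outcome (all TRUE or all FALSE) is flagged with no estimates.
#'
#' @param event_table standardized event table.
#' @param outcome "lookaway" or "predictive".
#' @param controlled include covariates.
#' @param model surprisal model label carried into the result.
#' @return a `model_fit_result`.
#' @export
fit_mixed_logistic <- function(event_table,
                               outcome = c("lookaway", "predictive"),
                               controlled = FALSE, model = "unigram") {
  outcome <- match.arg(outcome)
  if (is.null(event_table$z)) {
    stop("validation error: run standardize_surprisal() first")
  }
  dat <- analysis_rows(event_table, outcome, controlled)
  ycol <- if (outcome == "lookaway") "look_away" else "predictive_look"
  dat$y <- as.numeric(dat[[ycol]])
  if (nrow(dat) < 10L || length(unique(dat$y)) < 2L) {
    return(new_fit_result(outcome, model, controlled, "none", NULL,
                          NA_real_, nrow(dat),
                          length(unique(dat$subject_id)),
                          converged = FALSE,
                          message = "degenerate outcome: no variation"))
  }
  dat <- add_covariates(dat)
  quadratic <- outcome == "lookaway"
  form <- fit_formula("y", quadratic, controlled,
                      repeat_cov = outcome != "predictive")
  m <- tryCatch(
    lme4::glmer(form, data = dat, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa")),
    error = function(e) e)
  if (inherits(m, "error")) {
    # cluster-robust ordinary logistic fallback
    form_glm <- fit_formula("y", quadratic, controlled, re = FALSE,
                            repeat_cov = outcome != "predictive")
    g <- stats::glm(form_glm, data = dat, family = stats::binomial())
    V <- sandwich::vcovCL(g, cluster = dat$subject_id)
    est <- stats::coef(g)
    se <- sqrt(diag(V))
    coef_tab <- tibble::tibble(term = names(est), estimate = est,
                               se = se, statistic = est / se,
                               p = 2 * stats::pnorm(-abs(est / se)))
    return(new_fit_result(outcome, model, controlled, "glm_cluster",
                          coef_tab, NA_real_, nrow(dat),
                          length(unique(dat$subject_id)),
                          converged = FALSE, message = conditionMessage(m)))
  }
  co <- as.data.frame(summary(m)$coefficients)
  coef_tab <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    se = co[, "Std. Error"], statistic = co[, "z value"],
    p = co[, "Pr(>|z|)"])
  vc <- as.data.frame(lme4::VarCorr(m))
  new_fit_result(outcome, model, controlled, "glmer", coef_tab,
                 ri_var = vc$vcov[vc$grp == "subject_id"][1],
                 n_obs = nrow(dat),
                 n_groups = length(unique(dat$subject_id)),
                 converged = lme4_converged(m))
}

#' GAM smooth of a behavioural measure against surprisal
#'
#' Penalized-spline smooth of the outcome on raw surprisal (bits) --
#' identity link for log RT, logit link for the binary outcomes -- with the
#' smoothing parameter chosen by generalized cross-validation. The
#' controlled variant adds the covariates as linear terms (predictions are
#' made at their means). Returns the fitted curve on a grid spanning the
#' attained surprisal range with a pointwise 95% confidence band (and the
#' +/- 1 SE band), plus raw group means of three evenly spaced surprisal
#' bins with standard-error bars.
#'
#' @param event_table standardized event table.
#' @param outcome "rt", "lookaway" or "predictive".
#' @param controlled include covariates as linear terms.
#' @param model surprisal model label.
#' @param k spline basis dimension.
#' @param n_grid grid resolution of the returned curve.
#' @return object of class `gam_fit`: list with `grid` (x, fit, se, lo, hi
#'   on the response scale), `bins`, `interior_min`, `x_min`, the fitted
#'   mgcv model, and labels.
#' @export
fit_gam <- function(event_table, outcome = c("rt", "lookaway",
                                             "predictive"),
                    controlled = FALSE, model = "unigram", k = 10,
                    n_grid = 200L) {
  outcome <- match.arg(outcome)
  if (is.null(event_table$z)) {
    stop("validation error: run standardize_surprisal() first")
  }
  dat <- analysis_rows(event_table, outcome, controlled)
  if (nrow(dat) < 50L) {
    stop("validation error: need >= 50 rows for a GAM smooth, got ",
         nrow(dat))
  }
  dat <- add_covariates(dat)
  if (outcome == "rt") {
    dat$y <- log(dat$rt_ms)
    fam <- stats::gaussian()
  } else {
    ycol <- if (outcome == "lookaway") "look_away" else "predictive_look"
    dat$y <- as.numeric(dat[[ycol]])
    fam <- stats::binomial()
  }
  k_eff <- min(k, length(unique(dat$surprisal_bits)) - 1L)
  rhs <- paste0("s(surprisal_bits, k = ", k_eff, ")")
  if (controlled) rhs <- paste(rhs, "+ repeat01 + distance_z + trial_z")
  g <- mgcv::gam(stats::as.formula(paste("y ~", rhs)), data = dat,
                 family = fam, method = "GCV.Cp")
  xr <- range(dat$surprisal_bits)
  newd <- data.frame(surprisal_bits = seq(xr[1], xr[2],
                                          length.out = n_grid))
  if (controlled) {
    newd$repeat01 <- mean(dat$repeat01)
    newd$distance_z <- 0
    newd$trial_z <- 0
  }
  pr <- mgcv::predict.gam(g, newd, type = "link", se.fit = TRUE)
  inv <- fam$linkinv
  grid <- tibble::tibble(
    x = newd$surprisal_bits,
    fit = inv(as.numeric(pr$fit)),
    se_lo = inv(as.numeric(pr$fit) - as.numeric(pr$se.fit)),
    se_hi = inv(as.numeric(pr$fit) + as.numeric(pr$se.fit)),
    lo = inv(as.numeric(pr$fit) - 1.96 * as.numeric(pr$se.fit)),
    hi = inv(as.numeric(pr$fit) + 1.96 * as.numeric(pr$se.fit)))
  # three evenly spaced surprisal bins of the raw data
  breaks <- seq(xr[1], xr[2], length.out = 4L)
  bin <- cut(dat$surprisal_bits, breaks, include.lowest = TRUE)
  bins <- tibble::tibble(
    mid = (breaks[-4] + breaks[-1]) / 2,
    mean = as.numeric(tapply(dat$y, bin, mean)),
    se = as.numeric(tapply(dat$y, bin,
                           function(v) stats::sd(v) / sqrt(length(v)))),
    n = as.integer(table(bin)))
  i_min <- which.min(grid$fit)
  structure(list(outcome = outcome, model = model, controlled = controlled,
                 gam = g, grid = grid, bins = bins,
                 interior_min = i_min > 1L && i_min < nrow(grid),
                 x_min = grid$x[i_min]),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("<gam_fit> ", x$outcome, " ~ s(", x$model, " surprisal)",
      if (x$controlled) " (controlled)" else " (raw)",
      ": minimum at ", format(x$x_min, digits = 3), " bits",
      if (x$interior_min) " (interior)" else " (boundary)", "\n", sep = "")
  invisible(x)
}

#' Plot a GAM smooth with binned raw means
#'
#' @param x a `gam_fit`.
#' @param band "ci" for the pointwise 95% band (default) or "se" for +/- 1
#'   standard error.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.gam_fit <- function(x, band = c("ci", "se"), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  band <- match.arg(band)
  g <- x$grid
  if (band == "se") {
    g$lo <- g$se_lo
    g$hi <- g$se_hi
  }
  ylab <- switch(x$outcome, rt = "log RT",
                 lookaway = "P(look-away)", predictive = "P(predictive)")
  names(g)[names(g) == "x"] <- "xs"
  bins <- x$bins
  ggplot2::ggplot(g, ggplot2::aes(x = xs, y = fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      data = bins,
      ggplot2::aes(x = mid, y = mean, ymin = mean - se, ymax = mean + se)) +
    ggplot2::labs(x = paste(x$model, "surprisal (bits)"), y = ylab,
                  title = paste0(x$outcome,
                                 if (x$controlled) " (controlled)"
                                 else " (raw)")) +
    ggplot2::theme_minimal()
}

#' Run the full regression and GAM bundle
#'
#' Fits all 12 regressions (three outcomes x two observer models x
#' raw/controlled) and the matching GAM smooths. Per-fit errors are
#' collected, never aborting the bundle.
#'
#' @param event_table event table from [build_event_table()] or
#'   [simulate_event_outcomes()].
#' @param gams also fit GAM smooths (default TRUE).
#' @param scope standardization pool passed to [standardize_surprisal()].
#' @return object of class `analysis_bundle`: list with `fits` (named list
#'   of `model_fit_result`), `gams` (named list of `gam_fit` or error),
#'   `coefficients` (one long tibble), `errors`.
#' @export
run_analysis <- function(event_table, gams = TRUE, scope = "all") {
  if (is.null(event_table) || nrow(event_table) == 0L) {
    stop("validation error: empty event table")
  }
  fits <- list()
  gam_fits <- list()
  errors <- list()
  for (model in c("unigram", "transitional")) {
    tab <- standardize_surprisal(event_table, model = model, scope = scope)
    for (controlled in c(FALSE, TRUE)) {
      for (outcome in c("rt", "lookaway", "predictive")) {
        key <- paste(outcome, model,
                     if (controlled) "controlled" else "raw", sep = "_")
        res <- tryCatch({
          if (outcome == "rt") {
            fit_mixed_linear(tab, controlled = controlled, model = model)
          } else {
            fit_mixed_logistic(tab, outcome = outcome,
                               controlled = controlled, model = model)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[key]] <- conditionMessage(res)
        } else {
          fits[[key]] <- res
        }
        if (gams) {
          gres <- tryCatch(
            fit_gam(tab, outcome = outcome, controlled = controlled,
                    model = model),
            error = function(e) e)
          if (inherits(gres, "error")) {
            errors[[paste0("gam_", key)]] <- conditionMessage(gres)
          } else {
            gam_fits[[key]] <- gres
          }
        }
      }
    }
  }
  structure(list(fits = fits, gams = gam_fits,
                 coefficients = coefficient_table(fits), errors = errors),
            class = "analysis_bundle")
}

#' Long coefficient table of a set of fits
#'
#' @param fits named list of `model_fit_result`.
#' @return tibble with columns outcome, model, controlled, term, estimate,
#'   se, statistic, p, n_obs, n_groups, converged.
#' @export
coefficient_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (is.null(f$coefficients)) return(NULL)
    cbind(data.frame(outcome = f$outcome, model = f$model,
                     controlled = f$controlled),
          as.data.frame(f$coefficients),
          data.frame(n_obs = f$n_obs, n_groups = f$n_groups,
                     converged = f$converged))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!base::length(rows)) return(tibble::tibble())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("<analysis_bundle> ", base::length(x$fits), " fits, ",
      base::length(x$gams), " GAM smooths, ", base::length(x$errors),
      " errors\n", sep = "")
  invisible(x)
}
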