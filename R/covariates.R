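#' Flow metrics over the spawning window
#'
#' Summarizes a daily flow series to three metrics per reach-year over the
#' spawning window (default 01 July - 31 August, inclusive): maximum daily
#' flow, mean daily flow, and flow variability (coefficient of variation of
#' the window's daily flows, sample SD over mean). Every day of the window
#' must be present; gaps are an error.
#'
#' @param flow Data frame with columns reach_id, date (Date), flow_m3s.
#' @param window Character `c(start, end)` month-day bounds, `"MM-DD"`.
#' @return Data frame: reach_id, year, max_daily, mean_daily, cv_daily.
#' @examples
#' ds <- simulate_daily_series(2005, synthetic_truth(), seed = 1)
#' compute_flow_metrics(ds$flow)
#' @export
compute_flow_metrics <- function(flow, window = c("07-01", "08-31")) {
  if (!all(c("reach_id", "date", "flow_m3s") %in% names(flow)))
    stop("flow must carry reach_id, date, flow_m3s")
  flow$date <- as.Date(flow$date)
  if (any(flow$flow_m3s < 0, na.rm = TRUE)) stop("flow values must be >= 0")
  flow$year <- as.integer(format(flow$date, "%Y"))
  combos <- unique(flow[, c("reach_id", "year")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    r <- combos$reach_id[i]; y <- combos$year[i]
    lo <- as.Date(sprintf("%d-%s", y, window[1]))
    hi <- as.Date(sprintf("%d-%s", y, window[2]))
    if (is.na(lo) || is.na(hi) || lo > hi) stop("invalid or empty window")
    sub <- flow[flow$reach_id == r & flow$date >= lo & flow$date <= hi, ]
    expect_days <- as.integer(hi - lo) + 1L
    if (nrow(sub) != expect_days || anyNA(sub$flow_m3s))
      stop("flow series for ", r, " ", y, " does not cover the window (",
           nrow(sub), "/", expect_days, " days)")
    v <- sub$flow_m3s[order(sub$date)]
    m <- mean(v)
    if (m == 0) stop("all-zero flow in window for ", r, " ", y,
                     ": CV undefined at mean 0")
    data.frame(reach_id = r, year = y, max_daily = max(v), mean_daily = m,
               cv_daily = stats::sd(v) / m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$reach_id, out$year), , drop = FALSE]
}

#' Greedy pairwise-correlation screen
#'
#' Removes covariates until all pairwise absolute Pearson correlations are at
#' or below the threshold (default 0.6). At each step the worst offending
#' pair is found and the member with the larger mean absolute correlation to
#' all other remaining covariates is dropped (ties broken by dropping the
#' alphabetically later name). Constant columns, whose correlations are
#' undefined, are dropped first with a warning.
#'
#' @param covariates Data frame (numeric columns) with >= 2 covariates and
#'   >= 3 rows.
#' @param threshold Maximum tolerated absolute pairwise correlation.
#' @return Character vector of retained covariate names, with the dropped
#'   names in attribute `"dropped"`.
#' @export
screen_correlation <- function(covariates, threshold = 0.6) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least two covariates")
  if (nrow(covariates) < 3) stop("need at least three rows")
  dropped <- character(0)
  consts <- names(covariates)[vapply(covariates, function(v)
    stats::sd(v, na.rm = TRUE) == 0, logical(1))]
  if (length(consts)) {
    warning("dropping constant covariate(s): ", paste(consts, collapse = ", "))
    dropped <- consts
    covariates <- covariates[, setdiff(names(covariates), consts), drop = FALSE]
  }
  keep <- sort(names(covariates))
  while (length(keep) >= 2) {
    cm <- abs(stats::cor(covariates[, keep, drop = FALSE]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    pair <- which(cm == worst, arr.ind = TRUE)[1, ]
    cand <- keep[sort(unname(pair))]
    mean_r <- vapply(cand, function(nm) mean(cm[nm, setdiff(keep, nm)]), numeric(1))
    drop_nm <- if (abs(diff(mean_r)) < 1e-12) max(cand) else cand[which.max(mean_r)]
    dropped <- c(dropped, drop_nm)
    keep <- setdiff(keep, drop_nm)
  }
  structure(keep, dropped = dropped)
}

#' Backward stepwise temperature regression with deletion F-tests
#'
#' For each reach, fits daily water temperature as a linear function of the
#' climate covariates and repeatedly removes the least significant term: the
#' term whose single-term deletion F-test has the largest p-value, provided
#' that p-value is at or above `alpha` (default 0.15); ties are broken
#' alphabetically by term name. Elimination stops when every remaining term
#' has deletion p < alpha. The in-sample RMSE of the final model is reported.
#'
#' @param water_temp Data frame: reach_id, date, temp_c.
#' @param climate Data frame: date plus candidate covariate columns.
#' @param alpha F-test threshold for retention.
#' @return Named list of `"temp_model"` objects, one per reach: each holds
#'   `reach_id`, `retained_terms`, `coefficients`, `rmse_c`, `alpha`, the
#'   fitted `lm`, and the training covariate ranges.
#' @export
fit_temperature_stepwise <- function(water_temp, climate, alpha = 0.15) {
  if (!all(c("reach_id", "date", "temp_c") %in% names(water_temp)))
    stop("water_temp must carry reach_id, date, temp_c")
  if (!"date" %in% names(climate)) stop("climate must carry a date column")
  covars <- setdiff(names(climate), "date")
  if (length(covars) < 1) stop("climate must carry at least one covariate")
  models <- lapply(split(water_temp, water_temp$reach_id), function(wt) {
    dat <- merge(wt, climate, by = "date")
    if (nrow(dat) < length(covars) + 10)
      stop("need at least ", length(covars) + 10,
           " aligned observations for reach ", wt$reach_id[1])
    fit <- stats::lm(stats::reformulate(covars, response = "temp_c"), data = dat)
    if (any(is.na(stats::coef(fit)))) stop("rank-deficient climate design")
    repeat {
      terms_now <- attr(stats::terms(fit), "term.labels")
      if (length(terms_now) == 0) break
      d1 <- stats::drop1(fit, test = "F")
      p <- d1[["Pr(>F)"]][-1]
      names(p) <- rownames(d1)[-1]
      p[is.na(p)] <- 1              # deletion leaves RSS unchanged: droppable
      p <- p[order(-p, names(p))]   # worst p first; ties alphabetical
      if (p[1] < alpha) break
      fit <- stats::update(fit, stats::reformulate(
        if (length(terms_now) > 1) setdiff(terms_now, names(p)[1]) else "1",
        response = "temp_c"))
    }
    retained <- attr(stats::terms(fit), "term.labels")
    structure(list(
      reach_id = wt$reach_id[1],
      retained_terms = retained,
      coefficients = stats::coef(fit),
      rmse_c = sqrt(mean(stats::residuals(fit)^2)),
      alpha = alpha,
      fit = fit,
      train_range = vapply(dat[, covars, drop = FALSE], range, numeric(2))
    ), class = "temp_model")
  })
  models
}

#' @export
print.temp_model <- function(x, ...) {
  cat("Stream temperature model for reach ", x$reach_id, "\n",
      "  retained: ", if (length(x$retained_terms))
        paste(x$retained_terms, collapse = ", ") else "(intercept only)", "\n",
      "  RMSE: ", format(round(x$rmse_c, 3)), " degC (alpha = ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Backcast spawning-window stream temperatures from historic climate
#'
#' Applies a fitted reach temperature model to a historic daily climate
#' table and summarizes the daily predictions to mean, minimum, and maximum
#' over the spawning window for each year. Climate values outside the
#' model's training range trigger an extrapolation warning but predictions
#' proceed.
#'
#' @param model A `"temp_model"` from [fit_temperature_stepwise()].
#' @param climate Historic daily climate table (date + covariates).
#' @param window Month-day window bounds, as in [compute_flow_metrics()].
#' @return Data frame: reach_id, year, mean_c, min_c, max_c.
#' @export
backcast_temperature <- function(model, climate, window = c("07-01", "08-31")) {
  if (!inherits(model, "temp_model")) stop("model must be a temp_model")
  climate$date <- as.Date(climate$date)
  covars <- colnames(model$train_range)
  if (!all(covars %in% names(climate)))
    stop("historic climate lacks covariates: ",
         paste(setdiff(covars, names(climate)), collapse = ", "))
  years <- sort(unique(as.integer(format(climate$date, "%Y"))))
  out <- lapply(years, function(y) {
    lo <- as.Date(sprintf("%d-%s", y, window[1]))
    hi <- as.Date(sprintf("%d-%s", y, window[2]))
    sub <- climate[climate$date >= lo & climate$date <= hi, , drop = FALSE]
    if (nrow(sub) < as.integer(hi - lo) + 1L)
      stop("historic climate does not cover the ", y, " window")
    for (v in covars) {
      if (any(sub[[v]] < model$train_range[1, v] |
              sub[[v]] > model$train_range[2, v]))
        warning("extrapolating ", v, " outside the training range in ", y)
    }
    pred <- stats::predict(model$fit, newdata = sub)
    data.frame(reach_id = model$reach_id, year = y, mean_c = mean(pred),
               min_c = min(pred), max_c = max(pred), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary
#' least-squares regression of predictor j on all other predictors. Perfectly
#' collinear predictors report `Inf`.
#'
#' @param design Data frame or matrix of >= 2 numeric predictors, with more
#'   rows than predictors.
#' @return Named numeric vector of VIFs (each >= 1).
#' @examples
#' compute_vif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
compute_vif <- function(design) {
  x <- as.data.frame(design)
  if (ncol(x) < 2) stop("need at least two predictors")
  if (nrow(x) <= ncol(x)) stop("need more rows than predictors")
  vapply(names(x), function(nm) {
    fit <- stats::lm(stats::reformulate(setdiff(names(x), nm), response = nm),
                     data = x)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}
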