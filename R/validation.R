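# Four assessment metrics on observed vs predicted counts. Mean error is
# signed (observed - predicted); correlations return NA when either side is
# constant.
count_metrics <- function(obs, pred) {
  r <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_ else
    stats::cor(obs, pred)
  rho <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_ else
    stats::cor(obs, pred, method = "spearman")
  c(r = r, rho = rho,
    mean_error = mean(obs - pred),
    rmse = sqrt(mean((obs - pred)^2)))
}

# No-information benchmark for each metric, computed over the full grid of
# (observed_i, predicted_j) pairs, expressed on the loss scale used for the
# overfitting rate (1 - r, 1 - rho, |mean error|, rmse). The pairwise-grid
# correlation is identically zero (its covariance factorizes into two
# centered sums), so the correlation losses have a no-information value of 1;
# the grid mean error equals the apparent mean error.
noinfo_loss <- function(obs, pred) {
  grid_me <- mean(obs) - mean(pred)
  grid_rmse <- sqrt(mean(outer(obs, pred, `-`)^2))
  c(r = 1, rho = 1, mean_error = abs(grid_me), rmse = grid_rmse)
}

to_loss <- function(m) c(r = 1 - m[["r"]], rho = 1 - m[["rho"]],
                         mean_error = abs(m[["mean_error"]]),
                         rmse = m[["rmse"]])

#' 0.632+ bootstrap validation of a candidate count model
#'
#' Estimates optimism-corrected predictive performance: Pearson and Spearman
#' correlations, signed mean error (observed - predicted), and RMSE. For
#' each bootstrap resample (rows drawn with replacement; resamples with no
#' out-of-bag rows are redrawn) the model is refitted and evaluated on its
#' out-of-bag rows. Apparent and out-of-bag performance are blended with the
#' 0.632+ weight `w = 0.632 / (1 - 0.368 R)`, where the relative overfitting
#' rate `R = (loss_oob - loss_apparent) / (loss_noinfo - loss_apparent)` is
#' clipped to \[0, 1\] and the no-information loss comes from scoring
#' predictions against the pairwise-permuted responses. Correlation metrics
#' pass through the loss `1 - r` (and `1 - rho`); the signed mean error uses
#' `|mean error|` as its loss but is blended on the signed scale.
#'
#' @param spec A `"model_spec"`.
#' @param data Reach-year panel.
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param seed Integer seed.
#' @param ... Passed to [fit_nb()].
#' @return A one-row data frame of class `"validation_report"`: model, df,
#'   r_boot, rho_boot, mean_error_boot, rmse_boot, the apparent metrics, and
#'   bookkeeping (n_boot, n_skipped).
#' @export
bootstrap_632plus <- function(spec, data, n_boot = 200, seed = 1L, ...) {
  if (nrow(data) < 10) stop("need at least 10 rows for bootstrap validation")
  n_boot <- as.integer(n_boot)
  set.seed(derive_seed(seed, "validation"))

  full <- fit_nb(spec, data, ...)
  if (!isTRUE(full$converged)) stop("model ", spec$name, " does not fit the data")
  pred_app <- predict_counts(full, data, offset_km = data$length_km)$mean_count
  app <- count_metrics(data$peak_count, pred_app)
  gamma <- noinfo_loss(data$peak_count, pred_app)

  n <- nrow(data)
  oob_metrics <- matrix(NA_real_, n_boot, 4,
                        dimnames = list(NULL, c("r", "rho", "mean_error", "rmse")))
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) > 0) break
    }
    fit_b <- tryCatch(fit_nb(spec, data[idx, , drop = FALSE], ...),
                      error = function(e) NULL)
    if (is.null(fit_b) || !isTRUE(fit_b$converged)) { n_skipped <- n_skipped + 1L; next }
    pred_b <- tryCatch(
      predict_counts(fit_b, data[oob, , drop = FALSE],
                     offset_km = data$length_km[oob])$mean_count,
      error = function(e) NULL)
    if (is.null(pred_b)) { n_skipped <- n_skipped + 1L; next }
    oob_metrics[b, ] <- count_metrics(data$peak_count[oob], pred_b)
  }
  if (all(is.na(oob_metrics)))
    stop("every bootstrap resample failed for model ", spec$name)
  if (n_skipped > 0)
    warning(n_skipped, " of ", n_boot,
            " resamples skipped (non-convergence) for model ", spec$name)
  oob <- colMeans(oob_metrics, na.rm = TRUE)

  loss_app <- to_loss(app)
  loss_oob <- to_loss(oob)
  corrected <- vapply(c("r", "rho", "mean_error", "rmse"), function(m) {
    denom <- gamma[[m]] - loss_app[[m]]
    R <- if (!is.finite(denom) || denom <= 0) 0 else
      min(1, max(0, (loss_oob[[m]] - loss_app[[m]]) / denom))
    w <- 0.632 / (1 - 0.368 * R)
    (1 - w) * app[[m]] + w * oob[[m]]
  }, numeric(1))

  structure(data.frame(
    model = spec$name, model_num = spec$number, df = full$df,
    r_boot = corrected[["r"]], rho_boot = corrected[["rho"]],
    mean_error_boot = corrected[["mean_error"]], rmse_boot = corrected[["rmse"]],
    r_apparent = app[["r"]], rho_apparent = app[["rho"]],
    mean_error_apparent = app[["mean_error"]], rmse_apparent = app[["rmse"]],
    r_oob = oob[["r"]], rho_oob = oob[["rho"]],
    mean_error_oob = oob[["mean_error"]], rmse_oob = oob[["rmse"]],
    n_boot = n_boot, n_skipped = n_skipped,
    stringsAsFactors = FALSE
  ), class = c("validation_report", "data.frame"))
}

#' Out-of-sample assessment of a fitted count model
#'
#' Scores a fitted model against held-out reach-year rows that were not used
#' in model development: Pearson and Spearman correlations, signed mean error
#' (observed - predicted), and RMSE.
#'
#' @param fit A converged `"nb_fit"`.
#' @param holdout Held-out panel rows sharing the training schema.
#' @return Named numeric vector (r, rho, mean_error, rmse).
#' @export
out_of_sample_assess <- function(fit, holdout) {
  if (nrow(holdout) == 0) stop("empty holdout set")
  pred <- predict_counts(fit, holdout, offset_km = holdout$length_km)$mean_count
  count_metrics(holdout$peak_count, pred)
}

#' Select the best predictive model by mean metric rank
#'
#' Ranks every validated model on each of the four corrected metrics (higher
#' r and rho better; smaller |mean error| and RMSE better) and selects the
#' model with the lowest mean rank; ties go to the model with fewer df, then
#' alphabetically.
#'
#' @param reports Data frame of stacked [bootstrap_632plus()] rows (columns
#'   model, df, r_boot, rho_boot, mean_error_boot, rmse_boot).
#' @return The selected model's name.
#' @export
select_best_predictive <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 1) stop("no validation reports supplied")
  ranks <- cbind(rank(-reports$r_boot), rank(-reports$rho_boot),
                 rank(abs(reports$mean_error_boot)), rank(reports$rmse_boot))
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, reports$df, reports$model)
  reports$model[ord[1]]
}

#' Detection-bias check: total peak density against escapement
#'
#' Regresses annual total peak density (summed peak counts over all study
#' reaches per total stream km) on escapement by ordinary least squares, and
#' tabulates residuals by the year's survey condition (the worst condition
#' reported among the year's reaches). A strong positive relationship
#' supports treating detection efficiency as approximately constant across
#' years.
#'
#' @param panel Reach-year panel with peak_count, length_km, escapement,
#'   survey_condition, year.
#' @return List: `fit` (the lm), `r_squared`, `p_value`, `slope`, and
#'   `residuals_by_condition` (year, condition, residual).
#' @export
detection_bias_check <- function(panel) {
  need <- c("year", "peak_count", "length_km", "escapement", "survey_condition")
  if (!all(need %in% names(panel)))
    stop("panel lacks columns: ", paste(setdiff(need, names(panel)), collapse = ", "))
  years <- sort(unique(panel$year))
  if (length(years) < 3) stop("need at least 3 years with counts and escapement")
  severity <- c(good = 1, fair = 2, undefined = 3, poor = 4)
  ann <- do.call(rbind, lapply(years, function(y) {
    sub <- panel[panel$year == y, ]
    data.frame(year = y,
               density = sum(sub$peak_count) / sum(sub$length_km),
               escapement = sub$escapement[1],
               condition = names(which.max(severity[unique(sub$survey_condition)])),
               stringsAsFactors = FALSE)
  }))
  fit <- stats::lm(density ~ escapement, data = ann)
  sm <- summary(fit)
  list(fit = fit,
       r_squared = sm$r.squared,
       p_value = stats::coef(sm)["escapement", "Pr(>|t|)"],
       slope = stats::coef(fit)[["escapement"]],
       residuals_by_condition = data.frame(
         year = ann$year, condition = ann$condition,
         residual = stats::residuals(fit), stringsAsFactors = FALSE))
}
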