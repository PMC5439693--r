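#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the study defaults:
#' 1000 RSF permutations, 200 validation bootstraps, 10,000 isodars, VIF
#' screen at 3, correlation screen at 0.6, stepwise alpha 0.15, 90%
#' confidence intervals, and the 01 July - 31 August spawning window.
#'
#' @param out_dir Directory for stage outputs (created if missing).
#' @param seed Master integer seed; each stage derives its own substream.
#' @param n_subreaches,n_used Riverscape size and number of used sub-reaches.
#' @param n_years,escapement_range,start_year Count-panel settings.
#' @param holdout_years Additional years simulated for out-of-sample
#'   assessment (0 to skip).
#' @param logger_years Years of daily series used to train the temperature
#'   models (the remaining panel years are backcast).
#' @param n_boot_rsf,n_boot_val,n_iso Resampling sizes.
#' @param vif_max,corr_max,stepwise_alpha,ci_level Screening thresholds and
#'   interval level.
#' @param flow_covariate `"mean_daily"` or `"max_daily"`: which flow metric
#'   enters the count models as FLOW.
#' @param orientation Isodar regression orientation.
#' @param window Spawning window month-day bounds.
#' @param min_subreach_length_m Minimum sub-reach length entering reach RSF
#'   means.
#' @param validate_top How many top-ranked models get 0.632+ validation.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("spawnsel-run-"),
                            seed = 1L,
                            n_subreaches = 2536, n_used = 176,
                            n_years = 10, escapement_range = c(2000, 12000),
                            start_year = 1986L, holdout_years = 4,
                            logger_years = 2,
                            n_boot_rsf = 1000, n_boot_val = 200, n_iso = 10000,
                            vif_max = 3, corr_max = 0.6, stepwise_alpha = 0.15,
                            ci_level = 0.90,
                            flow_covariate = c("mean_daily", "max_daily"),
                            orientation = c("periphery_on_core",
                                            "core_on_periphery"),
                            window = c("07-01", "08-31"),
                            min_subreach_length_m = 50,
                            validate_top = 4) {
  flow_covariate <- match.arg(flow_covariate)
  orientation <- match.arg(orientation)
  stopifnot(n_subreaches >= 8, n_used >= 1, n_years >= 3,
            n_boot_rsf >= 1, n_boot_val >= 1, n_iso >= 100,
            vif_max > 1, corr_max > 0, corr_max < 1,
            stepwise_alpha > 0, stepwise_alpha < 1,
            ci_level > 0, ci_level < 1, validate_top >= 1,
            holdout_years >= 0, logger_years >= 1)
  wdates <- as.Date(paste0("2000-", window))
  if (anyNA(wdates) || wdates[1] >= wdates[2]) stop("window start must precede end")
  rm(wdates)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full habitat-selection analysis pipeline
#'
#' Executes the stages in dependency order on synthetic data: simulate
#' (riverscape, redd counts, count panel, daily series) -> RSF (bootstrap
#' fit, scores, reach means) -> covariates (flow metrics, correlation
#' screen, stepwise temperature models, backcasts, VIF report) ->
#' count-model (15-model set, AICc ranking) -> validation (0.632+ for the
#' top models, out-of-sample assessment, detection-bias check) -> isodar
#' (habitat predictions, bootstrap isodars, classification, observed
#' isodars). Every stage writes its tables as CSV into `config$out_dir`
#' together with a `provenance.json` sidecar (configuration, seed, package
#' version), so a rerun with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param truth Optional [synthetic_truth()] record (defaults to
#'   `synthetic_truth(seed = config$seed)`).
#' @return Invisibly, a list with every stage result (`truth`, `riverscape`,
#'   `subreaches`, `panel`, `holdout`, `daily`, `rsf`, `reach_rsf`,
#'   `flow_metrics`, `temp_models`, `temp_metrics`, `vif`, `fits`,
#'   `ranking`, `validation`, `best_model`, `detection`, `preds`, `isodar`,
#'   `verdict`, `observed`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), truth = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (is.null(truth)) truth <- synthetic_truth(seed = config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  message("stage: simulate")
  rs <- generate_riverscape(config$n_subreaches, truth, seed = config$seed)
  sr <- simulate_redds(rs, truth, n_used = config$n_used, seed = config$seed)
  n_total_years <- config$n_years + config$holdout_years
  panel_all <- simulate_panel(n_total_years, truth,
                              escapement_range = config$escapement_range,
                              seed = config$seed,
                              start_year = config$start_year)
  fit_years <- sort(unique(panel_all$year))[seq_len(config$n_years)]
  panel <- panel_all[panel_all$year %in% fit_years, ]
  holdout <- panel_all[!panel_all$year %in% fit_years, ]
  daily <- simulate_daily_series(sort(unique(panel_all$year)), truth,
                                 seed = config$seed)
  write_stage_csv(sr, out("subreaches.csv"))
  write_stage_csv(panel, out("panel.csv"))
  if (nrow(holdout)) write_stage_csv(holdout, out("panel_holdout.csv"))
  write_stage_csv(daily$climate, out("climate.csv"))
  write_stage_csv(daily$water_temp, out("water_temp.csv"))
  write_stage_csv(daily$flow, out("flow.csv"))
  jsonlite::write_json(
    list(rsf_beta = as.list(truth$rsf_beta), rsf_intercept = truth$rsf_intercept,
         count_beta = as.list(truth$count_beta), theta = truth$theta,
         temp_coefs = as.list(truth$temp_coefs), noise_sd = truth$noise_sd,
         seed = truth$seed),
    out("truth.json"), auto_unbox = TRUE, digits = NA)

  message("stage: rsf")
  used <- sr[sr$used, ]
  pool <- sr[sr$available, ]
  rsf <- fit_rsf_bootstrap(used, pool, n_boot = config$n_boot_rsf,
                           seed = config$seed)
  scores <- predict_rsf_scores(rsf, sr)
  reach_rsf <- summarize_reach_rsf(sr, scores,
                                   min_length_m = config$min_subreach_length_m)
  write_stage_csv(data.frame(term = colnames(rsf$coef_draws),
                             median = rsf$coef_median,
                             lo90 = rsf$coef_ci90["lo90", ],
                             hi90 = rsf$coef_ci90["hi90", ]),
                  out("rsf_coefficients.csv"))
  write_stage_csv(data.frame(id = sr$id, score = scores), out("rsf_scores.csv"))
  write_stage_csv(reach_rsf, out("reach_rsf.csv"))

  message("stage: covariates")
  flow_metrics <- compute_flow_metrics(daily$flow, window = config$window)
  retained <- screen_correlation(daily$climate[, setdiff(names(daily$climate),
                                                         "date")],
                                 threshold = config$corr_max)
  climate_screened <- daily$climate[, c("date", retained)]
  logger <- sort(unique(panel_all$year))[seq_len(config$logger_years)]
  wt_train <- daily$water_temp[
    as.integer(format(daily$water_temp$date, "%Y")) %in% logger, ]
  temp_models <- fit_temperature_stepwise(wt_train, climate_screened,
                                          alpha = config$stepwise_alpha)
  temp_metrics <- do.call(rbind, lapply(temp_models, backcast_temperature,
                                        climate = climate_screened,
                                        window = config$window))
  flow_col <- config$flow_covariate
  message("flow covariate entering the count models: ", flow_col)
  covars <- merge(flow_metrics, temp_metrics, by = c("reach_id", "year"))
  covars <- merge(covars, reach_rsf[, c("reach_id", "mean_rsf")], by = "reach_id")
  vif <- compute_vif(covars[, c("mean_rsf", "min_c", flow_col)])
  if (any(vif >= config$vif_max))
    warning("VIF screen flags: ",
            paste(names(vif)[vif >= config$vif_max], collapse = ", "))
  write_stage_csv(flow_metrics, out("flow_metrics.csv"))
  write_stage_csv(do.call(rbind, lapply(temp_models, function(m)
    data.frame(reach_id = m$reach_id,
               retained = paste(m$retained_terms, collapse = "+"),
               rmse_c = m$rmse_c, stringsAsFactors = FALSE))),
    out("temp_models.csv"))
  write_stage_csv(temp_metrics, out("temp_metrics.csv"))
  write_stage_csv(data.frame(term = names(vif), vif = unname(vif)),
                  out("vif_report.csv"))

  message("stage: count-model")
  merge_covars <- function(p) {
    p$mean_rsf <- NULL; p$temp_min <- NULL; p$flow_avg <- NULL
    p <- merge(p, covars[, c("reach_id", "year", "mean_rsf", "min_c",
                             "mean_daily", "max_daily")],
               by = c("reach_id", "year"))
    p$temp_min <- p$min_c
    p
  }
  panel_fit <- merge_covars(panel)
  cs <- build_candidate_set()
  fits <- lapply(cs, fit_nb, data = panel_fit, flow_covariate = flow_col)
  ranking <- rank_models(fits)
  write_stage_csv(ranking, out("model_ranking.csv"))
  write_stage_csv(do.call(rbind, lapply(fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    data.frame(model = f$spec$name, term = names(f$coefficients),
               estimate = unname(f$coefficients), theta = f$theta,
               stringsAsFactors = FALSE)
  })), out("model_fits.csv"))

  message("stage: validate")
  top <- ranking$Model_num[seq_len(min(config$validate_top, nrow(ranking)))]
  reports <- do.call(rbind, lapply(top, function(num) {
    bootstrap_632plus(cs[[num]], panel_fit, n_boot = config$n_boot_val,
                      seed = config$seed + num, flow_covariate = flow_col)
  }))
  best_name <- select_best_predictive(reports)
  best_spec <- cs[[reports$model_num[reports$model == best_name]]]
  best_fit <- fits[[best_spec$number]]
  oos <- NULL
  if (nrow(holdout) > 0) {
    hold_fit <- merge_covars(holdout)
    oos <- out_of_sample_assess(best_fit, hold_fit)
    reports$r_oos <- reports$rho_oos <- reports$mean_error_oos <-
      reports$rmse_oos <- NA_real_
    sel <- reports$model == best_name
    reports[sel, c("r_oos", "rho_oos", "mean_error_oos", "rmse_oos")] <-
      as.list(oos)
  }
  detection <- detection_bias_check(panel)
  write_stage_csv(reports, out("validation_report.csv"))

  message("stage: isodar (best model: ", best_name, ")")
  esc <- sort(unique(panel$escapement))
  preds <- predict_habitat_counts(best_fit, esc,
                                  offset_km = mean(study_reach_table()$length_km))
  iso <- bootstrap_isodars(preds, n_iso = config$n_iso, seed = config$seed,
                           orientation = config$orientation,
                           ci_level = config$ci_level)
  verdict <- classify_selection(iso, best_spec)
  observed <- list(
    C1_P1 = observed_isodar(panel, "C1", "P1"),
    C2_P2 = observed_isodar(panel, "C2", "P2"))
  write_stage_csv(data.frame(iteration = seq_along(iso$slopes),
                             slope = iso$slopes, intercept = iso$intercepts),
                  out("isodar_draws.csv"))
  write_stage_csv(data.frame(
    slope_mean = iso$slope_mean, intercept_mean = iso$intercept_mean,
    slope_lo90 = iso$slope_ci90[1], slope_hi90 = iso$slope_ci90[2],
    intercept_lo90 = iso$intercept_ci90[1], intercept_hi90 = iso$intercept_ci90[2],
    quantity_differs = verdict$quantity_differs,
    quality_differs = verdict$quality_differs,
    selection_regime = verdict$selection_regime,
    orientation = iso$orientation), out("isodar_summary.csv"))

  prov <- config
  class(prov) <- NULL
  prov$out_dir <- NULL
  jsonlite::write_json(
    list(config = prov, package_version = as.character(utils::packageVersion("spawnsel")),
         generated = "synthetic"),
    out("provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(truth = truth, riverscape = rs, subreaches = sr,
                 panel = panel, panel_fit = panel_fit, holdout = holdout,
                 daily = daily, rsf = rsf, reach_rsf = reach_rsf,
                 flow_metrics = flow_metrics, temp_models = temp_models,
                 temp_metrics = temp_metrics, vif = vif, fits = fits,
                 ranking = ranking, validation = reports,
                 best_model = best_name, oos = oos, detection = detection,
                 preds = preds, isodar = iso, verdict = verdict,
                 observed = observed, out_dir = config$out_dir))
}

#' Reduce raw aerial survey records to reach-year peak counts
#'
#' Takes the maximum count per reach and year (with its survey condition) as
#' the reach-year data point. Years in which not every study reach was
#' surveyed are flagged `in_fit = FALSE`: they are excluded from model
#' development but retained for out-of-sample assessment.
#'
#' @param raw Data frame of individual surveys: reach_id, year, date, count,
#'   condition.
#' @return Data frame: reach_id, year, peak_count, survey_condition, in_fit.
#' @export
reduce_to_peak_counts <- function(raw) {
  need <- c("reach_id", "year", "count", "condition")
  if (!all(need %in% names(raw)))
    stop("raw surveys need columns: ", paste(need, collapse = ", "))
  combos <- unique(raw[, c("reach_id", "year")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- raw[raw$reach_id == combos$reach_id[i] & raw$year == combos$year[i], ]
    j <- which.max(sub$count)
    data.frame(reach_id = sub$reach_id[1], year = sub$year[1],
               peak_count = sub$count[j], survey_condition = sub$condition[j],
               stringsAsFactors = FALSE)
  }))
  n_reaches <- length(unique(raw$reach_id))
  per_year <- table(out$year)
  complete <- as.integer(names(per_year)[per_year == n_reaches])
  out$in_fit <- out$year %in% complete
  dropped <- setdiff(unique(out$year), complete)
  if (length(dropped))
    message("years lacking all ", n_reaches, " reaches (held out): ",
            paste(sort(dropped), collapse = ", "))
  out <- out[order(out$year, out$reach_id), ]
  rownames(out) <- NULL
  out
}
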