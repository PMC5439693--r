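#' Predicted core and periphery counts for isodar construction
#'
#' Predicts the expected peak count and its standard error in each habitat
#' type (core, periphery) at each escapement value, using a common offset
#' length (by default the 21.8 km mean of the four study-reach lengths) so
#' the two habitats are compared over equal stream lengths. The fitted model
#' must include the core/periphery contrast. Any density-independent
#' covariates in the model are held at their training means.
#'
#' @param best_fit A converged `"nb_fit"` whose spec includes CP.
#' @param escapements Numeric vector of escapement values (non-empty).
#' @param offset_km Common offset stream length (default 21.8).
#' @return Data frame: escapement, habitat, mean_count, se_count, offset_km.
#' @export
predict_habitat_counts <- function(best_fit, escapements, offset_km = 21.8) {
  if (!inherits(best_fit, "nb_fit") || !isTRUE(best_fit$converged))
    stop("best_fit must be a converged nb_fit")
  if (!grepl("CP", best_fit$spec$rhs))
    stop("model ", best_fit$spec$name, " lacks the core/periphery term")
  if (length(escapements) < 1) stop("escapements must be non-empty")
  if (offset_km <= 0) stop("offset_km must be > 0")
  tr <- best_fit$glm$model
  nd <- expand.grid(escapement = escapements,
                    habitat = c("core", "periphery"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in c("RSF", "TEMP", "FLOW")) {
    if (v %in% names(tr)) {
      col <- switch(v, RSF = "mean_rsf", TEMP = "temp_min", FLOW = best_fit$flow_covariate)
      nd[[col]] <- mean(tr[[v]])
    }
  }
  pred <- predict_counts(best_fit, nd, offset_km = offset_km)
  data.frame(escapement = pred$escapement, habitat = pred$habitat,
             mean_count = pred$mean_count, se_count = pred$se_count,
             offset_km = offset_km, stringsAsFactors = FALSE)
}

# Truncated-at-zero normal draws by inverse CDF; sd = 0 collapses to the
# (non-negative part of the) mean.
rtnorm0 <- function(n, mean, sd) {
  out <- numeric(n)
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(0, mean[pos], sd[pos])
    out[pos] <- stats::qnorm(stats::runif(sum(pos), plo, 1), mean[pos], sd[pos])
  }
  if (any(!pos)) out[!pos] <- pmax(0, mean[!pos])
  out
}

#' Bootstrap isodar analysis from predicted habitat counts
#'
#' Propagates count-prediction uncertainty into the isodar: in each of
#' `n_iso` iterations one count per (escapement, habitat) is drawn from a
#' Normal distribution with the predicted mean and standard error, truncated
#' at zero, and an ordinary least-squares isodar is fitted across escapement
#' values — by default periphery counts regressed on core counts, so a slope
#' below 1 means core density rises faster with total abundance (higher core
#' quality). Slope and intercept draws are summarized by their means and 90%
#' percentile intervals, and the confidence-interval rules for habitat
#' quantity (intercept vs 0) and quality (slope vs 1) are evaluated.
#'
#' @param preds Output of [predict_habitat_counts()]: >= 3 escapement values
#'   with one row per (escapement, habitat).
#' @param n_iso Number of bootstrap isodars (default 10000, minimum 100).
#' @param seed Integer seed.
#' @param orientation `"periphery_on_core"` (default) or
#'   `"core_on_periphery"`: which habitat supplies the regression response.
#' @param ci_level Confidence level for the percentile intervals (default
#'   0.90).
#' @return An object of class `"isodar_result"`: slope/intercept draws,
#'   their means and percentile CIs, the CI-rule booleans
#'   (`quantity_differs`, `quality_differs`), the orientation, and the
#'   fraction of draws affected by zero truncation.
#' @export
bootstrap_isodars <- function(preds, n_iso = 10000, seed = 1L,
                              orientation = c("periphery_on_core",
                                              "core_on_periphery"),
                              ci_level = 0.90) {
  orientation <- match.arg(orientation)
  need <- c("escapement", "habitat", "mean_count", "se_count")
  if (!all(need %in% names(preds))) stop("preds lacks required columns")
  if (any(preds$se_count < 0)) stop("se_count must be >= 0")
  wide <- merge(
    preds[preds$habitat == "core", c("escapement", "mean_count", "se_count")],
    preds[preds$habitat == "periphery", c("escapement", "mean_count", "se_count")],
    by = "escapement", suffixes = c("_core", "_periphery"))
  m <- nrow(wide)
  if (m < 3) stop("need at least 3 escapement values with both habitats")
  n_iso <- as.integer(n_iso)
  if (n_iso < 100) stop("n_iso must be >= 100")
  set.seed(derive_seed(seed, "isodar"))

  draw <- function(mean, sd) matrix(
    rtnorm0(m * n_iso, rep(mean, n_iso), rep(sd, n_iso)), nrow = m)
  core <- draw(wide$mean_count_core, wide$se_count_core)
  peri <- draw(wide$mean_count_periphery, wide$se_count_periphery)
  if (orientation == "periphery_on_core") { x <- core; y <- peri }
  else { x <- peri; y <- core }

  xbar <- colMeans(x); ybar <- colMeans(y)
  sxx <- colSums(x^2) - m * xbar^2
  sxy <- colSums(x * y) - m * xbar * ybar
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  if (all(is.na(slope))) stop("degenerate isodar: no variation in the predictor")
  intercept <- ybar - slope * xbar
  keep <- is.finite(slope)
  slope <- slope[keep]; intercept <- intercept[keep]

  alpha <- (1 - ci_level) / 2
  slope_ci <- unname(stats::quantile(slope, c(alpha, 1 - alpha)))
  int_ci <- unname(stats::quantile(intercept, c(alpha, 1 - alpha)))
  trunc_frac <- mean(stats::pnorm(
    0, c(wide$mean_count_core, wide$mean_count_periphery),
    pmax(c(wide$se_count_core, wide$se_count_periphery), 1e-300)))

  structure(list(
    slopes = slope, intercepts = intercept,
    slope_mean = mean(slope), intercept_mean = mean(intercept),
    slope_ci90 = slope_ci, intercept_ci90 = int_ci,
    ci_level = ci_level,
    quantity_differs = int_ci[1] > 0 || int_ci[2] < 0,
    quality_differs = slope_ci[1] > 1 || slope_ci[2] < 1,
    orientation = orientation, n_iso = n_iso,
    truncation_frac = trunc_frac,
    n_escapements = m
  ), class = "isodar_result")
}

#' @export
print.isodar_result <- function(x, ...) {
  cat("Isodar bootstrap (", length(x$slopes), " isodars, ", x$orientation,
      ")\n", sep = "")
  cat(sprintf("  slope     %7.3f  %d%% CI [%.3f, %.3f]  quality differs: %s\n",
              x$slope_mean, round(100 * x$ci_level), x$slope_ci90[1],
              x$slope_ci90[2], x$quality_differs))
  cat(sprintf("  intercept %7.3f  %d%% CI [%.3f, %.3f]  quantity differs: %s\n",
              x$intercept_mean, round(100 * x$ci_level), x$intercept_ci90[1],
              x$intercept_ci90[2], x$quantity_differs))
  invisible(x)
}

#' Classify the habitat-selection regime from an isodar result
#'
#' Applies the confidence-interval rules: habitat quantity differs between
#' habitats when the intercept CI excludes zero, habitat quality differs
#' when the slope CI excludes one (intervals are closed, so a bound exactly
#' touching the critical value does not exclude it). When the structure of
#' the best count model is supplied, the selection regime is read from it:
#' an additive model (no interactions, no quadratic escapement term) is
#' consistent with ideal free habitat selection and a linear isodar, while
#' interactions or nonlinearity suggest despotic (pre-emptive) selection.
#'
#' @param result An `"isodar_result"`, or any list with `slope_ci90` and
#'   `intercept_ci90` elements of the form `c(lo, hi)`.
#' @param best_spec Optional `"model_spec"` of the best predictive model.
#' @return List: `quantity_differs`, `quality_differs`, `selection_regime`.
#' @examples
#' classify_selection(list(intercept_ci90 = c(-76.4, 297.2),
#'                         slope_ci90 = c(-0.105, 0.780)))
#' @export
classify_selection <- function(result, best_spec = NULL) {
  sci <- result$slope_ci90
  ici <- result$intercept_ci90
  if (is.null(sci) || is.null(ici) || length(sci) != 2 || length(ici) != 2 ||
      sci[1] > sci[2] || ici[1] > ici[2])
    stop("result must carry ordered slope_ci90 and intercept_ci90 bounds")
  regime <- if (is.null(best_spec)) NA_character_
  else if (spec_is_additive(best_spec)) "IFD-consistent linear isodar"
  else "IDD-suggestive"
  list(quantity_differs = unname(ici[1] > 0 || ici[2] < 0),
       quality_differs = unname(sci[1] > 1 || sci[2] < 1),
       selection_regime = regime)
}

#' Deterministic isodar from observed counts
#'
#' Converts observed peak counts of one core and one periphery reach to
#' densities (counts per stream km), pairs them by year, and fits a single
#' ordinary least-squares isodar (periphery density on core density). No
#' bootstrap: the returned CIs are zero-width at the point estimates.
#'
#' @param panel Reach-year panel.
#' @param core_reach,periphery_reach Reach ids to pair (e.g. `"C1"`, `"P1"`).
#' @return An `"isodar_result"` with single slope/intercept values.
#' @export
observed_isodar <- function(panel, core_reach, periphery_reach) {
  cc <- panel[panel$reach_id == core_reach, c("year", "peak_count", "length_km")]
  pp <- panel[panel$reach_id == periphery_reach, c("year", "peak_count", "length_km")]
  both <- merge(cc, pp, by = "year", suffixes = c("_core", "_periphery"))
  if (nrow(both) < 3)
    stop("fewer than 3 shared years between ", core_reach, " and ", periphery_reach)
  x <- both$peak_count_core / both$length_km_core
  y <- both$peak_count_periphery / both$length_km_periphery
  if (stats::var(x) == 0) stop("core densities constant: slope undefined")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  structure(list(
    slopes = slope, intercepts = intercept,
    slope_mean = slope, intercept_mean = intercept,
    slope_ci90 = c(slope, slope), intercept_ci90 = c(intercept, intercept),
    ci_level = NA_real_,
    quantity_differs = NA, quality_differs = NA,
    orientation = "periphery_on_core", n_iso = 1L,
    truncation_frac = 0, n_escapements = nrow(both),
    core_reach = core_reach, periphery_reach = periphery_reach
  ), class = "isodar_result")
}
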