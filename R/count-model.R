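#' The 15-model candidate set for peak spawner counts
#'
#' Builds the canonical candidate set of negative binomial models for peak
#' spawner counts: five density-dependent (DD) models built from escapement
#' (E), its quadratic, and the core/periphery contrast (CP); four
#' density-independent (DI) models built from the RSF score, minimum stream
#' temperature (TEMP) and the flow covariate (FLOW); and six combined (BOTH)
#' models with DI-by-escapement or DI-by-CP interactions. Every model carries
#' an offset of `log(length_km)` so coefficients describe counts per unit
#' stream length. A `*` in a model name denotes an interaction fitted with
#' its main effects.
#'
#' @return An object of class `"candidate_set"`: a list of 15 `"model_spec"`
#'   records (number, name, type, rhs formula text).
#' @examples
#' cs <- build_candidate_set()
#' length(cs)
#' cs[[2]]$name
#' @export
build_candidate_set <- function() {
  spec <- function(number, name, type, rhs)
    structure(list(number = number, name = name, type = type, rhs = rhs),
              class = "model_spec")
  structure(list(
    spec(1L,  "E",               "DD",   "E"),
    spec(2L,  "E+CP",            "DD",   "E + CP"),
    spec(3L,  "E*CP",            "DD",   "E * CP"),
    spec(4L,  "E+E^2+CP",        "DD",   "E + I(E^2) + CP"),
    spec(5L,  "E*CP+E^2",        "DD",   "E * CP + I(E^2)"),
    spec(6L,  "TEMP",            "DI",   "TEMP"),
    spec(7L,  "FLOW",            "DI",   "FLOW"),
    spec(8L,  "RSF",             "DI",   "RSF"),
    spec(9L,  "RSF+TEMP+FLOW",   "DI",   "RSF + TEMP + FLOW"),
    spec(10L, "FLOW*E",          "BOTH", "FLOW * E"),
    spec(11L, "TEMP*E",          "BOTH", "TEMP * E"),
    spec(12L, "RSF*E",           "BOTH", "RSF * E"),
    spec(13L, "FLOW*CP+E*CP",    "BOTH", "FLOW * CP + E * CP"),
    spec(14L, "TEMP*CP+E*CP",    "BOTH", "TEMP * CP + E * CP"),
    spec(15L, "RSF*CP+E*CP",     "BOTH", "RSF * CP + E * CP")
  ), class = "candidate_set")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d (%s): peak_count ~ %s + offset(log(length_km)) [%s]\n",
              x$number, x$name, x$rhs, x$type))
  invisible(x)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set of", length(x), "negative binomial count models\n")
  for (s in x) print(s)
  invisible(x)
}

# Does a spec's name announce an interaction or a nonlinear (quadratic)
# escapement term? Used for the habitat-selection regime reading.
spec_is_additive <- function(spec) {
  !grepl("\\*", spec$name) && !grepl("\\^2", spec$name)
}

# Map a reach-year panel to the model frame the candidate formulas expect.
# E is the (optionally z-scored) escapement; CP a core/periphery factor with
# periphery as the reference level.
build_model_frame <- function(data, standardize_escapement = TRUE,
                              center = NULL, scale = NULL,
                              flow_covariate = "flow_avg") {
  need <- c("peak_count", "escapement", "habitat", "length_km")
  if (!all(need %in% names(data)))
    stop("panel lacks required columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  if (any(data$length_km <= 0)) stop("length_km must be > 0")
  if (standardize_escapement) {
    if (is.null(center)) center <- mean(data$escapement)
    if (is.null(scale)) {
      scale <- stats::sd(data$escapement)
      if (!is.finite(scale) || scale == 0) scale <- 1
    }
    e <- (data$escapement - center) / scale
  } else {
    center <- 0; scale <- 1
    e <- data$escapement
  }
  mf <- data.frame(
    peak_count = data$peak_count,
    E = e,
    CP = factor(data$habitat, levels = c("periphery", "core")),
    length_km = data$length_km
  )
  if ("mean_rsf" %in% names(data)) mf$RSF <- data$mean_rsf
  if ("temp_min" %in% names(data)) mf$TEMP <- data$temp_min
  if (flow_covariate %in% names(data)) mf$FLOW <- data[[flow_covariate]]
  attr(mf, "escapement_center") <- center
  attr(mf, "escapement_scale") <- scale
  mf
}

#' Fit one candidate negative binomial count model
#'
#' Maximum-likelihood negative binomial regression (log link,
#' quadratic-variance parameterization) of peak counts on the spec's terms
#' with an offset of `log(length_km)`. Escapement enters as a z-score by
#' default (a linear reparameterization that leaves the likelihood and AICc
#' ranking unchanged) to stabilize the quadratic fits.
#'
#' @param spec A `"model_spec"` from [build_candidate_set()].
#' @param data Reach-year panel (see [simulate_panel()] for the schema).
#' @param standardize_escapement Standardize E before fitting (default TRUE).
#' @param flow_covariate Panel column supplying FLOW (default `"flow_avg"`,
#'   the window mean; set to e.g. `"max_daily"` after merging flow metrics).
#' @return An object of class `"nb_fit"`: spec, coefficients, theta, loglik,
#'   df (coefficients + dispersion), n, aicc, converged flag, and the
#'   underlying `glm.nb` fit.
#' @export
fit_nb <- function(spec, data, standardize_escapement = TRUE,
                   flow_covariate = "flow_avg") {
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec")
  mf <- build_model_frame(data, standardize_escapement,
                          flow_covariate = flow_covariate)
  vars <- all.vars(stats::as.formula(paste("~", spec$rhs)))
  if (!all(vars %in% names(mf)))
    stop("panel lacks covariates for model ", spec$name, ": ",
         paste(setdiff(vars, names(mf)), collapse = ", "))
  form <- stats::as.formula(
    paste("peak_count ~", spec$rhs, "+ offset(log(length_km))"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = mf)),
    error = function(e) NULL)
  theta_hat <- if (!is.null(fit)) fit$theta else NULL
  if (is.null(fit)) {
    # dispersion estimate diverged (counts show no overdispersion): take the
    # Poisson limit with a fixed large dispersion, still counted in df
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = mf,
                                  family = MASS::negative.binomial(1e6))),
      error = function(e) NULL)
    theta_hat <- 1e6
  }
  converged <- !is.null(fit) && isTRUE(fit$converged)
  if (is.null(fit)) {
    return(structure(list(spec = spec, converged = FALSE), class = "nb_fit"))
  }
  ll <- stats::logLik(fit)
  k <- length(stats::coef(fit)) + 1L     # coefficients + dispersion
  n <- stats::nobs(fit)
  if (n <= length(stats::coef(fit)) + 1)
    stop("too few observations (n = ", n, ") for model ", spec$name)
  structure(list(
    spec = spec,
    coefficients = stats::coef(fit),
    theta = theta_hat,
    loglik = as.numeric(ll),
    df = as.integer(k),
    n = as.integer(n),
    aicc = aicc(as.numeric(ll), k, n),
    converged = converged,
    escapement_center = attr(mf, "escapement_center"),
    escapement_scale = attr(mf, "escapement_scale"),
    flow_covariate = flow_covariate,
    standardize_escapement = standardize_escapement,
    glm = fit
  ), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Model", x$spec$name, "- did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("Model %d (%s): logLik %.2f, df %d, AICc %.1f, theta %.2f\n",
              x$spec$number, x$spec$name, x$loglik, x$df, x$aicc, x$theta))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts every
#' estimated parameter including the negative binomial dispersion.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (coefficients + dispersion).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-255.72, 4, 40)
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc with Akaike weights
#'
#' `delta_i = AICc_i - min(AICc)`; `weight_i = exp(-delta_i/2) /
#' sum(exp(-delta_j/2))`. Models are sorted by ascending AICc, ties broken
#' by smaller df and then by name. Accepts either a list of [fit_nb()]
#' results (non-converged fits are excluded with a warning) or a data frame
#' of already-summarized fits with columns `name`, `loglik`, `df` (and
#' optionally `number`, `type`) plus the common `n`.
#'
#' @param fits List of `"nb_fit"` objects, or a data frame of (name, loglik,
#'   df) rows.
#' @param n Number of observations; required for the data frame form,
#'   otherwise taken from the fits.
#' @return Data frame sorted by AICc: Model, Model_num, Type, df, logLik,
#'   AICc, delta, weight.
#' @export
rank_models <- function(fits, n = NULL) {
  if (is.data.frame(fits)) {
    if (is.null(n)) stop("n is required when ranking summarized fits")
    tab <- data.frame(
      Model = fits$name,
      Model_num = if ("number" %in% names(fits)) fits$number else NA_integer_,
      Type = if ("type" %in% names(fits)) fits$type else NA_character_,
      df = fits$df,
      logLik = fits$loglik,
      stringsAsFactors = FALSE
    )
    tab$AICc <- mapply(aicc, tab$logLik, tab$df, MoreArgs = list(n = n))
  } else {
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(ok)) stop("no converged fits to rank")
    if (any(!ok))
      warning("excluding ", sum(!ok), " non-converged model(s): ",
              paste(vapply(fits[!ok], function(f) f$spec$name, character(1)),
                    collapse = ", "))
    fits <- fits[ok]
    tab <- data.frame(
      Model = vapply(fits, function(f) f$spec$name, character(1)),
      Model_num = vapply(fits, function(f) f$spec$number, integer(1)),
      Type = vapply(fits, function(f) f$spec$type, character(1)),
      df = vapply(fits, function(f) f$df, integer(1)),
      logLik = vapply(fits, function(f) f$loglik, numeric(1)),
      AICc = vapply(fits, function(f) f$aicc, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab <- tab[order(tab$AICc, tab$df, tab$Model), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Predict counts with delta-method standard errors
#'
#' Response-scale predicted mean counts and standard errors from a fitted
#' candidate model at new covariate values and a common offset length. The
#' linear predictor's SE comes from the coefficient covariance; on the
#' response scale the delta method gives `SE = mu * SE_link`.
#'
#' @param fit A converged `"nb_fit"`.
#' @param newdata Data frame with the panel schema columns the model needs
#'   (escapement, habitat, and any DI covariates).
#' @param offset_km Offset stream length(s) in km, > 0 (recycled).
#' @return Data frame `newdata` plus `mean_count` and `se_count`.
#' @export
predict_counts <- function(fit, newdata, offset_km) {
  if (!inherits(fit, "nb_fit") || !isTRUE(fit$converged))
    stop("fit must be a converged nb_fit")
  if (any(offset_km <= 0)) stop("offset_km must be > 0")
  nd <- newdata
  nd$length_km <- offset_km
  if (!"peak_count" %in% names(nd)) nd$peak_count <- 0L
  mf <- build_model_frame(nd, fit$standardize_escapement,
                          center = fit$escapement_center,
                          scale = fit$escapement_scale,
                          flow_covariate = fit$flow_covariate)
  pr <- stats::predict(fit$glm, newdata = mf, type = "link", se.fit = TRUE)
  out <- newdata
  out$mean_count <- exp(pr$fit)
  out$se_count <- exp(pr$fit) * pr$se.fit
  out
}
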