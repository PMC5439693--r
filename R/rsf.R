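#' Bootstrap used/available resource selection function for redd counts
#'
#' Fits the regression-style RSF: in each of `n_boot` permutations, all used
#' sub-reaches (observed redd counts >= 1) are combined with an equal-sized
#' random draw (without replacement) from the available pool, the pool rows
#' are assigned a pseudo-response of zero redds, and a negative binomial
#' regression of redd count on VWI + BFW + GRAD is fitted. Per-coefficient
#' medians and 90% percentile intervals over the permutations summarize the
#' selection surface.
#'
#' Permutations whose fit fails to converge are skipped with a warning; the
#' run aborts if more than 10% fail.
#'
#' @param used Data frame of used sub-reaches (redd_count >= 1) with columns
#'   vwi, bfw, grad, redd_count.
#' @param available_pool Data frame of available sub-reaches (same attribute
#'   columns), at least as many rows as `used`.
#' @param n_boot Number of permutations (default 1000).
#' @param seed Integer seed.
#'
#' @return An object of class `"rsf_model"`: list with `coef_draws` (n_boot x
#'   4 matrix, NA rows for skipped permutations removed), `coef_median`,
#'   `coef_ci90` (2 x 4, rows lo/hi), `n_boot`, `n_failed`, `seed`.
#' @seealso [predict_rsf_scores()], [summarize_reach_rsf()]
#' @export
fit_rsf_bootstrap <- function(used, available_pool, n_boot = 1000, seed = 1L) {
  need <- c("vwi", "bfw", "grad")
  if (nrow(used) == 0) stop("no used sub-reaches supplied")
  if (!all(need %in% names(used)) || !all(need %in% names(available_pool)))
    stop("used and available_pool must carry vwi, bfw, grad columns")
  if (!"redd_count" %in% names(used)) stop("used must carry redd_count")
  if (anyNA(used[, need]) || anyNA(available_pool[, need]))
    stop("attribute fields must be complete")
  if (nrow(available_pool) < nrow(used))
    stop("available pool smaller than the used set")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  set.seed(derive_seed(seed, "rsf"))

  n_used <- nrow(used)
  used_dat <- data.frame(redd_count = as.integer(used$redd_count),
                         vwi = used$vwi, bfw = used$bfw, grad = used$grad)
  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("(Intercept)", "vwi", "bfw", "grad")))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(available_pool), n_used, replace = FALSE)
    avail <- data.frame(redd_count = 0L,
                        vwi = available_pool$vwi[idx],
                        bfw = available_pool$bfw[idx],
                        grad = available_pool$grad[idx])
    dat <- rbind(used_dat, avail)
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(redd_count ~ vwi + bfw + grad, data = dat)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- stats::coef(fit)
  }
  if (n_failed > 0.10 * n_boot)
    stop("more than 10% of RSF permutations failed to converge (",
         n_failed, "/", n_boot, ")")
  if (n_failed > 0L)
    warning(n_failed, " of ", n_boot, " RSF permutations failed and were skipped")
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ci <- apply(draws, 2, stats::quantile, probs = c(0.05, 0.95))
  rownames(ci) <- c("lo90", "hi90")
  structure(list(coef_draws = draws,
                 coef_median = apply(draws, 2, stats::median),
                 coef_ci90 = ci,
                 n_boot = n_boot, n_failed = n_failed, seed = as.integer(seed)),
            class = "rsf_model")
}

#' @export
print.rsf_model <- function(x, ...) {
  cat("Bootstrap resource selection function (", nrow(x$coef_draws),
      " successful permutations)\n", sep = "")
  tab <- rbind(median = x$coef_median, x$coef_ci90)
  print(round(t(tab), 4))
  invisible(x)
}

#' Predict 0-1 RSF suitability scores
#'
#' Expected redd counts from the median bootstrap coefficients, rescaled by
#' dividing by the maximum predicted count over the scored set, so all scores
#' lie in \[0, 1\] and at least one equals 1. Dividing by the maximum (rather
#' than min-max scaling) preserves the zero point of intensity of use.
#'
#' @param model An `"rsf_model"` from [fit_rsf_bootstrap()].
#' @param subreaches Data frame with vwi, bfw, grad.
#' @return Numeric vector of scores in \[0, 1\], one per row.
#' @export
predict_rsf_scores <- function(model, subreaches) {
  if (!inherits(model, "rsf_model")) stop("model must be an rsf_model")
  if (nrow(subreaches) == 0) stop("no sub-reaches to score")
  need <- c("vwi", "bfw", "grad")
  if (!all(need %in% names(subreaches))) stop("missing attribute columns")
  x <- cbind(1, as.matrix(subreaches[, need]))
  mu <- exp(drop(x %*% model$coef_median[c("(Intercept)", need)]))
  mu / max(mu)
}

#' Study-reach means of nested sub-reach RSF scores
#'
#' Aggregates sub-reach scores to one mean and SD per study reach. A
#' minimum-length filter (default 50 m) is applied before aggregation, so
#' only sub-reaches of 50-200 m contribute to reach summaries even though
#' shorter segments are scored.
#'
#' @param subreaches Sub-reach data frame with `study_reach` and `length_m`.
#' @param scores Numeric score vector aligned with `subreaches` rows.
#' @param min_length_m Minimum sub-reach length retained (default 50).
#' @return Data frame: reach_id, mean_rsf, sd_rsf, n_subreaches.
#' @export
summarize_reach_rsf <- function(subreaches, scores, min_length_m = 50) {
  if (length(scores) != nrow(subreaches))
    stop("scores must align with subreaches rows")
  keep <- subreaches$study_reach != "none" & subreaches$length_m >= min_length_m
  if (!any(keep)) stop("no study-reach sub-reaches pass the length filter")
  sr <- subreaches$study_reach[keep]
  sc <- scores[keep]
  reaches <- sort(unique(subreaches$study_reach[subreaches$study_reach != "none"]))
  missing <- setdiff(reaches, unique(sr))
  if (length(missing))
    stop("study reach with no scored members after length filter: ",
         paste(missing, collapse = ", "))
  out <- data.frame(
    reach_id = reaches,
    mean_rsf = vapply(reaches, function(r) mean(sc[sr == r]), numeric(1)),
    sd_rsf = vapply(reaches, function(r) {
      s <- stats::sd(sc[sr == r]); if (is.na(s)) 0 else s
    }, numeric(1)),
    n_subreaches = vapply(reaches, function(r) sum(sr == r), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
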