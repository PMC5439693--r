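#' Simulate the reach-by-year peak spawner count panel
#'
#' One row per study reach and year. Basin escapement is drawn for each year
#' from a truncated lognormal spanning `escapement_range`; the peak count for
#' each reach-year is negative binomial with log-mean
#' `b0 + b_E * (escapement/1000) + b_core * is_core + log(length_km)` and
#' dispersion `theta`, where the coefficients come from `truth$count_beta`.
#' Reach stream lengths are fixed (10.6-40.5 km, mean 21.8 km). The panel
#' also carries plausible density-independent covariates per reach-year
#' (mean RSF score, window minimum temperature, window mean flow) that have
#' no effect on the generated counts, plus a survey-condition label.
#'
#' @param n_years Number of years, >= 3.
#' @param truth A [synthetic_truth()] record.
#' @param escapement_range `(low, high)` bounds for annual escapement (fish).
#'   `low == high` gives every year the same escapement.
#' @param seed Integer seed.
#' @param start_year First calendar year of the panel.
#'
#' @return Data frame with columns reach_id, habitat, year, peak_count,
#'   escapement, length_km, mean_rsf, temp_min, flow_avg, survey_condition.
#' @examples
#' panel <- simulate_panel(10, synthetic_truth(), seed = 1)
#' nrow(panel)  # 40 = 10 years x 4 reaches
#' @export
simulate_panel <- function(n_years, truth,
                           escapement_range = c(2000, 12000),
                           seed = truth$seed, start_year = 1986L) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  n_years <- as.integer(n_years)
  if (is.na(n_years) || n_years < 3L) stop("n_years must be >= 3")
  lo <- escapement_range[1]; hi <- escapement_range[2]
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || lo > hi)
    stop("escapement_range must be finite with low <= high")
  set.seed(derive_seed(seed, "panel"))

  years <- seq.int(start_year, length.out = n_years)
  if (lo == hi) {
    escapement <- rep(lo, n_years)
  } else {
    # lognormal truncated to [lo, hi] by inverse CDF
    mlog <- mean(log(c(lo, hi)))
    slog <- (log(hi) - log(lo)) / 4
    plo <- stats::plnorm(lo, mlog, slog)
    phi <- stats::plnorm(hi, mlog, slog)
    escapement <- stats::qlnorm(stats::runif(n_years, plo, phi), mlog, slog)
  }

  reaches <- study_reach_table()
  rsf_base <- c(C1 = 0.259, C2 = 0.210, P1 = 0.120, P2 = 0.079)
  temp_base <- c(C1 = 5.9, C2 = 5.2, P1 = 4.6, P2 = 4.0)
  flow_base <- c(C1 = 60, C2 = 48, P1 = 40, P2 = 34)

  grid <- expand.grid(year = years, reach_id = reaches$reach_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(grid, reaches, by = "reach_id", sort = FALSE)
  grid <- grid[order(grid$year, grid$reach_id), ]
  grid$escapement <- escapement[match(grid$year, years)]

  b <- truth$count_beta
  eta <- b[["intercept"]] + b[["escapement"]] * grid$escapement / 1000 +
    b[["core"]] * (grid$habitat == "core") + log(grid$length_km)
  grid$peak_count <- stats::rnbinom(nrow(grid), size = truth$theta, mu = exp(eta))
  grid$mean_rsf <- unname(rsf_base[grid$reach_id])
  grid$temp_min <- unname(temp_base[grid$reach_id]) + stats::rnorm(nrow(grid), 0, 0.6)
  grid$flow_avg <- unname(flow_base[grid$reach_id]) *
    exp(stats::rnorm(nrow(grid), 0, 0.15))
  grid$survey_condition <- sample(c("good", "fair", "poor", "undefined"),
                                  nrow(grid), replace = TRUE,
                                  prob = c(0.5, 0.3, 0.1, 0.1))
  rownames(grid) <- NULL
  grid[, c("reach_id", "habitat", "year", "peak_count", "escapement",
           "length_km", "mean_rsf", "temp_min", "flow_avg", "survey_condition")]
}
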