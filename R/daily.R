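#' Simulate daily climate, water temperature, and flow series
#'
#' Emulates the daily inputs the covariate stage consumes: five climate
#' covariates from a valley climate station (mean air temperature, maximum
#' humidity, square-root-transformed minimum humidity, barometric pressure,
#' wind velocity), per-reach daily water temperature generated as the truth
#' record's linear function of the climate covariates plus Normal noise and
#' a fixed upstream cooling offset, and per-reach daily flow built from a
#' snowmelt-plus-rain seasonal baseflow with exponentially decaying storm
#' pulses (non-negative by construction).
#'
#' @param years Integer vector of calendar years to cover (full years daily).
#' @param truth A [synthetic_truth()] record; `temp_coefs` and `noise_sd`
#'   drive the water-temperature series.
#' @param seed Integer seed.
#' @param climate_cor Target Pearson correlation between the maximum-humidity
#'   and minimum-humidity covariates (the pair the collinearity screen is
#'   pointed at). Other pairs are only weakly correlated.
#'
#' @return A list of data frames: `climate` (date + 5 covariates),
#'   `water_temp` (reach_id, date, temp_c), `flow` (reach_id, date,
#'   flow_m3s).
#' @examples
#' ds <- simulate_daily_series(2005:2006, synthetic_truth(), seed = 1)
#' range(ds$flow$flow_m3s)
#' @export
simulate_daily_series <- function(years, truth, seed = truth$seed,
                                  climate_cor = 0.3) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  years <- as.integer(years)
  if (length(years) < 1L || anyNA(years)) stop("years must be a non-empty integer vector")
  if (abs(climate_cor) >= 1) stop("climate_cor must lie in (-1, 1)")
  set.seed(derive_seed(seed, "daily"))

  dates <- seq.Date(as.Date(sprintf("%d-01-01", min(years))),
                    as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  ar1 <- function(n, rho = 0.7, sd = 1) {
    z <- numeric(n)
    z[1] <- stats::rnorm(1, 0, sd)
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in seq_len(n - 1L)) z[i + 1L] <- rho * z[i] + innov[i]
    z
  }

  season <- cos(2 * pi * (doy - 196) / 365.25)   # peaks mid-July
  air_temp <- -3 + 20 * season + ar1(n, sd = 3)
  z_hmax <- ar1(n, sd = 1)
  humid_max <- pmin(100, pmax(20, 82 + 8 * z_hmax - 3 * season))
  # minimum humidity correlated with maximum humidity at the target r
  z_hmin <- climate_cor * z_hmax +
    sqrt(1 - climate_cor^2) * ar1(n, sd = 1)
  humid_min <- pmin(100, pmax(5, 45 + 10 * z_hmin - 4 * season))
  humid_min_sqrt <- sqrt(humid_min)
  pressure <- 1012 + ar1(n, sd = 4)
  wind <- exp(log(8) + 0.25 * ar1(n, sd = 1))

  climate <- data.frame(date = dates, air_temp = air_temp,
                        humid_max = humid_max,
                        humid_min_sqrt = humid_min_sqrt,
                        pressure = pressure, wind = wind)

  reaches <- study_reach_table()
  cool <- c(C1 = 0, C2 = -0.4, P1 = -0.8, P2 = -1.2)  # upstream cooling, degC
  cf <- truth$temp_coefs
  base_temp <- cf[["intercept"]] +
    cf[["air_temp"]] * air_temp + cf[["humid_max"]] * humid_max +
    cf[["humid_min_sqrt"]] * humid_min_sqrt + cf[["pressure"]] * pressure +
    cf[["wind"]] * wind

  water_temp <- do.call(rbind, lapply(reaches$reach_id, function(r) {
    data.frame(reach_id = r, date = dates,
               temp_c = base_temp + cool[[r]] +
                 stats::rnorm(n, 0, truth$noise_sd))
  }))

  # seasonal baseflow: snowmelt freshet (~May) + late-summer rain shoulder
  baseflow <- 18 + 55 * exp(-((doy - 140) / 28)^2) + 14 * exp(-((doy - 235) / 45)^2)
  scale_r <- c(C1 = 1, C2 = 0.8, P1 = 0.55, P2 = 0.4)
  n_storm <- stats::rpois(1, n / 18)
  storm_t <- sort(stats::runif(n_storm, 1, n))
  storm_a <- stats::rexp(max(n_storm, 1), rate = 1 / 35)
  pulses <- numeric(n)
  if (n_storm > 0) {
    for (s in seq_len(n_storm)) {
      idx <- which(seq_len(n) >= storm_t[s])
      pulses[idx] <- pulses[idx] + storm_a[s] * exp(-(idx - storm_t[s]) / 4)
    }
  }
  flow_common <- (baseflow + pulses) * exp(stats::rnorm(n, 0, 0.05))

  flow <- do.call(rbind, lapply(reaches$reach_id, function(r) {
    data.frame(reach_id = r, date = dates,
               flow_m3s = pmax(0, scale_r[[r]] * flow_common))
  }))

  rownames(water_temp) <- rownames(flow) <- NULL
  list(climate = climate, water_temp = water_temp, flow = flow)
}
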