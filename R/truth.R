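#' Ground-truth parameter set for the synthetic riverscape generator
#'
#' Bundles every parameter the generator treats as "true": the redd-count
#' resource-selection coefficients, the peak-count model coefficients, the
#' negative binomial dispersion, and the climate-to-water-temperature
#' regression. Downstream recovery tests compare fitted coefficients against
#' these values.
#'
#' @param rsf_beta Named numeric triple: log-scale effects of valley width
#'   index (`vwi`), bankfull width in m (`bfw`) and channel gradient in %
#'   (`grad`) on expected redd count. Defaults are the sign pattern a
#'   spawning salmon RSF shows in confined boreal rivers: wide channels
#'   selected, steep confined channels avoided.
#' @param rsf_intercept Log-scale intercept of the redd-count model.
#' @param count_beta Named numeric triple `(intercept, escapement, core)`:
#'   log-scale coefficients of the peak-count model. The escapement effect is
#'   per 1000 returning spawners; `core` is the additive log-effect of being
#'   in a core rather than periphery reach. The linear predictor always adds
#'   `log(length_km)` as an offset.
#' @param theta Negative binomial dispersion (size) parameter, > 0. Applies
#'   to both redd counts and peak counts.
#' @param temp_coefs Named numeric vector `(intercept, air_temp, humid_max,
#'   humid_min_sqrt, pressure, wind)` mapping daily climate covariates to
#'   daily water temperature (degrees C).
#' @param noise_sd Residual SD (degrees C) of daily water temperature around
#'   the climate regression, >= 0.
#' @param seed Integer seed stored with the truth record.
#'
#' @return An object of class `"synthetic_truth"` (a validated list).
#' @examples
#' truth <- synthetic_truth()
#' truth$theta
#' @export
synthetic_truth <- function(rsf_beta = c(vwi = -0.008, bfw = 0.069, grad = -0.590),
                            rsf_intercept = -1.0,
                            count_beta = c(intercept = 0.5, escapement = 0.18,
                                           core = 1.0),
                            theta = 5,
                            temp_coefs = c(intercept = 1.5, air_temp = 0.55,
                                           humid_max = 0.01, humid_min_sqrt = 0.08,
                                           pressure = 0, wind = -0.05),
                            noise_sd = 1,
                            seed = 1L) {
  rsf_beta <- unlist(rsf_beta)
  count_beta <- unlist(count_beta)
  temp_coefs <- unlist(temp_coefs)
  stopifnot(
    "rsf_beta must name vwi, bfw, grad" =
      all(c("vwi", "bfw", "grad") %in% names(rsf_beta)),
    "count_beta must name intercept, escapement, core" =
      all(c("intercept", "escapement", "core") %in% names(count_beta)),
    "temp_coefs must include an intercept" = "intercept" %in% names(temp_coefs)
  )
  if (!all(is.finite(c(rsf_beta, rsf_intercept, count_beta, temp_coefs))))
    stop("all truth coefficients must be finite")
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(rsf_beta = rsf_beta[c("vwi", "bfw", "grad")],
         rsf_intercept = rsf_intercept,
         count_beta = count_beta[c("intercept", "escapement", "core")],
         theta = theta,
         temp_coefs = temp_coefs,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth record\n")
  cat("  RSF: intercept", format(x$rsf_intercept),
      " beta:", paste(names(x$rsf_beta), format(x$rsf_beta), collapse = ", "), "\n")
  cat("  Count model:", paste(names(x$count_beta), format(x$count_beta),
                              collapse = ", "),
      " (escapement effect per 1000 spawners)\n")
  cat("  theta:", format(x$theta), " temperature noise SD:",
      format(x$noise_sd), "degC\n")
  invisible(x)
}

# Derive a reproducible sub-stream seed so each generator stage can be rerun
# independently of the others. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(riverscape = 101L, redds = 211L, panel = 307L, daily = 401L,
               rsf = 503L, validation = 601L, isodar = 701L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 2654435L + offsets[[stage]]) %% 2147483647)
}

# Fixed study-reach table: two core (C*) and two periphery (P*) reaches with
# stream lengths spanning 10.6-40.5 km and mean 21.8 km.
study_reach_table <- function() {
  data.frame(
    reach_id = c("C1", "C2", "P1", "P2"),
    habitat = c("core", "core", "periphery", "periphery"),
    length_km = c(40.5, 20.0, 16.1, 10.6),
    stringsAsFactors = FALSE
  )
}
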