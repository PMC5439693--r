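make_flow <- function(values, year = 2000, reach = "C1") {
  days <- seq.Date(as.Date(sprintf("%d-07-01", year)),
                   as.Date(sprintf("%d-08-31", year)), by = "day")
  data.frame(reach_id = reach, date = days,
             flow_m3s = rep_len(values, length(days)))
}

test_that("flow metrics match hand arithmetic and guard degenerate inputs", {
  const <- compute_flow_metrics(make_flow(7))
  expect_equal(const$max_daily, 7)
  expect_equal(const$mean_daily, 7)
  expect_equal(const$cv_daily, 0)

  # 3-day window: mean 20, max 30, CV = sd([10,20,30]) / 20 = 10/20
  three <- make_flow(0)
  three$flow_m3s <- 15
  three$flow_m3s[three$date <= as.Date("2000-07-03")] <- c(10, 20, 30)
  short <- compute_flow_metrics(three[three$date <= as.Date("2000-07-03"), ],
                                window = c("07-01", "07-03"))
  expect_equal(short$mean_daily, 20)
  expect_equal(short$max_daily, 30)
  expect_equal(short$cv_daily, 0.5)

  expect_error(compute_flow_metrics(make_flow(0)), "CV undefined")
  gap <- make_flow(5)[-10, ]
  expect_error(compute_flow_metrics(gap), "does not cover the window")
})

test_that("flow metrics are permutation-invariant and CV is scale-free", {
  f <- make_flow(0)
  set.seed(1); f$flow_m3s <- rlnorm(nrow(f), 3, 0.4)
  m1 <- compute_flow_metrics(f)
  shuf <- f[sample(nrow(f)), ]
  expect_equal(compute_flow_metrics(shuf), m1)
  f2 <- f; f2$flow_m3s <- f$flow_m3s * 13.7
  m2 <- compute_flow_metrics(f2)
  expect_equal(m2$cv_daily, m1$cv_daily, tolerance = 1e-12)
  expect_equal(m2$mean_daily, m1$mean_daily * 13.7, tolerance = 1e-12)
})

test_that("correlation screen keeps orthogonal sets and breaks correlated pairs", {
  set.seed(2)
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  x$b <- residuals(lm(b ~ a, x))          # exactly uncorrelated
  expect_equal(sort(unclass(screen_correlation(x))), c("a", "b"),
               ignore_attr = TRUE)

  x$dup <- 2 * x$a + 1                     # |r| = 1 with a
  kept <- screen_correlation(x)
  expect_equal(length(kept), 2)
  expect_false(all(c("a", "dup") %in% kept))

  x$flat <- 3
  expect_warning(kept2 <- screen_correlation(x), "constant")
  expect_false("flat" %in% kept2)
})

test_that("backward deletion keeps true terms at zero noise and is order-invariant", {
  exact <- synthetic_truth(noise_sd = 0)
  ds <- simulate_daily_series(2005, exact, seed = 12)
  models <- fit_temperature_stepwise(ds$water_temp, ds$climate)
  truth_terms <- names(which(exact$temp_coefs[-1] != 0))
  for (m in models) {
    expect_setequal(m$retained_terms, truth_terms)
    expect_lt(m$rmse_c, 1e-8)
  }
  # covariate column order must not change the outcome
  clim_rev <- ds$climate[, c("date", rev(setdiff(names(ds$climate), "date")))]
  models_rev <- fit_temperature_stepwise(ds$water_temp, clim_rev)
  expect_setequal(models_rev$C1$retained_terms, models$C1$retained_terms)
  expect_equal(sort(models_rev$C1$coefficients), sort(models$C1$coefficients),
               tolerance = 1e-10)
})

test_that("backcasts reproduce the generator exactly in the zero-noise closed loop", {
  exact <- synthetic_truth(noise_sd = 0)
  ds <- simulate_daily_series(2005:2006, exact, seed = 13)
  models <- fit_temperature_stepwise(
    ds$water_temp[format(ds$water_temp$date, "%Y") == "2005", ], ds$climate)
  tm <- backcast_temperature(models$P2, ds$climate)
  expect_true(all(tm$min_c <= tm$mean_c & tm$mean_c <= tm$max_c))
  window <- ds$water_temp$reach_id == "P2" &
    format(ds$water_temp$date, "%m-%d") >= "07-01" &
    format(ds$water_temp$date, "%m-%d") <= "08-31"
  truth_mean <- tapply(ds$water_temp$temp_c[window],
                       format(ds$water_temp$date[window], "%Y"), mean)
  expect_equal(unname(tm$mean_c), unname(as.numeric(truth_mean)), tolerance = 1e-8)
})

test_that("backcast handles constant and intercept-only cases and flags extrapolation", {
  days <- seq.Date(as.Date("2001-06-01"), as.Date("2001-09-30"), by = "day")
  set.seed(6)
  clim <- data.frame(date = days, a = rnorm(length(days)),
                     b = rnorm(length(days)))
  wt <- data.frame(reach_id = "C1", date = days,
                   temp_c = 9 + rnorm(length(days), 0, 0.1))
  # an absurdly strict retention threshold strips every term
  m <- fit_temperature_stepwise(wt, clim, alpha = 1e-9)$C1
  expect_length(m$retained_terms, 0)
  out <- backcast_temperature(m, clim)
  expect_equal(out$min_c, out$mean_c)
  expect_equal(out$max_c, out$mean_c)
  expect_equal(out$mean_c, unname(m$coefficients[["(Intercept)"]]))

  # constant historic climate collapses the window summary to one value
  ds <- simulate_daily_series(2005, default_truth, seed = 3)
  mm <- fit_temperature_stepwise(ds$water_temp, ds$climate)$C1
  clim_const <- ds$climate
  for (v in setdiff(names(clim_const), "date"))
    clim_const[[v]] <- mean(clim_const[[v]])
  cc <- backcast_temperature(mm, clim_const)
  expect_equal(cc$min_c, cc$max_c)

  clim_out <- ds$climate; clim_out$air_temp <- clim_out$air_temp + 100
  expect_warning(backcast_temperature(mm, clim_out), "extrapolating")
})

test_that("VIF matches the closed form, flags duplicates, and agrees with car", {
  set.seed(4)
  u <- c(scale(rnorm(100)))                 # mean 0, sd 1 exactly
  w <- c(scale(residuals(lm(rnorm(100) ~ u))))  # orthogonal to u and centered
  ortho <- data.frame(a = u, b = w)
  expect_equal(unname(compute_vif(ortho)), c(1, 1), tolerance = 1e-10)

  # build a pair with sample correlation exactly 0.8
  v <- 0.8 * u + sqrt(1 - 0.64) * w
  pair <- data.frame(a = u, b = v)
  expect_equal(unname(compute_vif(pair)), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-10)

  dup <- data.frame(a = u, b = v, c = u)
  expect_true(is.infinite(compute_vif(dup)[["a"]]))

  skip_if_not_installed("car")
  set.seed(5)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60))
  d$y <- rnorm(60)
  ours <- compute_vif(d[, 1:3])
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})
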