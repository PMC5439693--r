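test_that("riverscape respects size, length bounds, and reach allocation", {
  rs <- fixture_riverscape$subreaches
  expect_equal(nrow(rs), 800)
  expect_true(all(rs$length_m >= 20 & rs$length_m <= 200))
  expect_true(all(rs$grad > 0) && all(rs$bfw > 0) && all(rs$vwi > 0))
  expect_setequal(unique(rs$study_reach), c("none", "C1", "C2", "P1", "P2"))

  tiny <- generate_riverscape(8, default_truth, seed = 2)$subreaches
  expect_true(all(table(tiny$study_reach[tiny$study_reach != "none"]) >= 2))
  expect_error(generate_riverscape(5, default_truth), "n_subreaches")

  again <- generate_riverscape(800, default_truth, seed = 11)$subreaches
  expect_identical(rs, again)
})

test_that("core study reaches are intrinsically more suitable than periphery", {
  rs <- fixture_riverscape$subreaches
  core <- rs[rs$study_reach %in% c("C1", "C2"), ]
  peri <- rs[rs$study_reach %in% c("P1", "P2"), ]
  expect_lt(mean(core$grad), mean(peri$grad))
  expect_gt(mean(core$bfw), mean(peri$bfw))
})

test_that("simulate_redds marks exactly n_used sub-reaches and guards the pool", {
  sr <- simulate_redds(fixture_riverscape, default_truth, n_used = 176, seed = 5)
  expect_equal(sum(sr$used), 176)
  expect_true(all(sr$redd_count[sr$used] >= 1))
  expect_true(all(sr$redd_count[sr$available & !sr$used] == 0))
  expect_true(all(is.na(sr$redd_count[!sr$available])))
  pool_n <- sum(fixture_riverscape$subreaches$available)
  expect_error(simulate_redds(fixture_riverscape, default_truth,
                              n_used = pool_n + 1), "exceeds the available pool")
})

test_that("under a null selection surface, used sub-reaches are uniform over attributes", {
  null_truth <- synthetic_truth(rsf_beta = c(vwi = 0, bfw = 0, grad = 0),
                                rsf_intercept = log(2))
  pool <- fixture_riverscape$subreaches$available
  q <- stats::quantile(fixture_riverscape$subreaches$bfw[pool],
                       probs = seq(0, 1, 0.25))
  n_sig <- 0L
  for (s in 1:100) {
    sr <- simulate_redds(fixture_riverscape, null_truth, n_used = 120, seed = s)
    cut_used <- cut(sr$bfw[sr$used], q, include.lowest = TRUE)
    p <- suppressWarnings(stats::chisq.test(table(cut_used))$p.value)
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  # nominal 1% false-positive rate; allow binomial slack
  expect_lte(n_sig, 5L)
})

test_that("in the Poisson limit with a flat surface, used counts average the set intensity", {
  mu <- 5
  flat <- synthetic_truth(rsf_beta = c(vwi = 0, bfw = 0, grad = 0),
                          rsf_intercept = log(mu), theta = 1e6)
  sr <- simulate_redds(fixture_riverscape, flat, n_used = 176, seed = 8)
  counts <- sr$redd_count[sr$used]
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se + mu * (exp(-mu) / (1 - exp(-mu))))
})

test_that("panel has one row per reach-year with consistent labels and counts", {
  panel <- simulate_panel(10, default_truth, seed = 3)
  expect_equal(nrow(panel), 40)
  expect_true(all(panel$peak_count >= 0))
  expect_true(all(panel$length_km > 0))
  expect_true(all((substr(panel$reach_id, 1, 1) == "C") ==
                    (panel$habitat == "core")))
  expect_identical(panel, simulate_panel(10, default_truth, seed = 3))

  const <- simulate_panel(5, default_truth, escapement_range = c(8000, 8000))
  expect_true(all(const$escapement == 8000))
  expect_error(simulate_panel(5, default_truth, escapement_range = c(10, 5)),
               "escapement_range")
  expect_error(simulate_panel(2, default_truth), "n_years")
})

test_that("a null escapement effect is not spuriously detected by the count model", {
  null_truth <- synthetic_truth(count_beta = c(intercept = 1.2, escapement = 0,
                                               core = 1.0))
  cs <- build_candidate_set()
  covered <- 0L
  for (s in 1:100) {
    panel <- simulate_panel(10, null_truth, seed = 2000 + s)
    fit <- fit_nb(cs[[2]], panel)   # E + CP carries an escapement slope
    if (!isTRUE(fit$converged)) next
    se <- sqrt(diag(stats::vcov(fit$glm)))["E"]
    ci <- fit$coefficients[["E"]] + c(-1.96, 1.96) * se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 85L)
})

test_that("daily series are well-formed, reproducible, and flows never go negative", {
  ds <- simulate_daily_series(2005:2006, default_truth, seed = 4)
  expect_true(all(diff(ds$climate$date) == 1))
  expect_true(all(ds$flow$flow_m3s >= 0))
  expect_equal(nrow(ds$climate) * 4, nrow(ds$water_temp))
  ds2 <- simulate_daily_series(2005:2006, default_truth, seed = 4)
  expect_identical(ds, ds2)
  for (s in 1:5)
    expect_true(all(simulate_daily_series(2001, default_truth,
                                          seed = s)$flow$flow_m3s >= 0))
})

test_that("the humidity pair built at r = 0.9 trips the correlation screen", {
  ds <- simulate_daily_series(2005:2006, default_truth, seed = 9,
                              climate_cor = 0.9)
  clim <- ds$climate[, setdiff(names(ds$climate), "date")]
  expect_gt(abs(stats::cor(clim$humid_max, clim$humid_min_sqrt)), 0.6)
  kept <- screen_correlation(clim, threshold = 0.6)
  expect_equal(length(kept), 4)
  expect_false(all(c("humid_max", "humid_min_sqrt") %in% kept))
})

test_that("generated tables round-trip through the CSV writer and reader", {
  panel <- simulate_panel(5, default_truth, seed = 6)
  ds <- simulate_daily_series(2005, default_truth, seed = 6)
  for (tab in list(panel, ds$climate, ds$flow)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_stage_csv(tab, path)
    back <- read_stage_csv(path)
    expect_equal(back, tab, tolerance = 1e-12, ignore_attr = TRUE)
  }
})
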