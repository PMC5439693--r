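fit_best_additive <- function(seed = 17) {
  panel <- simulate_panel(10, default_truth, seed = seed)
  fit_nb(build_candidate_set()[[2]], panel)
}

test_that("habitat predictions pair every escapement with both habitats", {
  fit <- fit_best_additive()
  esc <- seq(2000, 11000, length.out = 10)
  preds <- predict_habitat_counts(fit, esc, offset_km = 21.8)
  expect_equal(nrow(preds), 20)
  expect_setequal(unique(preds$habitat), c("core", "periphery"))
  expect_true(all(preds$se_count >= 0))

  doubled <- predict_habitat_counts(fit, esc, offset_km = 43.6)
  expect_equal(doubled$mean_count, 2 * preds$mean_count, tolerance = 1e-10)
  expect_equal(doubled$se_count, 2 * preds$se_count, tolerance = 1e-10)

  no_cp <- fit_nb(build_candidate_set()[[1]],
                  simulate_panel(10, default_truth, seed = 2))
  expect_error(predict_habitat_counts(no_cp, esc), "core/periphery term")
})

test_that("a model with no core effect predicts both habitats identically", {
  panel <- exact_additive_panel(reps = 3)
  panel$peak_count <- as.integer(round(2 * 2^panel$E01))  # core effect removed
  fit <- fit_nb(build_candidate_set()[[2]], panel)
  preds <- predict_habitat_counts(fit, c(2000, 2500, 3000), offset_km = 5)
  wide <- merge(preds[preds$habitat == "core", c("escapement", "mean_count")],
                preds[preds$habitat == "periphery", c("escapement", "mean_count")],
                by = "escapement")
  expect_equal(wide$mean_count.x, wide$mean_count.y, tolerance = 1e-5)
})

test_that("noiseless isodars reduce to the closed-form regression of the means", {
  esc <- seq(2000, 11000, length.out = 10)
  peri_mu <- seq(20, 200, length.out = 10)
  preds <- data.frame(
    escapement = rep(esc, 2),
    habitat = rep(c("core", "periphery"), each = 10),
    mean_count = c(2 * peri_mu, peri_mu),   # core exactly twice periphery
    se_count = 0, offset_km = 21.8)
  iso <- bootstrap_isodars(preds, n_iso = 200, seed = 1)
  expect_equal(iso$slope_mean, 0.5, tolerance = 1e-10)
  expect_equal(iso$intercept_mean, 0, tolerance = 1e-8)
  expect_equal(unname(diff(iso$slope_ci90)), 0, tolerance = 1e-12)

  flipped <- bootstrap_isodars(preds, n_iso = 200, seed = 1,
                               orientation = "core_on_periphery")
  expect_equal(flipped$slope_mean, 2, tolerance = 1e-10)

  ident <- preds
  ident$mean_count <- rep(peri_mu, 2)       # periphery equals core exactly
  iso1 <- bootstrap_isodars(ident, n_iso = 200, seed = 1)
  expect_equal(iso1$slope_mean, 1, tolerance = 1e-10)
  expect_equal(iso1$intercept_mean, 0, tolerance = 1e-8)
  expect_false(iso1$quality_differs)
  expect_false(iso1$quantity_differs)
})

test_that("small prediction noise leaves the bootstrap slope near the noiseless slope", {
  esc <- seq(2000, 11000, length.out = 10)
  peri_mu <- seq(100, 800, length.out = 10)
  preds <- data.frame(
    escapement = rep(esc, 2),
    habitat = rep(c("core", "periphery"), each = 10),
    mean_count = c(2 * peri_mu, peri_mu),
    se_count = c(2 * peri_mu, peri_mu) * 0.01,   # SE/mean = 1%
    offset_km = 21.8)
  iso <- bootstrap_isodars(preds, n_iso = 20000, seed = 5)
  expect_equal(iso$slope_mean, 0.5, tolerance = 0.01)
  # reproducibility under the seed
  iso2 <- bootstrap_isodars(preds, n_iso = 20000, seed = 5)
  expect_identical(iso$slopes, iso2$slopes)
})

test_that("CI rules classify quantity and quality with a closed-interval convention", {
  v <- classify_selection(list(intercept_ci90 = c(-76.4, 297.2),
                               slope_ci90 = c(-0.105, 0.780)))
  expect_false(v$quantity_differs)
  expect_true(v$quality_differs)

  # bounds exactly touching the critical values do not exclude them
  touch <- classify_selection(list(intercept_ci90 = c(0, 50),
                                   slope_ci90 = c(0.2, 1)))
  expect_false(touch$quantity_differs)
  expect_false(touch$quality_differs)

  above <- classify_selection(list(intercept_ci90 = c(5, 50),
                                   slope_ci90 = c(1.2, 1.9)))
  expect_true(above$quantity_differs)
  expect_true(above$quality_differs)
  expect_error(classify_selection(list(intercept_ci90 = c(5, -5),
                                       slope_ci90 = c(0, 1))), "ordered")
})

test_that("the selection regime is read from the best model's structure", {
  cs <- build_candidate_set()
  cis <- list(intercept_ci90 = c(-10, 10), slope_ci90 = c(0.2, 0.8))
  expect_equal(classify_selection(cis, cs[[2]])$selection_regime,
               "IFD-consistent linear isodar")
  expect_equal(classify_selection(cis, cs[[3]])$selection_regime,
               "IDD-suggestive")   # E*CP interaction
  expect_equal(classify_selection(cis, cs[[4]])$selection_regime,
               "IDD-suggestive")   # quadratic escapement
  expect_true(is.na(classify_selection(cis)$selection_regime))
  # verdicts are a pure function of the stored bounds: idempotent
  expect_identical(classify_selection(cis, cs[[2]]),
                   classify_selection(cis, cs[[2]]))
})

test_that("observed isodars recover exact density relationships", {
  years <- 2001:2008
  base <- data.frame(year = rep(years, each = 2),
                     reach_id = rep(c("C1", "P1"), length(years)),
                     length_km = rep(c(20, 10), length(years)))
  dens <- seq(2, 16, length.out = length(years))
  base$peak_count <- ifelse(base$reach_id == "C1",
                            dens[match(base$year, years)] * 20 * 2,
                            dens[match(base$year, years)] * 10)
  iso <- observed_isodar(base, "C1", "P1")
  expect_equal(iso$slope_mean, 0.5, tolerance = 1e-10)   # 2:1 density ratio
  expect_equal(iso$intercept_mean, 0, tolerance = 1e-8)

  same <- base
  same$peak_count <- dens[match(same$year, years)] * same$length_km
  iso1 <- observed_isodar(same, "C1", "P1")
  expect_equal(iso1$slope_mean, 1, tolerance = 1e-10)
  expect_equal(iso1$intercept_mean, 0, tolerance = 1e-8)

  flat <- base
  flat$peak_count[flat$reach_id == "P1"] <- 30
  iso0 <- observed_isodar(flat, "C1", "P1")
  expect_equal(iso0$slope_mean, 0, tolerance = 1e-10)

  expect_error(observed_isodar(base[base$year < 2003, ], "C1", "P1"),
               "fewer than 3")
})
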