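# Shared fixtures, built once per test run.

default_truth <- synthetic_truth()

# A mid-sized riverscape reused across tests that only need attributes.
fixture_riverscape <- generate_riverscape(800, default_truth, seed = 11)

# Independent grid-search oracle for the negative binomial log-likelihood of
# y ~ b0 + b1 * x (log link, offset `off`), maximized over (b0, b1, theta) by
# three rounds of grid refinement. Stays independent of glm.nb: the initial
# grid is anchored on crude moments, never on the fitted coefficients.
nb_grid_loglik <- function(y, x, off = 0) {
  ll <- function(b0, b1, theta) {
    grid <- expand.grid(b0 = b0, b1 = b1, theta = theta,
                        KEEP.OUT.ATTRS = FALSE)
    eta <- outer(grid$b0, rep(1, length(y))) + outer(grid$b1, x) +
      matrix(off, nrow(grid), length(y), byrow = TRUE)
    mu <- exp(eta)
    l <- vapply(seq_len(nrow(grid)), function(i)
      sum(stats::dnbinom(y, size = grid$theta[i], mu = mu[i, ], log = TRUE)),
      numeric(1))
    list(grid = grid, loglik = l)
  }
  b0 <- seq(log(mean(y) + 0.5) - 2, log(mean(y) + 0.5) + 2, length.out = 31)
  b1 <- seq(-2, 2, length.out = 31)
  theta <- exp(seq(log(0.2), log(200), length.out = 31))
  best <- NULL
  for (round in 1:7) {
    res <- ll(b0, b1, theta)
    i <- which.max(res$loglik)
    best <- list(par = unlist(res$grid[i, ]), loglik = res$loglik[i])
    # keep the refinement box wide (+-3 old steps) so the curved (b0, b1)
    # likelihood ridge stays inside it while the step shrinks 5x per round
    step_b0 <- 3 * diff(b0)[1]; step_b1 <- 3 * diff(b1)[1]
    step_lt <- 3 * diff(log(theta))[1]
    b0 <- seq(best$par["b0"] - step_b0, best$par["b0"] + step_b0, length.out = 31)
    b1 <- seq(best$par["b1"] - step_b1, best$par["b1"] + step_b1, length.out = 31)
    theta <- exp(seq(log(best$par["theta"]) - step_lt,
                     log(best$par["theta"]) + step_lt, length.out = 31))
  }
  best
}

# Tiny panel whose counts follow an exact log-linear E + CP relationship
# (integer counts, no noise), so the additive model fits it perfectly.
exact_additive_panel <- function(reps = 3) {
  base <- expand.grid(E01 = c(0, 1), habitat = c("periphery", "core"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # log mu = log 2 + log 2 * E + log 3 * core  ->  mu in {2, 4, 6, 12}
  base$peak_count <- as.integer(round(2 * 2^base$E01 * 3^(base$habitat == "core")))
  out <- base[rep(seq_len(nrow(base)), each = reps), ]
  out$escapement <- out$E01 * 1000 + 2000
  out$length_km <- 1
  out$reach_id <- ifelse(out$habitat == "core", "C1", "P1")
  out$year <- seq_len(nrow(out))
  out$survey_condition <- "good"
  rownames(out) <- NULL
  out
}

# Table of printed candidate-model summaries (name, number, type, df,
# logLik) used wherever ranked-arithmetic checks need real inputs.
printed_model_table <- function() {
  data.frame(
    name = c("E+E^2+CP", "E+CP", "E*CP", "E*CP+E^2", "RSF*E", "TEMP*CP+E*CP",
             "RSF*CP+E*CP", "FLOW*CP+E*CP", "TEMP*E", "E", "RSF", "FLOW*E",
             "RSF+TEMP+FLOW", "TEMP", "FLOW"),
    number = c(4L, 2L, 3L, 5L, 12L, 14L, 15L, 13L, 11L, 1L, 8L, 10L, 9L, 6L, 7L),
    type = c("DD", "DD", "DD", "DD", "BOTH", "BOTH", "BOTH", "BOTH", "BOTH",
             "DD", "DI", "BOTH", "DI", "DI", "DI"),
    df = c(5L, 4L, 5L, 6L, 5L, 7L, 7L, 7L, 5L, 3L, 3L, 5L, 5L, 3L, 3L),
    loglik = c(-254.38, -255.72, -255.69, -254.35, -256.41, -254.43, -254.90,
               -255.55, -259.85, -263.02, -263.73, -262.93, -263.18, -268.69,
               -268.70),
    aicc_printed = c(520.5, 520.6, 523.1, 523.2, 524.6, 526.4, 527.3, 528.6,
                     531.5, 532.7, 534.1, 537.6, 538.1, 544.0, 544.1),
    stringsAsFactors = FALSE
  )
}
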