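#' Generate a synthetic riverscape of stream sub-reaches
#'
#' Builds a longitudinally ordered network of 20-200 m sub-reaches with
#' spatially autocorrelated geomorphic attributes: channel gradient (GRAD, %)
#' declines downstream, bankfull width (BFW, m) increases downstream, and the
#' valley width index (VWI) loosens downstream. Four contiguous blocks are
#' labelled as study reaches C1, C2 (downstream, core) and P1, P2 (upstream,
#' periphery), so core reaches receive higher intrinsic spawning suitability
#' by construction. A subset of sub-reaches is flagged as the "available"
#' pool, standing in for the documented anadromous distribution.
#'
#' Attributes are drawn from right-skewed strictly positive distributions
#' (GRAD and BFW lognormal, VWI gamma) around smooth downstream trends, with
#' an AR(1) latent field supplying local spatial autocorrelation.
#'
#' @param n_subreaches Number of sub-reaches, >= 8 so that each study reach
#'   receives at least two.
#' @param truth A [synthetic_truth()] record (carried through for provenance;
#'   attribute distributions do not depend on it).
#' @param seed Integer seed; identical inputs give byte-identical tables.
#' @param frac_available Fraction of sub-reaches (probability, applied with a
#'   downstream bias) placed in the available pool. Study-reach members are
#'   always available.
#'
#' @return A list with `subreaches` (data frame: id, length_m, grad, bfw,
#'   vwi, redd_count (NA until [simulate_redds()]), available, study_reach)
#'   and `reaches` (the four-row study reach table with stream lengths).
#' @examples
#' rs <- generate_riverscape(200, synthetic_truth(), seed = 1)
#' table(rs$subreaches$study_reach)
#' @export
generate_riverscape <- function(n_subreaches, truth, seed = truth$seed,
                                frac_available = 0.85) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  n <- as.integer(n_subreaches)
  if (is.na(n) || n < 8) stop("n_subreaches must be >= 8 (two per study reach)")
  if (frac_available <= 0 || frac_available > 1)
    stop("frac_available must be in (0, 1]")
  set.seed(derive_seed(seed, "riverscape"))

  pos <- (seq_len(n) - 0.5) / n          # 0 = downstream, 1 = headwaters
  ar1 <- function(n, rho = 0.8, sd = 1) {
    z <- numeric(n)
    z[1] <- stats::rnorm(1, 0, sd)
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in seq_len(n - 1L)) z[i + 1L] <- rho * z[i] + innov[i]
    z
  }

  length_m <- stats::runif(n, 20, 200)
  grad <- exp(log(0.4) + 1.3 * pos + 0.45 * ar1(n))          # % slope
  bfw  <- exp(log(18)  - 1.0 * pos + 0.25 * ar1(n))          # m
  # VWI via a gamma quantile transform of an autocorrelated gaussian field,
  # with valleys opening (larger VWI) downstream.
  zv <- ar1(n) - 0.8 * pos
  vwi <- stats::qgamma(stats::pnorm(zv, sd = sqrt(1 + 0.8^2 * stats::var(pos))),
                       shape = 4, scale = 1.6)
  vwi <- pmax(vwi, 1e-3)

  study_reach <- rep("none", n)
  sizes <- pmax(2L, as.integer(floor(n * c(0.10, 0.06, 0.05, 0.04))))
  if (sum(sizes) > n) sizes <- rep(2L, 4L)
  anchors <- c(0.06, 0.22, 0.52, 0.74)
  labels <- c("C1", "C2", "P1", "P2")
  pos_next <- 1L
  for (i in 1:4) {
    start <- max(pos_next,
                 min(as.integer(round(anchors[i] * n)) + 1L,
                     n - sum(sizes[i:4]) + 1L))
    study_reach[start:(start + sizes[i] - 1L)] <- labels[i]
    pos_next <- start + sizes[i]
  }

  available <- stats::runif(n) < stats::plogis(stats::qlogis(min(frac_available, 1 - 1e-9)) +
                                                 1.5 * (0.5 - pos))
  available[study_reach != "none"] <- TRUE

  subreaches <- data.frame(
    id = sprintf("SR%05d", seq_len(n)),
    length_m = length_m,
    grad = grad,
    bfw = bfw,
    vwi = vwi,
    redd_count = NA_integer_,
    available = available,
    study_reach = study_reach,
    stringsAsFactors = FALSE
  )
  list(subreaches = subreaches, reaches = study_reach_table())
}

# Zero-truncated negative binomial sampler by inverse CDF: draw the CDF
# uniformly above P(Y = 0).
rztnbinom <- function(n, mu, theta) {
  p0 <- stats::dnbinom(0, size = theta, mu = mu)
  u <- stats::runif(n, min = p0, max = 1)
  # guard the u == 1 corner and p0 ~ 1 (tiny mu): qnbinom handles both
  pmax(1L, stats::qnbinom(pmin(u, 1 - 1e-12), size = theta, mu = mu))
}

#' Simulate redd counts over the available sub-reach pool
#'
#' Spawning intensity follows a negative binomial with log-mean
#' `rsf_intercept + beta_vwi * VWI + beta_bfw * BFW + beta_grad * GRAD` and
#' dispersion `theta` from the truth record. Exactly `n_used` sub-reaches are
#' designated "used": they are sampled without replacement with probability
#' proportional to the negative binomial probability of observing at least
#' one redd, and their counts are drawn zero-truncated; all other available
#' sub-reaches receive a count of zero.
#'
#' @param riverscape Output of [generate_riverscape()] (or its `subreaches`
#'   data frame).
#' @param truth A [synthetic_truth()] record.
#' @param n_used Number of used sub-reaches (must not exceed the available
#'   pool).
#' @param seed Integer seed.
#'
#' @return The sub-reach data frame with `redd_count` filled for available
#'   rows (NA outside the pool) and a logical `used` column.
#' @examples
#' rs <- generate_riverscape(500, synthetic_truth(), seed = 1)
#' sr <- simulate_redds(rs, synthetic_truth(), n_used = 50, seed = 1)
#' sum(sr$used)
#' @export
simulate_redds <- function(riverscape, truth, n_used = 176, seed = truth$seed) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  sr <- if (is.list(riverscape) && !is.data.frame(riverscape))
    riverscape$subreaches else riverscape
  pool <- which(sr$available)
  n_used <- as.integer(n_used)
  if (n_used < 1L) stop("n_used must be positive")
  if (n_used > length(pool))
    stop("n_used (", n_used, ") exceeds the available pool (", length(pool), ")")
  set.seed(derive_seed(seed, "redds"))

  x <- as.matrix(sr[pool, c("vwi", "bfw", "grad")])
  mu <- exp(truth$rsf_intercept + drop(x %*% truth$rsf_beta))
  p_used <- 1 - stats::dnbinom(0, size = truth$theta, mu = mu)
  p_used <- pmax(p_used, 1e-12)
  used_in_pool <- sample(seq_along(pool), n_used, prob = p_used)

  sr$redd_count <- NA_integer_
  sr$redd_count[pool] <- 0L
  sr$redd_count[pool[used_in_pool]] <-
    as.integer(rztnbinom(n_used, mu[used_in_pool], truth$theta))
  sr$used <- !is.na(sr$redd_count) & sr$redd_count >= 1L
  sr
}
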