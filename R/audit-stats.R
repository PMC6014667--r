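# Prevalence estimation for misidentified database records, built on the
# binomial sampling design: sample n records from a group, find k
# misidentified, and propagate the uncertainty into (i) an exact interval on
# the misidentification ratio and (ii) absolute record counts via the
# Beta(k+1, n-k+1) posterior of a binomial proportion under a uniform prior.

#' Construct an AuditObservation
#'
#' @param taxonGroup Group label, e.g. "Arthropoda".
#' @param n Sample size.
#' @param k Misidentified records found in the sample.
#' @param nTotal Total database records for the group.
#' @return An \linkS4class{AuditObservation}.
#' @examples
#' auditObservation("Mollusca", n = 300, k = 1, nTotal = 109502)
#' @export
auditObservation <- function(taxonGroup, n, k, nTotal) {
  new("AuditObservation", taxonGroup = as.character(taxonGroup),
      n = as.integer(n), k = as.integer(k), nTotal = as.integer(nTotal))
}

#' @export
setMethod("show", "AuditObservation", function(object) {
  cat(sprintf("AuditObservation [%s]: k = %d of n = %d sampled (N = %d)\n",
              object@taxonGroup, object@k, object@n, object@nTotal))
})

#' Probability of detecting at least one misidentified record
#'
#' \code{P(X > 0) = 1 - (1 - p)^n}: the chance that a uniform random sample
#' of \code{n} records contains at least one misidentified record when the
#' population misidentification ratio is \code{p}.
#'
#' @param p Proportion of misidentified records in the population, in [0,1].
#' @param n Sample size (positive integer), vectorized.
#' @return The detection probability.
#' @examples
#' detectionProbability(0.01, 300)  # >= 0.95
#' @export
detectionProbability <- function(p, n) {
  if (any(p < 0 | p > 1) || anyNA(p))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (any(n < 1) || anyNA(n))
    stop("n must be a positive integer", call. = FALSE)
  1 - (1 - p)^n
}

#' Sample size needed to reach a target detection probability
#'
#' Inverts \code{P = 1 - (1-p)^n} to \code{n = log(1-P) / log(1-p)}.
#' \code{"exact-ceil"} returns the smallest integer sample size meeting the
#' target; \code{"next-hundred"} rounds that up to the next multiple of 100,
#' the convention used when planning a database audit by hand (it yields 300
#' for P = 0.95, p = 0.01).
#'
#' @param targetP Target detection probability, in (0,1).
#' @param p Assumed misidentification ratio, in (0,1).
#' @param rounding \code{"exact-ceil"} or \code{"next-hundred"}.
#' @return Positive integer sample size.
#' @examples
#' requiredSampleSize(0.95, 0.01)                     # 299
#' requiredSampleSize(0.95, 0.01, "next-hundred")     # 300
#' @export
requiredSampleSize <- function(targetP, p,
                               rounding = c("exact-ceil", "next-hundred")) {
  rounding <- match.arg(rounding)
  if (length(p) != 1 || is.na(p) || p <= 0 || p >= 1)
    stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (length(targetP) != 1 || is.na(targetP) || targetP <= 0 || targetP >= 1)
    stop("targetP must lie strictly in (0, 1)", call. = FALSE)
  n <- ceiling(log(1 - targetP) / log(1 - p))
  # guard against floating-point edge: ensure minimality and sufficiency
  while (detectionProbability(p, n) < targetP) n <- n + 1
  while (n > 1 && detectionProbability(p, n - 1) >= targetP) n <- n - 1
  n <- as.integer(n)
  if (rounding == "next-hundred") n <- as.integer(ceiling(n / 100) * 100)
  n
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact method inverts the binomial test via beta quantiles:
#' lower bound 0 when \code{k = 0}, else the \code{(1-conf)/2} quantile of
#' \code{Beta(k, n-k+1)}; upper bound 1 when \code{k = n}, else the
#' \code{1-(1-conf)/2} quantile of \code{Beta(k+1, n-k)}.
#'
#' @param k Number of successes, \code{0 <= k <= n}.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector \code{c(low, high)}.
#' @examples
#' exactBinomialCI(0, 300)  # upper bound ~0.012
#' exactBinomialCI(1, 300)  # upper bound ~0.018
#' @export
exactBinomialCI <- function(k, n, conf = 0.95) {
  k <- as.integer(k); n <- as.integer(n)
  if (anyNA(c(k, n)) || k < 0 || n < 1 || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  if (is.na(conf) || conf <= 0 || conf >= 1)
    stop("conf must lie strictly in (0, 1)", call. = FALSE)
  alpha <- 1 - conf
  low <- if (k == 0L) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Beta-posterior percentiles of the absolute misidentified-record count
#'
#' Draws \code{draws} probabilities from the posterior
#' \code{Beta(k+1, n-k+1)}, multiplies each by the total number of database
#' records for the group, and reports percentiles of the resulting counts
#' (linear interpolation between order statistics, rounded to integers —
#' these are counts of records).
#'
#' @param obs An \linkS4class{AuditObservation}.
#' @param draws Number of Monte-Carlo draws (at least 1000; default 10000).
#' @param percentiles Percentiles to report (default 5, 50, 95).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Named integer vector of counts, one per percentile.
#' @examples
#' obs <- auditObservation("Arthropoda", 300, 0, 2008162)
#' posteriorCountPercentiles(obs, seed = 42)
#' @export
posteriorCountPercentiles <- function(obs, draws = 10000,
                                      percentiles = c(5, 50, 95),
                                      seed = NULL) {
  stopifnot(is(obs, "AuditObservation"))
  draws <- as.integer(draws)
  if (draws < 1000) stop("draws must be at least 1000", call. = FALSE)
  p <- .withSeed(seed, rbeta(draws, obs@k + 1, obs@n - obs@k + 1))
  q <- quantile(p * obs@nTotal, probs = percentiles / 100, type = 7,
                names = FALSE)
  setNames(as.integer(round(q)), paste0("p", percentiles))
}

#' Predictive beta-binomial counts for prospective sample sizes
#'
#' Simulates how many erroneous records a fresh uniform sample of size
#' \code{s} would contain: for each of \code{draws} iterations a probability
#' is drawn from the posterior \code{Beta(k+1, n-k+1)} and a count from
#' \code{Binomial(s, p)}. The same posterior draws are reused across sample
#' sizes, and percentiles of the counts are reported.
#'
#' @param obs An \linkS4class{AuditObservation}.
#' @param sampleSizes Prospective sample sizes (default 300, 1000, 10000).
#' @param draws Monte-Carlo iterations (default 10000).
#' @param percentiles Percentiles to report (default 5, 50, 95).
#' @param seed Optional integer seed.
#' @return Integer matrix: one row per sample size, one column per
#'   percentile.
#' @examples
#' obs <- auditObservation("Mollusca", 300, 1, 109502)
#' predictiveSampleCounts(obs, seed = 42)
#' @export
predictiveSampleCounts <- function(obs, sampleSizes = c(300, 1000, 10000),
                                   draws = 10000,
                                   percentiles = c(5, 50, 95), seed = NULL) {
  stopifnot(is(obs, "AuditObservation"))
  draws <- as.integer(draws)
  if (draws < 1000) stop("draws must be at least 1000", call. = FALSE)
  if (!length(sampleSizes)) stop("sampleSizes must be non-empty", call. = FALSE)
  res <- .withSeed(seed, {
    p <- rbeta(draws, obs@k + 1, obs@n - obs@k + 1)
    vapply(sampleSizes, function(s) {
      x <- rbinom(draws, as.integer(s), p)
      as.integer(round(quantile(x, probs = percentiles / 100, type = 7,
                                names = FALSE)))
    }, integer(length(percentiles)))
  })
  res <- t(matrix(res, nrow = length(percentiles)))
  dimnames(res) <- list(as.character(sampleSizes), paste0("p", percentiles))
  res
}

#' Census error rates for a fully audited group
#'
#' For a group small enough to audit in full, converts per-class
#' misidentification counts into percentages of the total, plus the combined
#' incorrect percentage.
#'
#' @param counts Named integer vector (class -> count); may be empty.
#' @param total Total records in the group (positive).
#' @param digits Decimals to report (default 2).
#' @return A list: \code{perClass} (named numeric percentages) and
#'   \code{combined}.
#' @examples
#' censusRates(c(bacterial = 2, fungal = 1, other_metazoan = 22), 363)
#' @export
censusRates <- function(counts, total, digits = 2) {
  total <- as.integer(total)
  if (is.na(total) || total <= 0L)
    stop("total must be a positive integer", call. = FALSE)
  counts <- unlist(counts)
  if (length(counts) && sum(counts) > total)
    stop("counts sum exceeds total", call. = FALSE)
  perClass <- if (length(counts))
    round(100 * counts / total, digits) else setNames(numeric(0), character(0))
  list(perClass = perClass,
       combined = round(100 * sum(counts) / total, digits))
}

#' Full prevalence estimate for one audit observation
#'
#' Bundles the point ratio, exact interval, beta-posterior count percentiles
#' and predictive beta-binomial counts into one \linkS4class{AuditEstimate}.
#' One top-level seed drives the two stochastic parts through independent
#' derived substreams, so a pipeline run is reproducible end to end.
#'
#' @param obs An \linkS4class{AuditObservation}.
#' @param conf Confidence level (default 0.95).
#' @param draws Monte-Carlo draws (default 10000).
#' @param sampleSizes Prospective sample sizes (default 300, 1000, 10000).
#' @param percentiles Percentiles to report (default 5, 50, 95).
#' @param seed Optional integer seed.
#' @return An \linkS4class{AuditEstimate}.
#' @examples
#' est <- auditEstimate(auditObservation("Mollusca", 300, 1, 109502),
#'                      seed = 42)
#' est
#' @export
auditEstimate <- function(obs, conf = 0.95, draws = 10000,
                          sampleSizes = c(300, 1000, 10000),
                          percentiles = c(5, 50, 95), seed = NULL) {
  stopifnot(is(obs, "AuditObservation"))
  ci <- exactBinomialCI(obs@k, obs@n, conf)
  cp <- posteriorCountPercentiles(obs, draws = draws,
                                  percentiles = percentiles,
                                  seed = .deriveSeed(seed, 1L))
  pc <- predictiveSampleCounts(obs, sampleSizes = sampleSizes, draws = draws,
                               percentiles = percentiles,
                               seed = .deriveSeed(seed, 2L))
  new("AuditEstimate", observation = obs, pointRatio = obs@k / obs@n,
      conf = conf, ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      countPercentiles = cp, predictiveCounts = pc,
      draws = as.integer(draws),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @export
setMethod("show", "AuditEstimate", function(object) {
  obs <- object@observation
  cat(sprintf("AuditEstimate [%s]\n", obs@taxonGroup))
  cat(sprintf("  ratio k/n = %d/%d = %.4f, %.0f%% exact CI [%.4f, %.4f]\n",
              obs@k, obs@n, object@pointRatio, 100 * object@conf,
              object@ciLow, object@ciHigh))
  cp <- object@countPercentiles
  cat(sprintf("  posterior count of misidentified records (N = %d): %s\n",
              obs@nTotal,
              paste(sprintf("%s = %d", names(cp), cp), collapse = ", ")))
  pc <- object@predictiveCounts
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  predictive sample n = %s: %s\n", rownames(pc)[i],
                paste(sprintf("%s = %d", colnames(pc), pc[i, ]),
                      collapse = ", ")))
})

#' Serialize an AuditEstimate to a plain list (for JSON reports)
#'
#' @param x An \linkS4class{AuditEstimate}.
#' @return A nested list mirroring the estimate.
#' @export
auditEstimateAsList <- function(x) {
  stopifnot(is(x, "AuditEstimate"))
  obs <- x@observation
  list(
    taxon_group = obs@taxonGroup,
    n = obs@n, k = obs@k, n_total = obs@nTotal,
    point_ratio = x@pointRatio, conf = x@conf,
    ci_low = x@ciLow, ci_high = x@ciHigh,
    count_percentiles = as.list(x@countPercentiles),
    predictive_counts = lapply(
      setNames(seq_len(nrow(x@predictiveCounts)),
               rownames(x@predictiveCounts)),
      function(i) as.list(x@predictiveCounts[i, ])),
    draws = x@draws,
    seed = if (is.na(x@seed)) NULL else x@seed)
}
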