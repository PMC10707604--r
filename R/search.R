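## Candidate-site discovery and the iterative, simulation-calibrated
## multi-locus model selection procedure: a single-site likelihood-ratio
## scan proposes candidates, which are tested in order of decreasing LLR
## against a null distribution obtained by refitting on data simulated under
## the current null model; accepted sites join the null for later
## iterations.

#' Single-site selection scan along a chromosome
#'
#' At every \code{gridEvery}-th marker, fits a single selected site with
#' fixed position and dominance (additive by default) and records the
#' log-likelihood ratio against the neutral model with the same demography.
#'
#' @param data a \code{MarkerDataset}.
#' @param m,t demography of the admixed population (fitted or supplied).
#' @param gridEvery grid step in markers (default 50).
#' @param h dominance of the scanned site (default 0.5, additive).
#' @param sStart starting selection coefficient for each fit.
#' @param chromosomeLength in Morgans; defaults to the marker span.
#' @param k,radius,eps,gamma,config forwarded to \code{\link{twoStageFit}}.
#' @return data.frame (class \code{"scanProfile"}) with columns
#'   \code{position}, \code{bp}, \code{loglikAlt}, \code{loglikNull},
#'   \code{llr} (floored at 0 up to optimizer tolerance).
#' @export
singleSiteScan <- function(data, m, t, gridEvery = 50, h = 0.5,
                           sStart = 0.005, chromosomeLength = NULL,
                           k = 4, radius = 0.02, eps = 0.01, gamma = 0.01,
                           config = simplexConfig()) {
  gp <- geneticPositions(data)
  if (is.null(chromosomeLength)) chromosomeLength <- max(gp) * 1.001
  neutral <- SelectionModel(m, t, chromosomeLength)
  llNull <- forwardLoglik(neutral, data, k = k, radius = radius,
                          eps = eps, gamma = gamma)
  idx <- seq(1L, length(gp), by = as.integer(gridEvery))
  bp <- GenomicRanges::start(SummarizedExperiment::rowRanges(data))
  rows <- lapply(idx, function(i) {
    tmpl <- SelectionModel(m, t, chromosomeLength,
                           sites = data.frame(position = gp[i], s = sStart,
                                              h = h))
    fit <- twoStageFit(data, tmpl, free = "s", k = k, radius = radius,
                       eps = eps, gamma = gamma, config = config)
    data.frame(position = gp[i], bp = bp[i], loglikAlt = fit@loglik,
               loglikNull = llNull, llr = max(fit@loglik - llNull, 0),
               sHat = selectedSites(fit@model)$s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scanProfile", "data.frame")
  out
}

#' Local-maximum candidate sites from a scan profile
#'
#' A profile row is a candidate when its LLR is the maximum of the nearest
#' \code{window} profile rows and exceeds \code{threshold}; this removes
#' trivially close positions that likely reflect a single selected allele.
#'
#' @param profile output of \code{\link{singleSiteScan}}.
#' @param window neighborhood size in profile rows (default 1400 sampled
#'   sites, as appropriate for dense insect data; sparser data warrant
#'   smaller windows and higher thresholds, e.g. 300 and 40).
#' @param threshold minimum LLR (default 15).
#' @return data.frame of candidates (position, bp, llr, sHat), sorted by
#'   decreasing LLR.
#' @export
findPeaks <- function(profile, window = 1400, threshold = 15) {
  stopifnot(window >= 1, threshold >= 0)
  n <- nrow(profile)
  half <- max(1L, floor(window / 2))
  keep <- vapply(seq_len(n), function(i) {
    nb <- max(1L, i - half):min(n, i + half)
    profile$llr[i] > threshold &&
      profile$llr[i] == max(profile$llr[nb]) &&
      i == nb[which.max(profile$llr[nb])]  # ties: first position wins
  }, logical(1))
  out <- profile[keep, c("position", "bp", "llr", "sHat")]
  out <- out[order(-out$llr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fit the current null and the null + candidate alternative on one dataset.
.fitPair <- function(data, nullModel, candidatePos, sStart, h, k, radius,
                     eps, gamma, config) {
  nullFit <- twoStageFit(data, nullModel, free = "s", k = k, radius = radius,
                         eps = eps, gamma = gamma, config = config)
  altSites <- rbind(selectedSites(nullModel),
                    data.frame(position = candidatePos, s = sStart, h = h))
  altModel <- SelectionModel(nullModel@m, nullModel@t, nullModel@length,
                             altSites, nullModel@N)
  altFit <- twoStageFit(data, altModel, free = "s", k = k, radius = radius,
                        eps = eps, gamma = gamma, config = config)
  list(null = nullFit, alt = altFit,
       llr = max(altFit@loglik - nullFit@loglik, 0))
}

#' Null distribution of the likelihood ratio for one candidate site
#'
#' Simulates populations under the null model (finite calibration size N),
#' resamples reads at the template's markers, and on each replicate refits
#' both the null model and the null-plus-candidate alternative, recording
#' the log-likelihood ratio. Finite population size and read resampling
#' inflate this distribution beyond the asymptotic chi-squared expectation,
#' which is why the procedure calibrates against simulations.
#'
#' @param template a \code{MarkerDataset} whose markers/coverage the
#'   simulations copy.
#' @param nullModel the current null \code{SelectionModel}.
#' @param candidatePos genetic position of the tested site (Morgans).
#' @param nReps simulated replicates (default 20).
#' @param N calibration population size (default 10000, a conservative
#'   choice for large natural populations).
#' @param sStart,h starting value and dominance for the candidate site.
#' @param k,radius,eps,gamma,config forwarded to the fits.
#' @return Numeric vector of nReps nonnegative log-likelihood ratios.
#' @export
nullLRDistribution <- function(template, nullModel, candidatePos,
                               nReps = 20, N = 10000, sStart = 0.005,
                               h = 0.5, k = 4, radius = 0.02, eps = 0.01,
                               gamma = 0.01, config = simplexConfig()) {
  stopifnot(nReps >= 1)
  vapply(seq_len(nReps), function(rep) {
    sim <- simulateFromTemplate(template, nullModel, N = N, eps = eps)
    .fitPair(sim, nullModel, candidatePos, sStart, h, k, radius,
             eps, gamma, config)$llr
  }, numeric(1))
}

# Nearest-rank (exclusive) percentile: rank ceiling(p * (n + 1)), capped at
# n. With 20 replicates the 95th percentile is the maximum, a conservative
# threshold for small calibration runs.
.nearestRank <- function(x, p) {
  sort(x)[min(length(x), max(1L, ceiling(p * (length(x) + 1))))]
}

#' Iterative multi-locus model selection
#'
#' Starting from the neutral model, candidates are tested in order of
#' decreasing scan LLR. Each iteration fits the current null and the
#' null-plus-candidate alternative on the data, and compares their
#' log-likelihood ratio with the given percentile (nearest-rank) of the
#' ratio's distribution on \code{nReps} datasets simulated under the
#' current null. An accepted candidate's fitted model becomes the null for
#' subsequent iterations; a rejected candidate is discarded and never
#' revisited. Optionally the accepted sites' positions and then their
#' selection coefficients are re-optimized in a final refinement pass.
#'
#' @param data a \code{MarkerDataset}.
#' @param candidates data.frame with columns \code{position} and \code{llr}
#'   (e.g. from \code{\link{findPeaks}}); processed in decreasing LLR order.
#' @param m,t demography.
#' @param chromosomeLength in Morgans; defaults to the marker span.
#' @param nReps,N,percentile null-calibration settings (defaults 20, 10000,
#'   0.95).
#' @param h dominance used for every fitted site.
#' @param sStart starting s for newly added sites.
#' @param refine re-optimize positions then coefficients of accepted sites.
#' @param k,radius,eps,gamma,config forwarded to the fits.
#' @return List with \code{model} (final fitted \code{SelectionModel}),
#'   \code{loglik}, and \code{audit}: one row per candidate with the data
#'   LLR, the null-percentile threshold and the decision.
#' @export
iterativeSelection <- function(data, candidates, m, t,
                               chromosomeLength = NULL, nReps = 20,
                               N = 10000, percentile = 0.95, h = 0.5,
                               sStart = 0.005, refine = FALSE, k = 4,
                               radius = 0.02, eps = 0.01, gamma = 0.01,
                               config = simplexConfig()) {
  gp <- geneticPositions(data)
  if (is.null(chromosomeLength)) chromosomeLength <- max(gp) * 1.001
  candidates <- candidates[order(-candidates$llr), , drop = FALSE]
  nullModel <- SelectionModel(m, t, chromosomeLength, N = N)
  nullFit <- twoStageFit(data, nullModel, k = k, radius = radius,
                         eps = eps, gamma = gamma, config = config)
  audit <- data.frame(iteration = integer(0), position = numeric(0),
                      scanLLR = numeric(0), dataLLR = numeric(0),
                      nullPercentile = numeric(0), decision = character(0))
  iter <- 0L
  for (ci in seq_len(nrow(candidates))) {
    iter <- iter + 1L
    pos <- candidates$position[ci]
    pair <- .fitPair(data, nullModel, pos, sStart, h, k, radius,
                     eps, gamma, config)
    nullLLRs <- nullLRDistribution(data, nullModel, pos, nReps = nReps,
                                   N = N, sStart = sStart, h = h, k = k,
                                   radius = radius, eps = eps,
                                   gamma = gamma, config = config)
    thr <- .nearestRank(nullLLRs, percentile)
    accept <- pair$llr > thr
    audit <- rbind(audit, data.frame(
      iteration = iter, position = pos, scanLLR = candidates$llr[ci],
      dataLLR = pair$llr, nullPercentile = thr,
      decision = if (accept) "accepted" else "rejected"))
    if (accept) {
      nullModel <- pair$alt@model
      nullFit <- pair$alt
    }
  }
  if (refine && nrow(selectedSites(nullModel)) > 0) {
    # one cyclic pass: per-site (position, s) with the other sites held
    # fixed, then a joint re-optimization of all coefficients
    for (i in seq_len(nrow(selectedSites(nullModel)))) {
      fit <- .refineSite(data, nullModel, i, k, radius, eps, gamma, config)
      nullModel <- fit@model
      nullFit <- fit
    }
    nullFit <- twoStageFit(data, nullModel, free = "s", k = k,
                           radius = radius, eps = eps, gamma = gamma,
                           config = config)
    nullModel <- nullFit@model
  }
  list(model = nullModel, loglik = nullFit@loglik, audit = audit)
}

# Optimize (position, s) of site i holding the other sites fixed.
.refineSite <- function(data, model, i, k, radius, eps, gamma, config) {
  sites <- selectedSites(model)
  emis <- computeEmissions(data, eps, gamma)
  objective <- function(par) {
    st <- sites
    st$position[i] <- .decode01(par[1], 0, model@length)
    st$s[i] <- .decodeS(par[2])
    st <- st[order(st$position), , drop = FALSE]
    mod <- tryCatch(SelectionModel(model@m, model@t, model@length, st,
                                   model@N),
                    error = function(e) NULL)
    if (is.null(mod)) return(NaN)
    -forwardLoglik(mod, data, k = k, radius = radius, emissions = emis)
  }
  opt <- nelderMead(objective,
                    c(.encode01(sites$position[i], 0, model@length),
                      .encodeS(sites$s[i])), config)
  st <- sites
  st$position[i] <- .decode01(opt$par[1], 0, model@length)
  st$s[i] <- .decodeS(opt$par[2])
  st <- st[order(st$position), , drop = FALSE]
  new("FitResult",
      model = SelectionModel(model@m, model@t, model@length, st, model@N),
      loglik = -opt$value, evaluations = as.integer(opt$evaluations),
      converged = opt$converged, trace = opt$trace, flags = character(0))
}
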