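## Model-fitting drivers: maximize the forward log-likelihood over selected
## per-site parameters (s, h, position) with the two-stage simplex scheme,
## and neutral demographic fits of (m, t). Bounded parameters are optimized
## unconstrained through logit/log transforms: s on (-0.95, 0.95), h on
## (0, 1), position on (0, L), t on log scale.

.sMax <- 0.95
.encodeS <- function(s) qlogis((s + .sMax) / (2 * .sMax))
.decodeS <- function(x) plogis(x) * 2 * .sMax - .sMax
.encode01 <- function(p, lo = 0, hi = 1) {
  qlogis(pmin(pmax((p - lo) / (hi - lo), 1e-9), 1 - 1e-9))
}
.decode01 <- function(x, lo = 0, hi = 1) lo + plogis(x) * (hi - lo)

# Parameter vector layout for a model with free parameters per site.
.packParams <- function(sites, free, L = 1) {
  par <- numeric(0)
  for (i in seq_len(nrow(sites))) {
    if ("s" %in% free) par <- c(par, .encodeS(sites$s[i]))
    if ("h" %in% free) par <- c(par, .encode01(sites$h[i]))
    if ("position" %in% free) par <- c(par, .encode01(sites$position[i], 0, L))
  }
  par
}

.unpackParams <- function(par, sites, free, L) {
  j <- 1L
  for (i in seq_len(nrow(sites))) {
    if ("s" %in% free) { sites$s[i] <- .decodeS(par[j]); j <- j + 1L }
    if ("h" %in% free) { sites$h[i] <- .decode01(par[j]); j <- j + 1L }
    if ("position" %in% free) {
      sites$position[i] <- .decode01(par[j], 0, L)
      j <- j + 1L
    }
  }
  sites
}

#' Fit a selection model by two-stage simplex likelihood maximization
#'
#' Maximizes the forward log-likelihood of \code{data} over the chosen free
#' parameters of every selected site in \code{model} (demography stays
#' fixed). With no sites or no free parameters the bare log-likelihood of
#' the template model is returned. Fitted negative selection coefficients
#' (selection favoring ancestry 1) are allowed but flagged.
#'
#' @param data a \code{MarkerDataset}.
#' @param model template \code{SelectionModel}; site values are the
#'   optimization start.
#' @param free character subset of \code{c("s", "h", "position")} freed at
#'   every site (default "s"; fix h for additive or dominant fits).
#' @param k,radius,eps,gamma forwarded to \code{\link{forwardLoglik}}.
#' @param config a \code{\link{simplexConfig}}.
#' @return A \code{FitResult}.
#' @export
twoStageFit <- function(data, model, free = "s", k = 4, radius = 0.02,
                        eps = 0.01, gamma = 0.01,
                        config = simplexConfig()) {
  stopifnot(all(free %in% c("s", "h", "position")))
  sites <- selectedSites(model)
  emis <- computeEmissions(data, eps, gamma)
  gp <- geneticPositions(data)
  objective <- function(par) {
    st <- .unpackParams(par, sites, free, model@length)
    st <- st[order(st$position), , drop = FALSE]
    mod <- tryCatch(
      SelectionModel(model@m, model@t, model@length, st, model@N),
      error = function(e) NULL)
    if (is.null(mod)) return(NaN)
    -forwardLoglik(mod, data, k = k, radius = radius, emissions = emis)
  }
  if (nrow(sites) == 0 || length(free) == 0) {
    ll <- forwardLoglik(model, data, k = k, radius = radius, emissions = emis)
    return(new("FitResult", model = model, loglik = ll, evaluations = 1L,
               converged = TRUE,
               trace = data.frame(stage = integer(0), start = integer(0),
                                  size = numeric(0), evals = integer(0),
                                  value = numeric(0)),
               flags = character(0)))
  }
  start <- .packParams(sites, free, model@length)
  opt <- nelderMead(objective, start, config)
  stFit <- .unpackParams(opt$par, sites, free, model@length)
  stFit <- stFit[order(stFit$position), , drop = FALSE]
  fitted <- SelectionModel(model@m, model@t, model@length, stFit, model@N)
  flags <- character(0)
  if (any(stFit$s < 0))
    flags <- c(flags, "negative fitted s: selection favoring ancestry 1")
  new("FitResult", model = fitted, loglik = -opt$value,
      evaluations = as.integer(opt$evaluations), converged = opt$converged,
      trace = opt$trace, flags = flags)
}

#' Fit the neutral demography (m, t) of an admixed population
#'
#' Maximizes the neutral-model forward likelihood over the admixture
#' fraction m and the (integer) time since admixture t, assuming the data
#' are free of strong selection (in practice: run on a chromosome without
#' selection signals). t is searched on a log scale, rounded per evaluation,
#' and refined over +/- 2 integers around the continuous optimum.
#'
#' @param data a \code{MarkerDataset}.
#' @param mStart,tStart search starting point.
#' @param chromosomeLength chromosome length in Morgans; defaults to the
#'   span of the markers.
#' @param k,eps,gamma forwarded to the likelihood.
#' @param config a \code{\link{simplexConfig}}.
#' @return A \code{FitResult} holding the fitted neutral model; flags note
#'   boundary optima (m near 0 or 1).
#' @export
fitDemography <- function(data, mStart = 0.5, tStart = 100,
                          chromosomeLength = NULL, k = 4,
                          eps = 0.01, gamma = 0.01,
                          config = simplexConfig()) {
  gp <- geneticPositions(data)
  if (is.null(chromosomeLength)) chromosomeLength <- max(gp) * 1.001
  emis <- computeEmissions(data, eps, gamma)
  neutral <- function(m, t) {
    SelectionModel(m, t, chromosomeLength)
  }
  objective <- function(par) {
    m <- .decode01(par[1], 1e-4, 1 - 1e-4)
    t <- max(1L, as.integer(round(exp(par[2]))))
    -forwardLoglik(neutral(m, t), data, k = k, emissions = emis)
  }
  opt <- nelderMead(objective, c(.encode01(mStart, 1e-4, 1 - 1e-4),
                                 log(tStart)), config)
  mHat <- .decode01(opt$par[1], 1e-4, 1 - 1e-4)
  tCont <- max(1L, as.integer(round(exp(opt$par[2]))))
  tGrid <- unique(pmax(1L, tCont + (-2:2)))
  lls <- vapply(tGrid, function(tt)
    forwardLoglik(neutral(mHat, tt), data, k = k, emissions = emis),
    numeric(1))
  tHat <- tGrid[which.max(lls)]
  flags <- character(0)
  if (mHat < 0.01 || mHat > 0.99)
    flags <- c(flags, "admixture fraction at the search boundary")
  new("FitResult", model = neutral(mHat, tHat), loglik = max(lls),
      evaluations = as.integer(opt$evaluations + length(tGrid)),
      converged = opt$converged, trace = opt$trace, flags = flags)
}
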