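## Forward-algorithm likelihood and forward-backward posterior decoding for
## the three-state (ancestry-0 dosage) chain, vectorized across samples with
## per-marker scaling.

.initialDistribution <- function(m) c((1 - m)^2, 2 * m * (1 - m), m^2)

# Forward pass over the retained markers. E: (nUsed x 3 x nS); Td: 3x3xnInt.
# Returns list(loglik per sample, alphas if keep).
.forwardPass <- function(Td, E, pi0, keep = FALSE) {
  nU <- dim(E)[1]
  nS <- dim(E)[3]
  alpha <- matrix(pi0, nS, 3, byrow = TRUE) * t(E[1, , , drop = TRUE])
  dim(alpha) <- c(nS, 3)
  sc <- rowSums(alpha)
  bad <- sc <= 0
  if (any(bad)) { alpha[bad, ] <- 1 / 3; sc[bad] <- 1e-300 }
  alpha <- alpha / sc
  ll <- log(sc)
  alphas <- if (keep) array(NA_real_, c(nU, nS, 3)) else NULL
  if (keep) alphas[1, , ] <- alpha
  for (i in seq_len(nU - 1)) {
    alpha <- (alpha %*% Td[, , i]) * t(E[i + 1, , , drop = TRUE])
    sc <- rowSums(alpha)
    bad <- sc <= 0
    if (any(bad)) { alpha[bad, ] <- 1 / 3; sc[bad] <- 1e-300 }
    alpha <- alpha / sc
    ll <- ll + log(sc)
    if (keep) alphas[i + 1, , ] <- alpha
  }
  list(loglik = ll, alphas = alphas)
}

#' Forward-algorithm log-likelihood of a selection model
#'
#' Computes the log-likelihood of a multi-locus selection model given the
#' read-pileup or genotype observations, summing independent per-sample
#' forward log-likelihoods over the hidden ancestry-dosage chain. The chain
#' starts from the stationary pulse distribution ((1-m)^2, 2m(1-m), m^2) and
#' uses the expected transition probabilities of the model; the \code{k} and
#' \code{radius} speed-ups of \code{\link{transitionsAlongChromosome}}
#' apply (every marker keeps its emissions; \code{k} only thins the window
#' evolutions).
#'
#' @param model a \code{SelectionModel}.
#' @param data a \code{MarkerDataset}.
#' @param k marker thinning (default 4).
#' @param radius selected-site influence radius in Morgans (default 0.02).
#' @param eps,gamma emission error parameters.
#' @param emissions optional precomputed array from
#'   \code{\link{computeEmissions}} (full marker set); avoids recomputation
#'   inside optimization loops.
#' @param transitions optional precomputed \code{TransitionSet}.
#' @return Scalar log-likelihood.
#' @export
forwardLoglik <- function(model, data, k = 4, radius = 0.02,
                          eps = 0.01, gamma = 0.01, emissions = NULL,
                          transitions = NULL) {
  if (is.null(emissions)) emissions <- computeEmissions(data, eps, gamma)
  if (is.null(transitions))
    transitions <- transitionsAlongChromosome(model, geneticPositions(data),
                                              radius = radius, k = k)
  used <- transitions@usedIdx
  E <- emissions[used, , , drop = FALSE]
  if (dim(E)[3] == 0) return(0)
  cpp_forward_loglik(transitions@diploid, E, .initialDistribution(model@m))
}

# Split the chromosome into segments at midpoints of the largest inter-site
# gaps so no segment holds more than maxSites sites.
.decodeSegments <- function(sites, L, maxSites) {
  n <- nrow(sites)
  if (n <= maxSites) return(data.frame(from = 0, to = L))
  nSeg <- ceiling(n / maxSites)
  gaps <- diff(sites$position)
  cut <- sort(order(gaps, decreasing = TRUE)[seq_len(nSeg - 1)])
  mids <- (sites$position[cut] + sites$position[cut + 1]) / 2
  data.frame(from = c(0, mids), to = c(mids, L))
}

#' Posterior decoding of local ancestry
#'
#' Forward-backward posterior probabilities of ancestry-0 dosage for every
#' sample at every marker. Decoding folds in the effects of all selected
#' sites (\code{radius = Inf}, \code{k = 1} by default). Because the cost of
#' the transition computation is exponential in the number of sites per
#' tracked window, models with more than \code{maxSites} sites are refused
#' unless \code{split = TRUE}, in which case the chromosome is decoded in
#' segments cut at the largest inter-site gaps.
#'
#' @inheritParams forwardLoglik
#' @param split split the chromosome at large inter-site gaps when the model
#'   has more than \code{maxSites} sites.
#' @param maxSites maximum sites folded into one decoded segment (default 6).
#' @return Array (markers x samples x 3) of posterior dosage probabilities;
#'   rows sum to 1.
#' @export
posteriorDecode <- function(model, data, k = 1, radius = Inf,
                            eps = 0.01, gamma = 0.01, split = FALSE,
                            maxSites = 6) {
  sites <- selectedSites(model)
  if (nrow(sites) > maxSites && !split)
    stop("model has ", nrow(sites), " sites; decoding cost is exponential ",
         "in the number of sites per window. Call with split = TRUE to ",
         "decode the chromosome in segments cut at large inter-site gaps.")
  gp <- geneticPositions(data)
  segs <- .decodeSegments(sites, model@length, maxSites)
  nM <- nrow(data)
  nS <- ncol(data)
  post <- array(NA_real_, c(nM, nS, 3))
  emissions <- computeEmissions(data, eps, gamma)
  for (si in seq_len(nrow(segs))) {
    midx <- which(gp >= segs$from[si] & gp <= segs$to[si])
    if (length(midx) < 2) next
    segSites <- sites[sites$position >= segs$from[si] &
                      sites$position <= segs$to[si], , drop = FALSE]
    segModel <- SelectionModel(model@m, model@t, model@length,
                               sites = segSites, N = model@N)
    ts <- transitionsAlongChromosome(segModel, gp[midx],
                                     radius = radius, k = k)
    used <- midx[ts@usedIdx]
    E <- emissions[used, , , drop = FALSE]
    pi0 <- .initialDistribution(model@m)
    fw <- .forwardPass(ts@diploid, E, pi0, keep = TRUE)
    nU <- length(used)
    beta <- matrix(1, nS, 3)
    post[used[nU], , ] <- fw$alphas[nU, , ]
    for (i in rev(seq_len(nU - 1))) {
      eb <- t(E[i + 1, , , drop = TRUE]) * beta
      dim(eb) <- c(nS, 3)
      beta <- eb %*% t(ts@diploid[, , i])
      beta <- beta / pmax(rowSums(beta), 1e-300)
      g <- fw$alphas[i, , ] * beta
      post[used[i], , ] <- g / pmax(rowSums(g), 1e-300)
    }
  }
  post
}
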