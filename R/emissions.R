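## Emission probabilities for the three ancestry-dosage states. Panel allele
## frequencies are estimated with 0.5 pseudo-counts; given ancestry dosage z,
## each chromosome carries the A allele with the frequency of its ancestry,
## the three possible allelic genotypes g are marginalized, and reads are
## binomial draws with sequencing error eps. This is a deliberately simple,
## swappable emission model (it ignores finite-panel sampling corrections).

# P(g | z) weights: list over z = 0, 1, 2 of (nM x 3) matrices over g.
.genotypeWeights <- function(f0, f1) {
  list(
    z0 = cbind((1 - f1)^2, 2 * f1 * (1 - f1), f1^2),
    z1 = cbind((1 - f0) * (1 - f1), f0 * (1 - f1) + f1 * (1 - f0), f0 * f1),
    z2 = cbind((1 - f0)^2, 2 * f0 * (1 - f0), f0^2))
}

#' Emission probabilities for a marker dataset
#'
#' Likelihood of each sample's observation at each marker under ancestry-0
#' dosage z in {0, 1, 2}. Pileup mode: reads_A ~ Binomial(total, q_g) with
#' q_g = (g/2)(1 - eps) + (1 - g/2) eps, marginalized over the allelic
#' genotype g given z and the panel allele frequencies (0.5 pseudo-counts).
#' Genotype mode: observed dosage equals g with probability 1 - gamma,
#' either other value with probability gamma / 2. Missing observations give
#' (1, 1, 1). Markers whose panels are empty carry no information and are
#' skipped (flat emissions) with a warning.
#'
#' @param data a \code{MarkerDataset}.
#' @param eps per-read sequencing error in [0, 0.5).
#' @param gamma genotyping error for genotype mode.
#' @return Array of dimension (markers, 3, samples); second dimension is
#'   z = 0, 1, 2 ancestry-0 copies.
#' @export
computeEmissions <- function(data, eps = 0.01, gamma = 0.01) {
  stopifnot(eps >= 0, eps < 0.5)
  pc <- panelCounts(data)
  n0 <- pc[, "p0A"] + pc[, "p0a"]
  n1 <- pc[, "p1A"] + pc[, "p1a"]
  empty <- n0 == 0 | n1 == 0
  if (any(empty))
    warning(sum(empty), " marker(s) with an empty parental panel carry no ",
            "information and are skipped")
  f0 <- (pc[, "p0A"] + 0.5) / (n0 + 1)
  f1 <- (pc[, "p1A"] + 0.5) / (n1 + 1)
  W <- .genotypeWeights(f0, f1)
  nM <- nrow(data)
  nS <- ncol(data)
  E <- array(1, c(nM, 3, nS))
  if (nS == 0) return(E)
  if (datasetMode(data) == "pileup") {
    rA <- SummarizedExperiment::assay(data, "readsA")
    rT <- SummarizedExperiment::assay(data, "readsTot")
    obs <- !is.na(rT) & rT > 0
    q <- c(eps, 0.5, 1 - eps)
    Lg <- lapply(1:3, function(g) {
      L <- matrix(1, nM, nS)
      L[obs] <- dbinom(rA[obs], rT[obs], q[g])
      L
    })
    for (z in 1:3) {
      Ez <- W[[z]][, 1] * Lg[[1]] + W[[z]][, 2] * Lg[[2]] + W[[z]][, 3] * Lg[[3]]
      Ez[!obs] <- 1
      Ez[empty, ] <- 1
      E[, z, ] <- Ez
    }
  } else {
    dg <- SummarizedExperiment::assay(data, "dosage")
    obs <- !is.na(dg)
    for (z in 1:3) {
      Ez <- matrix(1, nM, nS)
      for (g in 0:2) {
        Pobs <- matrix(0, nM, nS)
        Pobs[obs] <- ifelse(dg[obs] == g, 1 - gamma, gamma / 2)
        if (g == 0) Ezacc <- W[[z]][, g + 1] * Pobs
        else Ezacc <- Ezacc + W[[z]][, g + 1] * Pobs
      }
      Ezacc[!obs] <- 1
      Ezacc[empty, ] <- 1
      E[, z, ] <- Ezacc
    }
  }
  E
}

#' Diploid transition matrix from a haploid one
#'
#' The two chromosomes of an unphased diploid transition independently; from
#' dosage 1 the ancestry-0 and ancestry-1 chromosomes each follow their own
#' row of A. States are ancestry-0 dosage 0, 1, 2.
#'
#' @param A 2x2 row-stochastic haploid transition (row/col 1 = ancestry 0).
#' @return 3x3 row-stochastic matrix.
#' @export
diploidTransition <- function(A) {
  a00 <- A[1, 1]; a01 <- A[1, 2]
  a10 <- A[2, 1]; a11 <- A[2, 2]
  matrix(c(
    a11^2,        2 * a10 * a11,            a10^2,
    a01 * a11,    a00 * a11 + a01 * a10,    a00 * a10,
    a01^2,        2 * a00 * a01,            a00^2),
    3, 3, byrow = TRUE)
}

# Vectorized diploidTransition over a 2 x 2 x n array.
.diploidTransitionArray <- function(A) {
  a00 <- A[1, 1, ]; a01 <- A[1, 2, ]; a10 <- A[2, 1, ]; a11 <- A[2, 2, ]
  Td <- array(NA_real_, c(3, 3, dim(A)[3]))
  Td[1, 1, ] <- a11^2
  Td[1, 2, ] <- 2 * a10 * a11
  Td[1, 3, ] <- a10^2
  Td[2, 1, ] <- a01 * a11
  Td[2, 2, ] <- a00 * a11 + a01 * a10
  Td[2, 3, ] <- a00 * a10
  Td[3, 1, ] <- a01^2
  Td[3, 2, ] <- 2 * a00 * a01
  Td[3, 3, ] <- a00^2
  Td
}
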