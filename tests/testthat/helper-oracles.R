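# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ code paths: the gamete enumerator walks every
# (parent pair, crossover interval) outcome directly, and the forward oracle
# sums over all hidden dosage paths.

# One full generation (random mating -> selection + single-crossover
# recombination -> normalization) by exhaustive enumeration over parent
# pairs and gamete outcomes. H indexed MSB-first as in the package.
oracleGeneration <- function(H, s, h, r) {
  P <- length(s)
  nh <- 2^P
  bit <- function(idx, p) bitwAnd(bitwShiftR(idx, P - p), 1L)
  fitness <- function(a, b) {
    w <- 1
    for (p in seq_len(P)) {
      d0 <- (bit(a, p) == 0) + (bit(b, p) == 0)
      w <- w * if (d0 == 2) 1 else if (d0 == 1) 1 - h[p] * s[p] else 1 - s[p]
    }
    w
  }
  out <- numeric(nh)
  stay <- 1 - sum(r)
  for (a in 0:(nh - 1)) for (b in 0:(nh - 1)) {
    D <- H[a + 1] * H[b + 1]
    if (D == 0) next
    S <- fitness(a, b)
    out[a + 1] <- out[a + 1] + D * S * stay
    out[b + 1] <- out[b + 1] + D * S * stay
    for (j in seq_len(P - 1)) {
      leftMask <- bitwShiftL(bitwShiftL(1L, j) - 1L, P - j)
      rightMask <- bitwAnd(nh - 1L, bitwNot(leftMask))
      k <- bitwOr(bitwAnd(a, leftMask), bitwAnd(b, rightMask))
      l <- bitwOr(bitwAnd(b, leftMask), bitwAnd(a, rightMask))
      out[k + 1] <- out[k + 1] + D * S * r[j]
      out[l + 1] <- out[l + 1] + D * S * r[j]
    }
  }
  out / sum(out)
}

# Exhaustive-path forward likelihood for one sample: sum over all 3^nM
# dosage paths of prior * transitions * emissions.
oraclePathLoglik <- function(Td, E, pi0) {
  nM <- dim(E)[1]
  paths <- as.matrix(expand.grid(rep(list(1:3), nM)))
  tot <- 0
  for (pi in seq_len(nrow(paths))) {
    z <- paths[pi, ]
    p <- pi0[z[1]] * E[1, z[1]]
    for (i in seq_len(nM - 1))
      p <- p * Td[z[i], z[i + 1], i] * E[i + 1, z[i + 1]]
    tot <- tot + p
  }
  log(tot)
}

# Direct-sum emission oracle for one pileup observation.
oracleEmission <- function(p0A, p0a, p1A, p1a, readsA, readsTot, eps) {
  f0 <- (p0A + 0.5) / (p0A + p0a + 1)
  f1 <- (p1A + 0.5) / (p1A + p1a + 1)
  gw <- list(c((1 - f1)^2, 2 * f1 * (1 - f1), f1^2),
             c((1 - f0) * (1 - f1), f0 * (1 - f1) + f1 * (1 - f0), f0 * f1),
             c((1 - f0)^2, 2 * f0 * (1 - f0), f0^2))
  sapply(1:3, function(z)
    sum(gw[[z]] * dbinom(readsA, readsTot, c(eps, 0.5, 1 - eps))))
}

# Hudson Fst estimator from two allele-frequency vectors with sample sizes.
hudsonFst <- function(f1, f2, n1, n2) {
  num <- (f1 - f2)^2 - f1 * (1 - f1) / (n1 - 1) - f2 * (1 - f2) / (n2 - 1)
  den <- f1 * (1 - f2) + f2 * (1 - f1)
  mean(num) / mean(den)
}

neutralSites <- function() data.frame(position = numeric(0), s = numeric(0),
                                      h = numeric(0))

# Small synthetic dataset helper used by several files.
makeSmallDataset <- function(model, N = 2000, nMarkers = 120, nSamples = 30,
                             depth = 2, F = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulateDataset(model, N = N, nMarkers = nMarkers, nSamples = nSamples,
                  depth = depth, F = F)
}
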