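# Emission, transition-assembly and forward/backward tests, anchored on the
# exhaustive-path oracle and on simulations with known truth.

makeTinyDataset <- function(readsA, readsTot, p0A = 10, p0a = 0, p1A = 0,
                            p1a = 10, gp = NULL) {
  nM <- nrow(readsA)
  if (is.null(gp)) gp <- seq(0, by = 0.01, length.out = nM)
  MarkerDataset(chrom = "chr1", bp = seq_len(nM) * 1000, geneticPos = gp,
                p0A = rep(p0A, nM), p0a = rep(p0a, nM),
                p1A = rep(p1A, nM), p1a = rep(p1a, nM),
                readsA = readsA, readsTot = readsTot)
}

test_that("diploid transitions compound two independent haploid chains", {
  expect_equal(diploidTransition(diag(2)), diag(3))
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  Td <- diploidTransition(A)
  expect_equal(Td[3, 3], 0.81)
  expect_equal(Td[3, 2], 0.18)
  expect_equal(Td[3, 1], 0.01)
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(runif(4), 2)
    A <- A / rowSums(A)
    expect_equal(rowSums(diploidTransition(A)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("emissions: no reads are uninformative; error 0.5 flattens everything", {
  ds <- makeTinyDataset(matrix(0, 3, 2), matrix(0, 3, 2))
  E <- computeEmissions(ds)
  expect_true(all(E == 1))
  ds2 <- makeTinyDataset(matrix(3, 3, 2), matrix(5, 3, 2), p0A = 8, p0a = 2,
                         p1A = 3, p1a = 7)
  E2 <- computeEmissions(ds2, eps = 0.4999999)
  expect_equal(E2[, 1, ], E2[, 2, ], tolerance = 1e-5)
  expect_equal(E2[, 2, ], E2[, 3, ], tolerance = 1e-5)
})

test_that("emissions match the direct-sum oracle, including fixed differences", {
  # near-fixed panels, 5 reads all A: likelihoods approach (0, 0.5^5, 1)
  ds <- makeTinyDataset(matrix(5, 1, 1), matrix(5, 1, 1), p0A = 1000,
                        p0a = 0, p1A = 0, p1a = 1000)
  E <- computeEmissions(ds, eps = 0)
  oracle <- oracleEmission(1000, 0, 0, 1000, 5, 5, 0)
  expect_equal(as.vector(E[1, , 1]), oracle, tolerance = 1e-12)
  expect_equal(oracle, c(0, 0.5^5, 1), tolerance = 0.01)
  # a generic panel/observation case against the oracle
  ds2 <- makeTinyDataset(matrix(2, 1, 1), matrix(7, 1, 1), p0A = 12,
                         p0a = 8, p1A = 3, p1a = 17)
  expect_equal(as.vector(computeEmissions(ds2, eps = 0.02)[1, , 1]),
               oracleEmission(12, 8, 3, 17, 2, 7, 0.02), tolerance = 1e-12)
})

test_that("genotype-mode emissions marginalize genotypes with symmetric error", {
  ds <- MarkerDataset("chr1", c(100, 200), c(0, 0.01),
                      p0A = c(18, 3), p0a = c(2, 17), p1A = c(2, 15),
                      p1a = c(18, 5), dosage = matrix(c(2, NA), 2, 1))
  gamma <- 0.06
  E <- computeEmissions(ds, gamma = gamma)
  f0 <- (c(18, 3) + 0.5) / 21
  f1 <- (c(2, 15) + 0.5) / 21
  # oracle: P(obs | z) = sum_g P(g | z) P(obs | g), marker 1, obs = 2
  gw <- list(c((1 - f1[1])^2, 2 * f1[1] * (1 - f1[1]), f1[1]^2),
             c((1 - f0[1]) * (1 - f1[1]),
               f0[1] * (1 - f1[1]) + f1[1] * (1 - f0[1]), f0[1] * f1[1]),
             c((1 - f0[1])^2, 2 * f0[1] * (1 - f0[1]), f0[1]^2))
  pObs <- c(gamma / 2, gamma / 2, 1 - gamma)  # for g = 0, 1, 2
  for (z in 1:3)
    expect_equal(E[1, z, 1], sum(gw[[z]] * pObs), tolerance = 1e-12)
  # missing genotype carries no information
  expect_equal(as.vector(E[2, , 1]), c(1, 1, 1))
})

test_that("markers with empty panels are flagged and carry flat emissions", {
  ds <- MarkerDataset("chr1", c(100, 200), c(0, 0.01),
                      p0A = c(0, 5), p0a = c(0, 5), p1A = c(0, 2),
                      p1a = c(0, 8),
                      readsA = matrix(2, 2, 1), readsTot = matrix(4, 2, 1))
  expect_warning(E <- computeEmissions(ds), "empty parental panel")
  expect_equal(as.vector(E[1, , 1]), c(1, 1, 1))
})

test_that("forward log-likelihood equals the exhaustive-path oracle", {
  set.seed(11)
  m <- 0.3
  model <- SelectionModel(m, 30, 0.1,
                          sites = data.frame(position = 0.015, s = 0.1,
                                             h = 0.5))
  rA <- matrix(rbinom(4, 4, 0.5), 4, 1)
  ds <- makeTinyDataset(rA, matrix(4, 4, 1), p0A = 9, p0a = 1, p1A = 2,
                        p1a = 8)
  ll <- forwardLoglik(model, ds, k = 1, radius = 1)
  ts <- transitionsAlongChromosome(model, geneticPositions(ds), radius = 1,
                                   k = 1)
  E <- computeEmissions(ds)[, , 1]
  oracle <- oraclePathLoglik(ts@diploid, E,
                             c((1 - m)^2, 2 * m * (1 - m), m^2))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("sample independence: duplicating every sample doubles the log-likelihood", {
  set.seed(12)
  model <- SelectionModel(0.2, 50, 0.3)
  sim <- makeSmallDataset(model, N = 500, nMarkers = 40, nSamples = 10,
                          seed = 12)
  d1 <- sim$data
  rA <- SummarizedExperiment::assay(d1, "readsA")
  rT <- SummarizedExperiment::assay(d1, "readsTot")
  rd <- SummarizedExperiment::rowData(d1)
  rr <- SummarizedExperiment::rowRanges(d1)
  d2 <- MarkerDataset(as.character(GenomicRanges::seqnames(rr)),
                      GenomicRanges::start(rr), rd$geneticPos, rd$p0A,
                      rd$p0a, rd$p1A, rd$p1a,
                      readsA = cbind(rA, rA), readsTot = cbind(rT, rT))
  expect_equal(forwardLoglik(model, d2), 2 * forwardLoglik(model, d1),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to reversing the chromosome", {
  set.seed(13)
  model <- SelectionModel(0.25, 60, 0.2,
                          sites = data.frame(position = 0.09, s = 0.05,
                                             h = 0.5))
  sim <- makeSmallDataset(SelectionModel(0.25, 60, 0.2), N = 400,
                          nMarkers = 50, nSamples = 8, seed = 13)
  d1 <- sim$data
  rd <- SummarizedExperiment::rowData(d1)
  rr <- SummarizedExperiment::rowRanges(d1)
  n <- nrow(d1)
  L <- 0.2
  rev_gp <- rev(L - rd$geneticPos)
  d2 <- MarkerDataset(as.character(GenomicRanges::seqnames(rr))[n:1],
                      rev(2e7 - GenomicRanges::start(rr)), rev_gp,
                      rev(rd$p0A), rev(rd$p0a), rev(rd$p1A), rev(rd$p1a),
                      readsA = SummarizedExperiment::assay(d1, "readsA")[n:1, , drop = FALSE],
                      readsTot = SummarizedExperiment::assay(d1, "readsTot")[n:1, , drop = FALSE])
  model2 <- SelectionModel(0.25, 60, 0.2,
                           sites = data.frame(position = L - 0.09, s = 0.05,
                                              h = 0.5))
  # exact under neutrality (the chain is reversible and the pulse prior is
  # its true marginal) ...
  neutral <- SelectionModel(0.25, 60, 0.2)
  expect_equal(forwardLoglik(neutral, d1, k = 1),
               forwardLoglik(neutral, d2, k = 1), tolerance = 1e-6)
  # ... and approximate with selection, where the neutral pulse prior is
  # only an approximation to the hitchhiked end-marker marginal
  expect_equal(forwardLoglik(model, d1, k = 1, radius = 0.05),
               forwardLoglik(model2, d2, k = 1, radius = 0.05),
               tolerance = 0.01)
})

test_that("posterior decoding recovers the prior without data and sums to one", {
  model <- SelectionModel(0.3, 50, 0.1)
  ds <- makeTinyDataset(matrix(0, 10, 3), matrix(0, 10, 3),
                        gp = seq(0, 0.09, by = 0.01))
  post <- posteriorDecode(model, ds)
  prior <- c(0.49, 0.42, 0.09)
  for (j in 1:3)
    expect_equal(post[, j, ], matrix(prior, 10, 3, byrow = TRUE),
                 tolerance = 1e-9)
})

test_that("deep-coverage decoding recovers the simulated dosage", {
  set.seed(21)
  model <- SelectionModel(0.3, 30, 0.2)
  pos <- seq(0.002, 0.198, length.out = 60)
  panels <- MarkerDataset("chr1", round(pos * 5e7), pos,
                          p0A = rep(200, 60), p0a = rep(0, 60),
                          p1A = rep(0, 60), p1a = rep(200, 60),
                          extraRowData = data.frame(freq0 = rep(1, 60),
                                                    freq1 = rep(0, 60)))
  pop <- simulatePopulation(model, N = 300)
  ds <- sampleReads(pop, panels, nSamples = 20, depth = 30, eps = 0.001)
  post <- posteriorDecode(model, ds)
  call <- apply(post, c(1, 2), which.max) - 1
  truth <- SummarizedExperiment::assay(ds, "trueDosage")
  expect_gte(mean(call == truth), 0.99)
  expect_equal(apply(post, c(1, 2), sum),
               matrix(1, nrow(ds), ncol(ds)), tolerance = 1e-9)
  # mean posterior dosage tracks the sampled individuals' true ancestry
  expect_equal(mean(post[, , 2] / 2 + post[, , 3]), mean(truth) / 2,
               tolerance = 0.02)
})

test_that("decoding refuses over-large site sets unless splitting is allowed", {
  sites <- data.frame(position = seq(0.01, 0.07, by = 0.01), s = 0.01,
                      h = 0.5)
  model <- SelectionModel(0.2, 10, 0.1, sites = sites)
  ds <- makeTinyDataset(matrix(1, 12, 1), matrix(2, 12, 1),
                        gp = seq(0.005, 0.095, length.out = 12))
  expect_error(posteriorDecode(model, ds), "split")
  post <- posteriorDecode(model, ds, split = TRUE)
  expect_equal(apply(post, c(1, 2), sum), matrix(1, 12, 1),
               tolerance = 1e-9)
})
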