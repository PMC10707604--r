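# Oracle and property tests for the haplotype-distribution machinery: the
# brute-force gamete enumerator (helper-oracles.R), the one-locus recursion,
# and the neutral junction closed form all check the same quantities through
# independent routes.

test_that("initial haplotype distribution has only the two founder haplotypes", {
  H <- initHaplotypes(0.2, 3)
  expect_equal(H, c(0.2, 0, 0, 0, 0, 0, 0, 0.8))
  expect_equal(initHaplotypes(0.5, 2), c(0.5, 0, 0, 0.5))
  for (m in c(0.05, 0.33, 0.9)) expect_equal(sum(initHaplotypes(m, 4)), 1)
  expect_error(initHaplotypes(0, 3), "m must")
  expect_error(initHaplotypes(1.4, 3), "m must")
})

test_that("diploid distribution is the normalized symmetric tensor product", {
  H <- c(0.2, 0, 0, 0.8)
  D <- diploidDistribution(H)
  expect_equal(D[1], 0.04)
  expect_equal(D[4], 0.16)
  expect_equal(D[13], 0.16)
  expect_equal(D[16], 0.64)
  expect_equal(sum(D[-c(1, 4, 13, 16)]), 0)
  set.seed(1)
  H2 <- runif(8)
  H2 <- H2 / sum(H2)
  D2 <- diploidDistribution(H2)
  expect_equal(sum(D2), 1)
  M2 <- matrix(D2, 8, 8, byrow = TRUE)
  expect_equal(M2, t(M2))
})

test_that("transform row sums equal exactly twice the diploid fitness", {
  s <- c(0, 0.1, -0.2, 0)
  h <- c(0.5, 0.3, 0.8, 0.5)
  r <- c(0.01, 0.005, 0.02)
  M <- buildTransform(s, h, r)
  P <- 4L
  nh <- 2L^P
  bit <- function(idx, p) bitwAnd(bitwShiftR(idx, P - p), 1L)
  S <- sapply(0:(nh * nh - 1), function(i) {
    a <- i %/% nh; b <- i %% nh
    w <- 1
    for (p in 1:P) {
      d0 <- (bit(a, p) == 0) + (bit(b, p) == 0)
      w <- w * if (d0 == 2) 1 else if (d0 == 1) 1 - h[p] * s[p] else 1 - s[p]
    }
    w
  })
  expect_equal(rowSums(M), 2 * S, tolerance = 1e-14)
  expect_true(all(M >= 0))
  expect_error(buildTransform(c(0, 0), c(0.5, 0.5), 1.2), "split the window")
})

test_that("homozygote rows put all mass on the parental haplotype", {
  M <- buildTransform(c(0, 0.1), c(0.5, 0.5), 0.03)
  nh <- 4L
  for (a in 0:(nh - 1)) {
    row <- M[a * nh + a + 1, ]
    expect_equal(which(row > 0), a + 1L)
  }
})

test_that("one generation of the machinery equals the brute-force gamete enumerator", {
  set.seed(42)
  for (rep in 1:5) {
    P <- sample(2:4, 1)
    s <- c(0, runif(P - 2, -0.3, 0.3), 0)
    h <- runif(P, 0, 1)
    r <- runif(P - 1, 0, 0.05)
    H <- runif(2^P)
    H <- H / sum(H)
    M <- buildTransform(s, h, r)
    expect_equal(evolveHaplotypes(H, M, 1), oracleGeneration(H, s, h, r),
                 tolerance = 1e-12)
  }
  # hand-sized case: one selected site between two markers
  s <- c(0, 0.1, 0)
  h <- c(0.5, 0.5, 0.5)
  r <- c(0.01, 0.02)
  H0 <- initHaplotypes(0.3, 3)
  expect_equal(evolveHaplotypes(H0, buildTransform(s, h, r), 1),
               oracleGeneration(H0, s, h, r), tolerance = 1e-14)
})

test_that("evolution keeps probability vectors normalized and t = 0 is identity", {
  H0 <- initHaplotypes(0.2, 3)
  M <- buildTransform(c(0, 0.2, 0), c(0.5, 1, 0.5), c(0.01, 0.02))
  expect_identical(evolveHaplotypes(H0, M, 0), H0)
  H <- H0
  for (g in 1:20) {
    H <- evolveHaplotypes(H, M, 1)
    expect_true(all(H >= 0))
    expect_equal(sum(H), 1, tolerance = 1e-12)
  }
})

test_that("neutral evolution conserves every marginal at m", {
  m <- 0.3
  H <- admixsel:::cpp_evolve_window(rep(0, 3), rep(0.5, 3),
                                    c(0.02, 0.03), m, 40)
  idx <- seq_along(H) - 1L
  for (p in 1:3) {
    marg <- sum(H[admixsel:::.bitAt(idx, p, 3L) == 0])
    expect_equal(marg, m, tolerance = 1e-12)
  }
})

test_that("single-locus marginal equals the one-locus recursion per generation", {
  m <- 0.2
  s <- 0.05
  h <- 0.7
  tr <- oneLocusTrajectory(m, s, h, 120)
  H <- initHaplotypes(m, 3)
  M <- buildTransform(c(0, s, 0), c(0.5, h, 0.5), c(0.004, 0.006))
  idx <- seq_along(H) - 1L
  for (g in 1:120) {
    H <- evolveHaplotypes(H, M, 1)
    marg <- sum(H[admixsel:::.bitAt(idx, 2L, 3L) == 0])
    expect_equal(marg, tr[g + 1], tolerance = 1e-10)
  }
})

test_that("neutral two-locus association decays geometrically as (1-r)^t", {
  m <- 0.2
  r <- 0.01
  for (t in c(1, 10, 200)) {
    H <- admixsel:::cpp_evolve_window(c(0, 0), c(0.5, 0.5), r, m, t)
    expect_equal(H[1] - m^2, (m - m^2) * (1 - r)^t, tolerance = 1e-12)
  }
})

test_that("transition extraction matches the junction closed form under neutrality", {
  m <- 0.2
  d <- 0.015
  t <- 80
  A <- windowTransition(0.1, 0.1 + d, neutralSites(), m, t)
  expect_equal(A, neutralTransition(d, m, t), tolerance = 1e-9)
  cc <- (1 - d)^t
  expect_equal(A[1, 1], cc + (1 - cc) * m, tolerance = 1e-9)
  expect_equal(A[2, 1], (1 - cc) * m, tolerance = 1e-9)
})

test_that("neutral closed form: identity at d = 0 and single-generation junction rate", {
  expect_equal(neutralTransition(0, 0.3, 100), diag(2))
  A <- neutralTransition(0.01, 0.2, 1)
  expect_equal(A[1, 2], 0.008)
  # grid equality against the numerical machinery
  for (d in c(0.001, 0.02)) for (m in c(0.1, 0.5)) for (t in c(5, 150)) {
    expect_equal(windowTransition(0, d, neutralSites(), m, t),
                 neutralTransition(d, m, t), tolerance = 1e-9)
  }
})

test_that("t = 0 transition is the identity and selection increases persistence", {
  H0 <- initHaplotypes(0.2, 2)
  expect_equal(transitionFromDistribution(H0, 1, 2), diag(2))
  # an intervening favored site keeps flanking ancestry-0 together
  site <- data.frame(position = 0.105, s = 0.05, h = 0.5)
  Asel <- windowTransition(0.1, 0.11, site, 0.2, 300)
  Aneu <- neutralTransition(0.01, 0.2, 300)
  expect_gt(Asel[1, 1], Aneu[1, 1])
})

test_that("ancestry relabeling symmetry holds", {
  # exchanging m <-> 1-m with the mirrored fitness table
  # (s' = -s/(1-s), h' = 1-h) relabels the transition matrix
  m <- 0.3
  s <- 0.08
  h <- 0.3
  t <- 60
  site <- function(s, h) data.frame(position = 0.105, s = s, h = h)
  A <- windowTransition(0.1, 0.112, site(s, h), m, t)
  B <- windowTransition(0.1, 0.112, site(-s / (1 - s), 1 - h), 1 - m, t)
  expect_equal(A, B[2:1, 2:1], tolerance = 1e-9)
})

test_that("degenerate left-marker marginals yield identity rows with a warning", {
  H <- c(0, 0, 0.4, 0.6)  # left marker always ancestry 1
  expect_warning(A <- transitionFromDistribution(H, 1, 2), "degenerate")
  expect_equal(A[1, ], c(1, 0))
})

test_that("chromosome-level transitions reduce to the neutral closed form without sites", {
  model <- SelectionModel(0.25, 40, 0.5)
  pos <- sort(runif(41, 0, 0.5))
  ts <- transitionsAlongChromosome(model, pos, radius = 0.02, k = 4)
  iv <- transitionIntervals(ts)
  for (i in seq_len(nrow(iv))) {
    expect_equal(ts@haploid[, , i],
                 neutralTransition(iv$distance[i], 0.25, 40),
                 tolerance = 1e-12)
  }
  expect_true(all(iv$nSites == 0))
})

test_that("k = 1 with a covering radius matches per-interval window transitions", {
  model <- SelectionModel(0.2, 50, 0.2,
                          sites = data.frame(position = 0.101, s = 0.05,
                                             h = 0.5))
  pos <- seq(0.09, 0.11, by = 0.004)
  ts <- transitionsAlongChromosome(model, pos, radius = 1, k = 1)
  for (i in seq_len(length(pos) - 1)) {
    expect_equal(ts@haploid[, , i],
                 windowTransition(pos[i], pos[i + 1],
                                  selectedSites(model), 0.2, 50),
                 tolerance = 1e-12)
  }
  expect_equal(ts@usedIdx, seq_along(pos))
})

test_that("the fast window kernel matches the reference transform/evolve route", {
  s <- c(0, 0.02, -0.05, 0)
  h <- c(0.5, 0.3, 0.9, 0.5)
  r <- c(0.004, 0.01, 0.002)
  Hfast <- as.vector(admixsel:::cpp_evolve_window(s, h, r, 0.25, 300L))
  Hslow <- evolveHaplotypes(initHaplotypes(0.25, 4),
                            buildTransform(s, h, r), 300)
  expect_equal(Hfast, Hslow, tolerance = 1e-12)
})

test_that("k only thins window evolutions: every interval keeps a transition", {
  model <- SelectionModel(0.2, 50, 0.2,
                          sites = data.frame(position = 0.1001, s = 0.05,
                                             h = 0.5))
  pos <- seq(0.08, 0.12, by = 5e-4)
  ts4 <- transitionsAlongChromosome(model, pos, radius = 0.01, k = 4)
  ts1 <- transitionsAlongChromosome(model, pos, radius = 0.01, k = 1)
  expect_equal(ts4@usedIdx, seq_along(pos))
  expect_equal(dim(ts4@haploid)[3], length(pos) - 1)
  # neutral intervals are exact regardless of k
  iv <- transitionIntervals(ts4)
  neutral <- which(iv$nSites == 0)
  expect_equal(ts4@haploid[, , neutral], ts1@haploid[, , neutral])
  # reused windowed intervals approximate the exactly computed ones
  win <- which(iv$nSites > 0)
  expect_gt(length(win), 1)
  expect_lt(max(abs(ts4@haploid[, , win] - ts1@haploid[, , win])), 0.01)
})

test_that("windows are never reused across sparse marker gaps", {
  model <- SelectionModel(0.2, 50, 0.2,
                          sites = data.frame(position = 0.101, s = 0.05,
                                             h = 0.5))
  pos <- seq(0, 0.2, by = 0.01)  # 1 cM apart: reuse distance cap kicks in
  ts4 <- transitionsAlongChromosome(model, pos, radius = 0.02, k = 4)
  ts1 <- transitionsAlongChromosome(model, pos, radius = 0.02, k = 1)
  expect_equal(ts4@haploid, ts1@haploid, tolerance = 1e-12)
})

test_that("expected local ancestry is m under neutrality and peaks at a selected site", {
  neutral <- SelectionModel(0.3, 100, 0.5)
  expect_equal(expectedLocalAncestry(neutral, c(0.1, 0.25, 0.4)),
               rep(0.3, 3))
  model <- SelectionModel(0.2, 150, 0.5,
                          sites = data.frame(position = 0.25, s = 0.05,
                                             h = 0.5))
  atSite <- expectedLocalAncestry(model, 0.25)
  expect_equal(atSite, oneLocusTrajectory(0.2, 0.05, 0.5, 150)[151],
               tolerance = 1e-6)
  nearby <- expectedLocalAncestry(model, 0.25 + c(-0.005, 0, 0.005))
  expect_gt(nearby[2], nearby[1])
  expect_gt(nearby[2], nearby[3])
})
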