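## Expected haplotype dynamics over a tracked window (selected sites plus two
## flanking ancestry-informative markers) and the ancestry transition
## probabilities extracted from them. The heavy loops live in C++
## (src/dynamics.cpp); these wrappers validate inputs and organize windows.

.bitAt <- function(idx, p, P) bitwAnd(bitwShiftR(idx, P - p), 1L)

#' Initial haplotype distribution at the admixture pulse
#'
#' At generation 0 only the two unadmixed haplotypes exist: the all-ancestry-0
#' haplotype (index 0) with frequency m, and the all-ancestry-1 haplotype
#' (last index) with frequency 1 - m.
#'
#' @param m admixture fraction in (0, 1).
#' @param nPositions number of tracked positions (>= 2).
#' @return Numeric vector of length 2^nPositions summing to 1.
#' @export
initHaplotypes <- function(m, nPositions) {
  if (!(m > 0 && m < 1)) stop("m must lie in (0, 1)")
  if (nPositions < 2) stop("need at least two tracked positions")
  H <- numeric(2^nPositions)
  H[1] <- m
  H[length(H)] <- 1 - m
  H
}

#' Diploid genotype distribution under random mating
#'
#' Tensor product of the haplotype distribution with itself:
#' D[i * 2^P + j] = H[i] * H[j] (0-based), modeling an infinite population
#' with random mating and no segregation distortion.
#'
#' @param H haplotype probability vector of length 2^P.
#' @return Numeric vector of length 4^P.
#' @export
diploidDistribution <- function(H) {
  as.vector(t(outer(H, H)))
}

#' Diploid-to-haploid transform matrix
#'
#' Builds the matrix M mapping the diploid genotype distribution of one
#' generation to the (unnormalized) gamete haplotype distribution of the
#' next. For diploid genotype i = (a, b) with multiplicative fitness S_i, a
#' crossover in interval j (rate r_j) contributes S_i * r_j to the two
#' recombinant haplotypes, and the no-crossover gametes contribute
#' S_i * (1 - sum(r)) to each parental haplotype, so every row sums to
#' 2 * S_i. At most one crossover per window per meiosis is modeled, which
#' requires sum(r) < 1.
#'
#' @param s,h per-position selection and dominance coefficients (markers use
#'   s = 0); length P.
#' @param r adjacent genetic distances in Morgans; length P - 1, sum < 1.
#' @return Matrix of dimension 4^P x 2^P.
#' @export
buildTransform <- function(s, h, r) {
  cpp_build_transform(as.numeric(s), as.numeric(h), as.numeric(r))
}

#' Evolve a haplotype distribution for t generations
#'
#' Applies random mating (tensor product), the diploid-to-haploid transform
#' M, and renormalization, t times. M stays constant across generations.
#'
#' @param H0 initial haplotype distribution (length 2^P).
#' @param M transform from \code{\link{buildTransform}}.
#' @param t number of generations (>= 0).
#' @return Haplotype distribution after t generations.
#' @export
evolveHaplotypes <- function(H0, M, t) {
  if (t == 0) return(H0)
  as.vector(cpp_evolve(as.numeric(H0), M, as.integer(t)))
}

#' Ancestry transition matrix between two tracked markers
#'
#' Collapses a haplotype distribution to the joint 2x2 ancestry distribution
#' of two focal positions and row-normalizes by the left-marker marginals.
#' A zero left marginal is degenerate: the corresponding row is replaced by
#' the identity row with a warning.
#'
#' @param H haplotype distribution of length 2^P.
#' @param leftIndex,rightIndex 1-based indices of the two focal positions
#'   among the P tracked positions (1 = leftmost).
#' @return 2x2 row-stochastic matrix A with A[a1, a2] =
#'   P(right ancestry a2 - 1 | left ancestry a1 - 1).
#' @export
transitionFromDistribution <- function(H, leftIndex, rightIndex) {
  P <- as.integer(round(log2(length(H))))
  stopifnot(2^P == length(H), leftIndex >= 1, rightIndex <= P)
  idx <- seq_along(H) - 1L
  bl <- .bitAt(idx, leftIndex, P)
  br <- .bitAt(idx, rightIndex, P)
  J <- matrix(0, 2, 2)
  for (a in 0:1) for (b in 0:1)
    J[a + 1, b + 1] <- sum(H[bl == a & br == b])
  for (a in 1:2) {
    rs <- sum(J[a, ])
    if (rs > 0) J[a, ] <- J[a, ] / rs
    else {
      warning("degenerate left-marker marginal; substituting identity row")
      J[a, ] <- as.numeric(seq_len(2) == a)
    }
  }
  J
}

#' Closed-form neutral ancestry transition
#'
#' Under neutrality and the single-crossover model, the probability that no
#' junction forms between two positions at map distance d over t generations
#' is c = (1 - d)^t, and conditional on a junction the right-hand ancestry is
#' drawn from the marginal (m, 1 - m). Used for intervals outside the radius
#' of every selected site.
#'
#' @param d map distance in Morgans (0 <= d < 1).
#' @param m admixture fraction.
#' @param t generations since the pulse.
#' @return 2x2 row-stochastic matrix (row/column 1 = ancestry 0).
#' @export
neutralTransition <- function(d, m, t) {
  stopifnot(d >= 0, d < 1)
  cc <- (1 - d)^t
  matrix(c(cc + (1 - cc) * m, (1 - cc) * (1 - m),
           (1 - cc) * m, cc + (1 - cc) * (1 - m)),
         2, 2, byrow = TRUE)
}

# Strictly order window positions, nudging selected sites that collide with
# a marker (or each other) by +1e-9 M.
.resolvePositions <- function(pos) {
  ord <- order(pos)
  p <- pos[ord]
  for (i in seq_along(p)[-1])
    if (p[i] <= p[i - 1]) p[i] <- p[i - 1] + 1e-9
  list(pos = p, order = ord)
}

#' Ancestry transition between two markers with intervening selection
#'
#' Evolves the full haplotype distribution over the two focal markers plus
#' the given selected sites and extracts the marker-to-marker transition.
#'
#' @param left,right genetic positions (Morgans) of the two focal markers.
#' @param sites data.frame(position, s, h) of selected sites to fold in (may
#'   lie outside [left, right]).
#' @param m,t demography.
#' @return 2x2 row-stochastic matrix.
#' @export
windowTransition <- function(left, right, sites, m, t) {
  w <- .makeWindow(left, right, sites)
  H <- cpp_evolve_window(w$s, w$h, w$r, m, as.integer(t))
  transitionFromDistribution(H, w$left + 1L, w$right + 1L)
}

# Window descriptor: positions sorted, markers tagged neutral, 0-based bit
# indices of the two focal markers.
.makeWindow <- function(left, right, sites) {
  pos <- c(left, right, sites$position)
  s <- c(0, 0, sites$s)
  h <- c(0.5, 0.5, sites$h)
  key <- c(1L, 2L, rep(0L, nrow(sites)))
  res <- .resolvePositions(pos)
  o <- res$order
  list(pos = res$pos, s = s[o], h = h[o],
       r = diff(res$pos),
       left = which(key[o] == 1L) - 1L,
       right = which(key[o] == 2L) - 1L)
}

#' Transition matrices along a chromosome
#'
#' Computes the ancestry transition matrix for every pair of adjacent
#' markers under a multi-locus selection model, with the two standard
#' speed-ups: a selected site is folded into an interval's computation only
#' when it lies within \code{radius} of the interval (default 2 cM), and
#' within each contiguous run of selection-influenced intervals only every
#' k-th interval's window is evolved numerically (default 4), neighboring
#' intervals reusing the nearest computed matrix. Because adjacent
#' intervals are a fraction of a centimorgan apart, the reused matrices are
#' locally smooth in the site geometry; every marker keeps its own
#' transition and (downstream) its emissions. Intervals beyond the reach of
#' every site use the exact neutral closed form regardless of \code{k}.
#' Use \code{k = 1} for final reported fits and decoding.
#'
#' @param model a \code{SelectionModel}.
#' @param markerPos genetic positions of the markers (Morgans, nondecreasing).
#' @param radius influence radius of a selected site in Morgans (default
#'   0.02 = 2 cM).
#' @param k within runs of selection-influenced intervals, evolve every
#'   k-th window and reuse it for the neighbors (default 4).
#' @param maxReuseDist never reuse a window across more than this map
#'   distance (Morgans; default 0.002 = 0.2 cM), so sparse marker sets
#'   fall back towards exact per-interval computation automatically.
#' @return A \code{TransitionSet} with one matrix per adjacent marker pair.
#' @export
transitionsAlongChromosome <- function(model, markerPos, radius = 0.02,
                                       k = 4, maxReuseDist = 0.002) {
  stopifnot(k >= 1, radius >= 0)
  k <- as.integer(k)
  nM <- length(markerPos)
  if (nM < 2) stop("need at least two markers")
  x <- markerPos
  nInt <- nM - 1L
  sites <- selectedSites(model)
  m <- model@m
  t <- model@t
  A <- array(NA_real_, c(2, 2, nInt))
  inRange <- lapply(seq_len(nInt), function(i)
    which(sites$position >= x[i] - radius &
          sites$position <= x[i + 1] + radius))
  nSitesUsed <- lengths(inRange)
  windowed <- which(nSitesUsed > 0)
  neutral <- setdiff(seq_len(nInt), windowed)
  if (length(neutral)) {  # vectorized closed form
    cc <- (1 - diff(x)[neutral])^t
    A[1, 1, neutral] <- cc + (1 - cc) * m
    A[1, 2, neutral] <- (1 - cc) * (1 - m)
    A[2, 1, neutral] <- (1 - cc) * m
    A[2, 2, neutral] <- cc + (1 - cc) * (1 - m)
  }
  if (length(windowed)) {
    # representatives: every k-th interval within each contiguous run of
    # windowed intervals (ties to the nearest computed window)
    runs <- split(windowed, cumsum(c(1L, diff(windowed) != 1L)))
    mid <- (x[-1] + x[-nM]) / 2
    reps <- integer(0)
    assign <- integer(nInt)
    for (run in runs) {
      # a new representative every k intervals, or sooner when the map
      # distance from the current one exceeds maxReuseDist
      rIdx <- run[1]
      for (j in seq_along(run)[-1]) {
        i <- run[j]
        if ((j - 1L) %% k == 0L ||
            mid[i] - mid[rIdx[length(rIdx)]] > maxReuseDist)
          rIdx <- c(rIdx, i)
      }
      reps <- c(reps, rIdx)
      nearest <- vapply(run, function(i) rIdx[which.min(abs(mid[rIdx] - mid[i]))],
                        integer(1))
      assign[run] <- nearest
    }
    windows <- lapply(reps, function(i) {
      w <- .makeWindow(x[i], x[i + 1], sites[inRange[[i]], , drop = FALSE])
      list(s = w$s, h = w$h, r = w$r, left = w$left, right = w$right)
    })
    res <- cpp_window_transitions(windows, m, as.integer(t))
    names(res) <- as.character(reps)
    for (i in windowed) A[, , i] <- res[[as.character(assign[i])]]
  }
  Td <- .diploidTransitionArray(A)
  new("TransitionSet", haploid = A, diploid = Td,
      intervals = data.frame(from = x[-nM], to = x[-1],
                             distance = diff(x), nSites = nSitesUsed),
      usedIdx = seq_len(nM), m = m, t = t)
}

#' Expected local ancestry along a position grid
#'
#' Expected ancestry-0 haplotype frequency at each grid position under the
#' model, computed from the haplotype dynamics with the selected sites
#' within \code{radius} of the position folded in. Positions beyond the
#' reach of every site sit at the neutral expectation m.
#'
#' @param model a \code{SelectionModel}.
#' @param grid genetic positions (Morgans).
#' @param radius site influence radius in Morgans; \code{Inf} folds in every
#'   site (exponential cost in the number of sites).
#' @return Numeric vector of expected ancestry-0 frequencies.
#' @export
expectedLocalAncestry <- function(model, grid, radius = 0.02) {
  sites <- selectedSites(model)
  m <- model@m
  t <- model@t
  vapply(grid, function(x) {
    inr <- which(abs(sites$position - x) <= radius)
    if (length(inr) == 0) return(m)
    st <- sites[inr, , drop = FALSE]
    pos <- c(x, st$position)
    s <- c(0, st$s)
    h <- c(0.5, st$h)
    res <- .resolvePositions(pos)
    o <- res$order
    H <- cpp_evolve_window(s[o], h[o], diff(res$pos), m, as.integer(t))
    P <- length(res$pos)
    bit <- which(o == 1L)  # tracked slot of the query position
    idx <- seq_along(H) - 1L
    sum(H[.bitAt(idx, bit, P) == 0])
  }, numeric(1))
}
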