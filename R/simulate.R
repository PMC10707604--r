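## Synthetic-data machinery: Balding-Nichols parental panels, tract-based
## forward Wright-Fisher simulation of a single admixture pulse with
## multi-locus selection (C++), and low-coverage read sampling. Defaults
## follow the standard validation conditions: N = 10000 diploids, 75 sampled
## individuals, ~2x read depth, panel divergence F = 0.2.

#' Generate parental reference panels for synthetic markers
#'
#' Marker skeleton for simulation: marker positions uniform on the genetic
#' map, ancestral allele frequencies ~ Uniform(0.05, 0.95), per-population
#' frequencies from the Balding-Nichols model with divergence parameter F
#' (Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 means identical frequencies), and
#' panel allele counts binomially sampled at the given panel sizes. True
#' population frequencies are kept in rowData (freq0, freq1) for read
#' sampling and validation.
#'
#' @param nMarkers number of markers (>= 2).
#' @param length chromosome length in Morgans.
#' @param F divergence parameter in [0, 1).
#' @param panelSize alleles sampled per panel (length-2 vector or scalar).
#' @param minFreqDiff marker ascertainment: retained markers must have a
#'   true between-population frequency difference of at least this value
#'   (default 0.2). Ancestry-informative sites are, by definition, sites
#'   whose allele frequencies differ between the source populations, and
#'   real input tables are pre-filtered accordingly; set to 0 to keep all
#'   drawn markers. Ignored when \code{F = 0}.
#' @param chrom chromosome name.
#' @param bpPerMorgan basepairs per Morgan for the synthetic physical map
#'   (default 5e7, i.e. a flat 2 cM/Mb).
#' @return A \code{MarkerDataset} with 0 samples (pileup mode).
#' @export
generatePanels <- function(nMarkers, length = 0.5, F = 0.2,
                           panelSize = c(50, 50), minFreqDiff = 0.2,
                           chrom = "chr1", bpPerMorgan = 5e7) {
  stopifnot(nMarkers >= 2, F >= 0, F < 1)
  panelSize <- rep(panelSize, length.out = 2)
  pos <- sort(runif(nMarkers, 0, length))
  pos <- pos + seq(0, 1e-9, length.out = nMarkers)  # enforce strict order
  if (F == 0) {
    p <- runif(nMarkers, 0.05, 0.95)
    f0 <- f1 <- p
  } else {
    # rejection-sample ascertained (informative) marker frequencies
    f0 <- f1 <- numeric(0)
    while (base::length(f0) < nMarkers) {
      nDraw <- max(nMarkers, 64L)
      p <- runif(nDraw, 0.05, 0.95)
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      g0 <- rbeta(nDraw, a, b)
      g1 <- rbeta(nDraw, a, b)
      keep <- abs(g0 - g1) >= minFreqDiff
      f0 <- c(f0, g0[keep])
      f1 <- c(f1, g1[keep])
    }
    f0 <- f0[seq_len(nMarkers)]
    f1 <- f1[seq_len(nMarkers)]
  }
  c0 <- rbinom(nMarkers, panelSize[1], f0)
  c1 <- rbinom(nMarkers, panelSize[2], f1)
  MarkerDataset(chrom = chrom, bp = pmax(1, round(pos * bpPerMorgan)),
                geneticPos = pos,
                p0A = c0, p0a = panelSize[1] - c0,
                p1A = c1, p1a = panelSize[2] - c1,
                extraRowData = data.frame(freq0 = f0, freq1 = f1))
}

#' Forward Wright-Fisher simulation of an admixture pulse
#'
#' Simulates N diploids for t generations after a single admixture pulse:
#' generation 0 has round(mN) pure ancestry-0 founders; each generation,
#' parents are sampled with probability proportional to their multiplicative
#' fitness across the model's selected sites, and meiosis places
#' Poisson(L) crossovers uniformly (no interference). Optionally a
#' Binomial(N, migrationRate) subset is replaced each generation by
#' unadmixed migrants (split between the two sources by
#' \code{migrantFraction0}).
#'
#' @param model a \code{SelectionModel} (its \code{N} is overridden by the
#'   \code{N} argument if given).
#' @param N number of diploids (default: the model's N; must be finite).
#' @param migrationRate per-generation replacement rate (default 0).
#' @param migrantFraction0 fraction of migrants from ancestry 0 (default 0.5).
#' @param recordSiteFrequencies track per-generation ancestry-0 frequency at
#'   each selected site.
#' @return An \code{AdmixedPopulation}.
#' @export
simulatePopulation <- function(model, N = model@N, migrationRate = 0,
                               migrantFraction0 = 0.5,
                               recordSiteFrequencies = FALSE) {
  if (!is.finite(N)) stop("simulation needs a finite N")
  sites <- selectedSites(model)
  res <- cpp_simulate_population(as.integer(N), model@m, model@t,
                                 model@length, sites$position, sites$s,
                                 sites$h, migrationRate, migrantFraction0,
                                 recordSiteFrequencies)
  new("AdmixedPopulation", starts = res$starts, anc = res$anc,
      N = as.integer(N), length = model@length, generation = model@t,
      siteFrequencies = res$freq)
}

#' Ancestry dosage of individuals at given positions
#'
#' @param pop an \code{AdmixedPopulation}.
#' @param positions genetic positions in Morgans.
#' @param individuals indices of diploid individuals (default all).
#' @return Matrix (positions x individuals) of ancestry-0 dosages in 0:2.
#' @export
ancestryDosage <- function(pop, positions, individuals = seq_len(pop@N)) {
  chromAnc <- function(ci) {
    st <- pop@starts[[ci]]
    pop@anc[[ci]][findInterval(positions, st)]
  }
  vapply(individuals, function(i) {
    (chromAnc(2L * i - 1L) == 0L) + (chromAnc(2L * i) == 0L)
  }, integer(length(positions)))
}

#' Sample sequencing reads (or genotypes) from a simulated population
#'
#' Draws diploid individuals without replacement, assigns each chromosome an
#' allele from its ancestry's true population frequency at every marker
#' (independently across markers given ancestry), and samples reads with
#' Poisson(depth) coverage and symmetric per-read error eps. The true
#' ancestry dosage is attached as a \code{trueDosage} assay for validation.
#'
#' @param pop an \code{AdmixedPopulation}.
#' @param panels a \code{MarkerDataset} skeleton from
#'   \code{\link{generatePanels}} (needs freq0/freq1 rowData).
#' @param nSamples diploid individuals to sample (default 75).
#' @param depth mean read depth per marker (default 2); 0 gives all-missing
#'   observations.
#' @param eps per-read error rate.
#' @param genotype return called genotypes (assay \code{dosage}) instead of
#'   reads.
#' @param gamma genotyping error used in genotype mode.
#' @return A \code{MarkerDataset} with \code{nSamples} columns.
#' @export
sampleReads <- function(pop, panels, nSamples = 75, depth = 2, eps = 0.01,
                        genotype = FALSE, gamma = 0) {
  stopifnot(nSamples <= pop@N)
  rd <- SummarizedExperiment::rowData(panels)
  if (is.null(rd$freq0))
    stop("panels must carry true population frequencies (freq0/freq1)")
  gp <- rd$geneticPos
  nM <- length(gp)
  ids <- sample.int(pop@N, nSamples)
  anc1 <- vapply(ids, function(i) {
    st <- pop@starts[[2L * i - 1L]]
    pop@anc[[2L * i - 1L]][findInterval(gp, st)]
  }, integer(nM))
  anc2 <- vapply(ids, function(i) {
    st <- pop@starts[[2L * i]]
    pop@anc[[2L * i]][findInterval(gp, st)]
  }, integer(nM))
  trueDosage <- (anc1 == 0L) + (anc2 == 0L)
  fmat <- cbind(rd$freq0, rd$freq1)
  allele1 <- matrix(rbinom(nM * nSamples, 1, fmat[cbind(rep(seq_len(nM), nSamples),
                                                        as.vector(anc1) + 1L)]),
                    nM, nSamples)
  allele2 <- matrix(rbinom(nM * nSamples, 1, fmat[cbind(rep(seq_len(nM), nSamples),
                                                        as.vector(anc2) + 1L)]),
                    nM, nSamples)
  g <- allele1 + allele2
  ds <- if (genotype) {
    dg <- g
    if (gamma > 0) {
      flip <- matrix(runif(nM * nSamples) < gamma, nM, nSamples)
      dg[flip] <- (dg[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3
    }
    MarkerDataset(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(panels))),
                  GenomicRanges::start(SummarizedExperiment::rowRanges(panels)),
                  gp, rd$p0A, rd$p0a, rd$p1A, rd$p1a,
                  dosage = dg, trueDosage = trueDosage,
                  extraRowData = data.frame(freq0 = rd$freq0, freq1 = rd$freq1))
  } else {
    tot <- matrix(rpois(nM * nSamples, depth), nM, nSamples)
    q <- eps + (g / 2) * (1 - 2 * eps)
    rA <- matrix(rbinom(nM * nSamples, as.vector(tot), as.vector(q)),
                 nM, nSamples)
    MarkerDataset(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(panels))),
                  GenomicRanges::start(SummarizedExperiment::rowRanges(panels)),
                  gp, rd$p0A, rd$p0a, rd$p1A, rd$p1a,
                  readsA = rA, readsTot = tot, trueDosage = trueDosage,
                  extraRowData = data.frame(freq0 = rd$freq0, freq1 = rd$freq1))
  }
  ds
}

#' One-call synthetic dataset under a selection model
#'
#' Convenience wrapper: generate panels, simulate the admixed population
#' forward in time, and sample reads.
#'
#' @inheritParams generatePanels
#' @inheritParams sampleReads
#' @param model a \code{SelectionModel}.
#' @param N diploid population size.
#' @param migrationRate forwarded to \code{\link{simulatePopulation}}.
#' @return List with elements \code{data} (a \code{MarkerDataset}),
#'   \code{population} and \code{panels}.
#' @export
simulateDataset <- function(model, N = 10000, nMarkers = 300,
                            F = 0.2, panelSize = c(50, 50), nSamples = 75,
                            depth = 2, eps = 0.01, genotype = FALSE,
                            migrationRate = 0) {
  panels <- generatePanels(nMarkers, length = model@length, F = F,
                           panelSize = panelSize)
  pop <- simulatePopulation(model, N = N, migrationRate = migrationRate)
  data <- sampleReads(pop, panels, nSamples = nSamples, depth = depth,
                      eps = eps, genotype = genotype)
  list(data = data, population = pop, panels = panels)
}

#' Simulate a dataset matching an existing dataset's markers
#'
#' Used by null calibration: simulate a population under \code{model} and
#' resample reads at the template's markers. True population frequencies are
#' taken from the template's freq0/freq1 rowData when present (synthetic
#' data), otherwise estimated from the panel counts with 0.5 pseudo-counts.
#'
#' @param template a \code{MarkerDataset}.
#' @param model the generating \code{SelectionModel}.
#' @param N diploid population size for the simulation.
#' @param nSamples samples to draw (default: the template's sample count).
#' @param depth mean depth (default: the template's mean coverage).
#' @param eps per-read error.
#' @return A \code{MarkerDataset}.
#' @export
simulateFromTemplate <- function(template, model, N = 10000,
                                 nSamples = ncol(template), depth = NULL,
                                 eps = 0.01) {
  rd <- SummarizedExperiment::rowData(template)
  panels <- template[, integer(0)]
  if (is.null(rd$freq0)) {
    pc <- panelCounts(template)
    rd2 <- rd
    rd2$freq0 <- (pc[, "p0A"] + 0.5) / (pc[, "p0A"] + pc[, "p0a"] + 1)
    rd2$freq1 <- (pc[, "p1A"] + 0.5) / (pc[, "p1A"] + pc[, "p1a"] + 1)
    SummarizedExperiment::rowData(panels) <- rd2
  }
  if (is.null(depth)) {
    depth <- if (datasetMode(template) == "pileup")
      mean(SummarizedExperiment::assay(template, "readsTot"), na.rm = TRUE)
    else 0
  }
  pop <- simulatePopulation(model, N = N)
  sampleReads(pop, panels, nSamples = nSamples,
              depth = depth, eps = eps,
              genotype = datasetMode(template) == "genotype")
}
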