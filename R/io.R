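## Readers and writers for the tab-delimited marker/read dialect, simple
## recombination maps, and model files. File layout (headerless TSV):
## chrom, bp (1-based), panel0_A, panel0_a, panel1_A, panel1_a,
## distance-from-previous-marker (Morgans; first row measures from the
## chromosome start), then per-sample columns: a readsA/reads_a pair per
## sample in pileup mode, or one A-allele dosage per sample in genotype
## mode (NA for missing). Internal coordinates are 0-based Morgans.

#' Read a marker/read table
#'
#' @param path file path.
#' @param mode "pileup" (per-sample read-count pairs) or "genotype"
#'   (per-sample dosages).
#' @return A \code{MarkerDataset}.
#' @export
readMarkerDataset <- function(path, mode = c("pileup", "genotype")) {
  mode <- match.arg(mode)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 7) stop("need at least 7 columns (no samples found?)")
  counts <- as.matrix(tab[, 3:6])
  if (any(counts < 0, na.rm = TRUE)) {
    bad <- which(rowSums(counts < 0, na.rm = TRUE) > 0)[1]
    stop("negative panel count at line ", bad)
  }
  dist <- tab[, 7]
  if (any(dist < 0)) {
    stop("negative inter-marker distance at line ", which(dist < 0)[1])
  }
  gp <- cumsum(dist)
  nS <- ncol(tab) - 7L
  if (mode == "pileup") {
    if (nS %% 2 != 0)
      stop("pileup mode expects per-sample column pairs; got ", nS,
           " sample columns")
    nS <- nS %/% 2L
    sm <- as.matrix(tab[, -(1:7), drop = FALSE])
    if (any(sm < 0, na.rm = TRUE)) {
      bad <- which(rowSums(sm < 0, na.rm = TRUE) > 0)[1]
      stop("negative read count at line ", bad)
    }
    rA <- sm[, 2 * seq_len(nS) - 1, drop = FALSE]
    ra <- sm[, 2 * seq_len(nS), drop = FALSE]
    MarkerDataset(tab[, 1], tab[, 2], gp, tab[, 3], tab[, 4], tab[, 5],
                  tab[, 6], readsA = rA, readsTot = rA + ra)
  } else {
    dg <- as.matrix(tab[, -(1:7), drop = FALSE])
    if (any(!(dg %in% c(0, 1, 2, NA))))
      stop("genotype dosages must be 0, 1, 2 or NA; offending line ",
           which(rowSums(!(dg %in% c(0, 1, 2, NA))) > 0)[1])
    MarkerDataset(tab[, 1], tab[, 2], gp, tab[, 3], tab[, 4], tab[, 5],
                  tab[, 6], dosage = dg)
  }
}

#' Write a marker/read table
#'
#' Inverse of \code{\link{readMarkerDataset}}; the \code{trueDosage} assay
#' and any truth rowData of synthetic datasets are not written.
#'
#' @param data a \code{MarkerDataset}.
#' @param path output file path.
#' @export
writeMarkerDataset <- function(data, path) {
  rr <- SummarizedExperiment::rowRanges(data)
  gp <- geneticPositions(data)
  pc <- panelCounts(data)
  base <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                     bp = GenomicRanges::start(rr),
                     p0A = pc[, "p0A"], p0a = pc[, "p0a"],
                     p1A = pc[, "p1A"], p1a = pc[, "p1a"],
                     dist = c(gp[1], diff(gp)))
  if (datasetMode(data) == "pileup") {
    rA <- SummarizedExperiment::assay(data, "readsA")
    rT <- SummarizedExperiment::assay(data, "readsTot")
    nS <- ncol(rA)
    sm <- matrix(0, nrow(data), 2 * nS)
    sm[, 2 * seq_len(nS) - 1] <- rA
    sm[, 2 * seq_len(nS)] <- rT - rA
    out <- cbind(base, sm)
  } else {
    out <- cbind(base, SummarizedExperiment::assay(data, "dosage"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Recombination maps
#'
#' A recombination map is a data.frame with columns \code{bp} (strictly
#' increasing) and \code{cM} (nondecreasing cumulative map position).
#' \code{readRecombinationMap} reads one from a two-column TSV (with
#' header); \code{flatRecombinationMap} builds a constant-rate map.
#'
#' @param path TSV path with columns bp, cM.
#' @return data.frame of class \code{"recombinationMap"}.
#' @export
readRecombinationMap <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE)
  if (!all(c("bp", "cM") %in% names(tab)))
    stop("recombination map needs columns 'bp' and 'cM'")
  .asRecombinationMap(tab)
}

.asRecombinationMap <- function(tab) {
  if (nrow(tab) < 2) stop("recombination map needs at least two points")
  if (any(diff(tab$bp) <= 0)) stop("map bp positions must be strictly increasing")
  if (any(diff(tab$cM) < 0)) stop("cumulative cM must be nondecreasing")
  class(tab) <- c("recombinationMap", "data.frame")
  tab
}

#' @rdname readRecombinationMap
#' @param ratePerMb recombination rate in cM per Mb (e.g. 2).
#' @param maxBp extent of the map in bp.
#' @export
flatRecombinationMap <- function(ratePerMb, maxBp) {
  .asRecombinationMap(data.frame(bp = c(1, maxBp),
                                 cM = c(0, (maxBp - 1) / 1e6 * ratePerMb)))
}

#' Convert basepair positions to Morgans
#'
#' Linear interpolation of the cumulative map, divided by 100. Queries
#' outside the map span are clamped to its ends with a warning.
#'
#' @param map a recombination map (see \code{\link{readRecombinationMap}}).
#' @param bp basepair positions.
#' @return Genetic positions in Morgans.
#' @export
bpToMorgans <- function(map, bp) {
  if (is.null(map$bp) || nrow(map) == 0) stop("empty recombination map")
  if (any(bp < min(map$bp) | bp > max(map$bp)))
    warning("query outside the map span; clamped to the map ends")
  approx(map$bp, map$cM, xout = bp, rule = 2)$y / 100
}

#' Read/write selection model files
#'
#' YAML with keys \code{m}, \code{t}, \code{chromosome_length_morgans},
#' optional \code{N}, and \code{sites}: a list of
#' \code{{position_morgans, s, h}} entries.
#'
#' @param path file path.
#' @return A \code{SelectionModel}.
#' @export
readSelectionModel <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- NULL
  if (length(y$sites))
    sites <- data.frame(
      position = vapply(y$sites, `[[`, numeric(1), "position_morgans"),
      s = vapply(y$sites, `[[`, numeric(1), "s"),
      h = vapply(y$sites, `[[`, numeric(1), "h"))
  SelectionModel(y$m, y$t, y$chromosome_length_morgans, sites,
                 N = if (is.null(y$N)) Inf else y$N)
}

#' @rdname readSelectionModel
#' @param model a \code{SelectionModel}.
#' @export
writeSelectionModel <- function(model, path) {
  st <- selectedSites(model)
  y <- list(m = model@m, t = model@t,
            chromosome_length_morgans = model@length,
            sites = lapply(seq_len(nrow(st)), function(i)
              list(position_morgans = st$position[i], s = st$s[i],
                   h = st$h[i])))
  if (is.finite(model@N)) y$N <- model@N
  yaml::write_yaml(y, path)
  invisible(path)
}
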