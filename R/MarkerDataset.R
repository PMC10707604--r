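#' Ancestry-informative marker dataset
#'
#' Markers with parental-panel allele counts, genetic positions, and
#' per-sample observations (read counts in pileup mode, or allele dosages in
#' genotype mode), held as a \code{RangedSummarizedExperiment}. Rows are
#' markers (with chromosome/bp coordinates as \code{rowRanges} and the panel
#' counts, genetic positions and any simulation truth in \code{rowData});
#' columns are samples. Pileup mode carries assays \code{readsA} and
#' \code{readsTot}; genotype mode carries assay \code{dosage} (count of the
#' A allele, \code{NA} when missing). Synthetic datasets additionally carry
#' a \code{trueDosage} assay (ancestry-0 dosage) used only for validation.
#'
#' @slot mode "pileup" or "genotype".
#' @name MarkerDataset-class
#' @import SummarizedExperiment
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols
#' @exportClass MarkerDataset
setClass("MarkerDataset",
  contains = "RangedSummarizedExperiment",
  representation(mode = "character"))

setValidity("MarkerDataset", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("pileup", "genotype"))
    return("mode must be 'pileup' or 'genotype'")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("geneticPos", "p0A", "p0a", "p1A", "p1a")
  if (!all(need %in% names(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  gp <- rd$geneticPos
  if (length(gp) > 1 && any(diff(gp) < 0))
    msg <- c(msg, "genetic positions must be nondecreasing")
  pc <- cbind(rd$p0A, rd$p0a, rd$p1A, rd$p1a)
  if (any(pc < 0)) msg <- c(msg, "panel allele counts must be nonnegative")
  an <- SummarizedExperiment::assayNames(object)
  if (object@mode == "pileup") {
    if (!all(c("readsA", "readsTot") %in% an))
      msg <- c(msg, "pileup mode requires assays readsA and readsTot")
  } else if (!"dosage" %in% an) {
    msg <- c(msg, "genotype mode requires assay dosage")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerDataset
#'
#' @param chrom chromosome identifier (recycled).
#' @param bp 1-based basepair positions.
#' @param geneticPos genetic positions in Morgans from the chromosome start,
#'   nondecreasing.
#' @param p0A,p0a counts of the A and a alleles in the ancestry-0 panel.
#' @param p1A,p1a counts in the ancestry-1 panel.
#' @param readsA,readsTot matrices (markers x samples) of A-allele and total
#'   read counts (pileup mode).
#' @param dosage matrix of A-allele dosages in {0, 1, 2, NA} (genotype mode).
#' @param trueDosage optional matrix of true ancestry-0 dosages (synthetic
#'   data only).
#' @param extraRowData optional data.frame of additional per-marker columns
#'   (e.g. true panel frequencies of synthetic data).
#' @return A \code{MarkerDataset}.
#' @export
MarkerDataset <- function(chrom, bp, geneticPos, p0A, p0a, p1A, p1a,
                          readsA = NULL, readsTot = NULL, dosage = NULL,
                          trueDosage = NULL, extraRowData = NULL) {
  nM <- length(bp)
  mode <- if (!is.null(dosage)) "genotype" else "pileup"
  assays <- list()
  if (mode == "pileup") {
    if (is.null(readsA)) readsA <- matrix(NA_real_, nM, 0)
    if (is.null(readsTot)) readsTot <- matrix(NA_real_, nM, 0)
    storage.mode(readsA) <- "double"
    storage.mode(readsTot) <- "double"
    assays <- list(readsA = readsA, readsTot = readsTot)
  } else {
    storage.mode(dosage) <- "double"
    assays <- list(dosage = dosage)
  }
  if (!is.null(trueDosage)) assays$trueDosage <- trueDosage
  assays <- lapply(assays, function(a) { dimnames(a) <- NULL; a })
  rr <- GenomicRanges::GRanges(rep(as.character(chrom), length.out = nM),
                               IRanges::IRanges(start = bp, width = 1))
  rd <- S4Vectors::DataFrame(geneticPos = as.numeric(geneticPos),
                             p0A = as.numeric(p0A), p0a = as.numeric(p0a),
                             p1A = as.numeric(p1A), p1a = as.numeric(p1a))
  if (!is.null(extraRowData)) rd <- cbind(rd, S4Vectors::DataFrame(extraRowData))
  S4Vectors::mcols(rr) <- rd
  nS <- ncol(assays[[1]])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = sprintf("sample%d", seq_len(nS))))
  new("MarkerDataset", se, mode = mode)
}

#' @rdname MarkerDataset
#' @param x a \code{MarkerDataset}.
#' @export
geneticPositions <- function(x) {
  SummarizedExperiment::rowData(x)$geneticPos
}

#' @rdname MarkerDataset
#' @export
panelCounts <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cbind(p0A = rd$p0A, p0a = rd$p0a, p1A = rd$p1A, p1a = rd$p1a)
}

#' @rdname MarkerDataset
#' @export
datasetMode <- function(x) x@mode

setMethod("show", "MarkerDataset", function(object) {
  cat("MarkerDataset (", object@mode, " mode): ", nrow(object), " markers, ",
      ncol(object), " samples\n", sep = "")
  gp <- geneticPositions(object)
  if (length(gp))
    cat("  genetic span: ", sprintf("%.4f", max(gp) - min(gp)), " Morgans\n",
        sep = "")
})
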