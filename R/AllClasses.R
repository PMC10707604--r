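#' @import methods
#' @importFrom stats dbinom plogis qlogis rbeta rbinom rpois runif median approx setNames quantile
#' @importFrom utils read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib admixsel, .registration = TRUE
NULL

#' Multi-locus selection model for a single admixture pulse
#'
#' A \code{SelectionModel} bundles the demography of a single-pulse admixture
#' event (admixture fraction \code{m}, time since admixture \code{t}
#' generations, optional population size \code{N}) with an ordered set of
#' selected sites along one chromosome. Each selected site has a genetic
#' position (Morgans from the chromosome start), a selection coefficient
#' \code{s} and a dominance coefficient \code{h}, giving diploid genotype
#' fitnesses 1, 1 - h*s and 1 - s for 2, 1 and 0 copies of ancestry 0
#' (\code{h} is thus the dominance of the disfavored ancestry: 0.5 is
#' additive, 0 makes the favored allele's benefit fully dominant, 1 makes
#' it recessive).
#' Positive \code{s} favors ancestry 0 (the pulse ancestry with founder
#' frequency \code{m}); negative \code{s} (favoring ancestry 1) is permitted
#' subject to all fitnesses remaining positive, and is flagged when fitted.
#'
#' @slot m numeric in (0, 1); admixture fraction of ancestry 0 at the pulse.
#' @slot t positive integer; generations from the pulse to sampling.
#' @slot N numeric; population size (used by the simulator and by null
#'   calibration only; the transition model itself assumes an infinite
#'   population). May be \code{Inf}.
#' @slot sites data.frame with columns \code{position} (Morgans), \code{s},
#'   \code{h}, strictly increasing in position.
#' @slot length numeric; chromosome length in Morgans.
#' @name SelectionModel-class
#' @exportClass SelectionModel
setClass("SelectionModel",
  representation(m = "numeric", t = "integer", N = "numeric",
                 sites = "data.frame", length = "numeric"))

setValidity("SelectionModel", function(object) {
  msg <- character(0)
  if (length(object@m) != 1 || !is.finite(object@m) ||
      object@m <= 0 || object@m >= 1)
    msg <- c(msg, "m must be a single number in (0, 1)")
  if (length(object@t) != 1 || is.na(object@t) || object@t < 1L)
    msg <- c(msg, "t must be a positive integer")
  if (length(object@N) != 1 || is.na(object@N) || object@N <= 0)
    msg <- c(msg, "N must be positive (possibly Inf)")
  if (length(object@length) != 1 || !is.finite(object@length) ||
      object@length <= 0)
    msg <- c(msg, "chromosome length must be a positive number of Morgans")
  st <- object@sites
  if (!all(c("position", "s", "h") %in% names(st))) {
    msg <- c(msg, "sites must have columns position, s, h")
  } else if (nrow(st) > 0) {
    if (any(diff(st$position) <= 0))
      msg <- c(msg, "site positions must be strictly increasing (no duplicates)")
    if (any(st$position < 0 | st$position > object@length))
      msg <- c(msg, "site positions must lie within [0, chromosome length]")
    if (any(st$h < 0 | st$h > 1))
      msg <- c(msg, "dominance h must lie in [0, 1]")
    if (any(1 - st$s <= 0) || any(1 - st$h * st$s <= 0))
      msg <- c(msg, "all genotype fitnesses must be positive (need 1 - s > 0 and 1 - h*s > 0)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SelectionModel
#'
#' @param m admixture fraction of ancestry 0 at the pulse, in (0, 1).
#' @param t generations since the pulse (positive integer; rounded).
#' @param chromosomeLength chromosome length in Morgans.
#' @param sites data.frame with columns \code{position} (Morgans), \code{s},
#'   \code{h}; \code{NULL} for a neutral model. Rows are sorted by position.
#' @param N population size for simulation/calibration; \code{Inf} by default.
#' @return A \code{SelectionModel} object.
#' @examples
#' SelectionModel(m = 0.2, t = 500, chromosomeLength = 0.5,
#'                sites = data.frame(position = 0.25, s = 0.01, h = 0.5))
#' @export
SelectionModel <- function(m, t, chromosomeLength, sites = NULL, N = Inf) {
  if (is.null(sites) || nrow(sites) == 0) {
    sites <- data.frame(position = numeric(0), s = numeric(0), h = numeric(0))
  } else {
    sites <- as.data.frame(sites)[, c("position", "s", "h")]
    sites <- sites[order(sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  }
  new("SelectionModel", m = as.numeric(m), t = as.integer(round(t)),
      N = as.numeric(N), sites = sites,
      length = as.numeric(chromosomeLength))
}

#' Ancestry transition matrices along a chromosome
#'
#' Per-interval haploid 2x2 and diploid 3x3 ancestry transition matrices for
#' a (possibly thinned) marker set, as produced by
#' \code{\link{transitionsAlongChromosome}}. Haploid state 1 is ancestry 0;
#' diploid states are ancestry-0 dosage 0, 1, 2.
#'
#' @slot haploid numeric array 2 x 2 x nInterval.
#' @slot diploid numeric array 3 x 3 x nInterval.
#' @slot intervals data.frame describing each interval (endpoints in Morgans,
#'   distance, number of selected sites folded into the computation).
#' @slot usedIdx integer indices of the retained markers in the original set.
#' @slot m,t the demography the matrices were computed under.
#' @name TransitionSet-class
#' @exportClass TransitionSet
setClass("TransitionSet",
  representation(haploid = "array", diploid = "array",
                 intervals = "data.frame", usedIdx = "integer",
                 m = "numeric", t = "integer"))

setValidity("TransitionSet", function(object) {
  nI <- nrow(object@intervals)
  if (!identical(dim(object@haploid), c(2L, 2L, as.integer(nI))))
    return("haploid array must be 2 x 2 x nrow(intervals)")
  if (!identical(dim(object@diploid), c(3L, 3L, as.integer(nI))))
    return("diploid array must be 3 x 3 x nrow(intervals)")
  if (nI > 0) {
    rs <- apply(object@haploid, 3, rowSums)
    if (any(abs(rs - 1) > 1e-9)) return("haploid rows must sum to 1")
  }
  TRUE
})

#' Simulated admixed population of ancestry tracts
#'
#' Diploid individuals produced by the forward Wright-Fisher simulator. Each
#' of the 2N chromosomes is a list of ancestry tracts partitioning
#' [0, L) Morgans; chromosomes 2i - 1 and 2i belong to individual i.
#'
#' @slot starts list of numeric vectors; tract start positions per chromosome
#'   (first entry always 0).
#' @slot anc list of integer vectors; tract ancestries (0 or 1).
#' @slot N integer; number of diploid individuals.
#' @slot length numeric; chromosome length L in Morgans.
#' @slot generation integer; generations simulated since the pulse.
#' @slot siteFrequencies matrix (t x nSites) of per-generation ancestry-0
#'   frequencies at the selected sites, if recorded.
#' @name AdmixedPopulation-class
#' @exportClass AdmixedPopulation
setClass("AdmixedPopulation",
  representation(starts = "list", anc = "list", N = "integer",
                 length = "numeric", generation = "integer",
                 siteFrequencies = "matrix"))

setValidity("AdmixedPopulation", function(object) {
  if (length(object@starts) != 2L * object@N ||
      length(object@anc) != 2L * object@N)
    return("need exactly 2N chromosomes")
  TRUE
})

#' Result of a likelihood fit
#'
#' @slot model the fitted \code{SelectionModel}.
#' @slot loglik maximized forward log-likelihood.
#' @slot evaluations number of objective evaluations used.
#' @slot converged logical; whether every simplex search hit its stopping
#'   rule (rather than the evaluation cap).
#' @slot trace data.frame with one row per simplex search (stage, start,
#'   evaluations, best objective).
#' @slot flags character; notes such as negatively fitted selection
#'   coefficients or boundary optima.
#' @name FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "SelectionModel", loglik = "numeric",
                 evaluations = "integer", converged = "logical",
                 trace = "data.frame", flags = "character"))
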