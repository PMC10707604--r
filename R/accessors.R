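#' @describeIn SelectionModel-class admixture fraction m.
#' @param object,x a \code{SelectionModel}.
#' @export
setGeneric("admixtureFraction", function(x) standardGeneric("admixtureFraction"))

#' @rdname SelectionModel-class
#' @export
setMethod("admixtureFraction", "SelectionModel", function(x) x@m)

#' @rdname SelectionModel-class
#' @export
setGeneric("admixtureTime", function(x) standardGeneric("admixtureTime"))

#' @rdname SelectionModel-class
#' @export
setMethod("admixtureTime", "SelectionModel", function(x) x@t)

#' @rdname SelectionModel-class
#' @export
setGeneric("selectedSites", function(x) standardGeneric("selectedSites"))

#' @rdname SelectionModel-class
#' @export
setMethod("selectedSites", "SelectionModel", function(x) x@sites)

#' @rdname SelectionModel-class
#' @export
setGeneric("chromosomeLength", function(x) standardGeneric("chromosomeLength"))

#' @rdname SelectionModel-class
#' @export
setMethod("chromosomeLength", "SelectionModel", function(x) x@length)

setMethod("show", "SelectionModel", function(object) {
  cat("SelectionModel: m = ", object@m, ", t = ", object@t,
      ", L = ", object@length, " M, N = ", object@N, "\n", sep = "")
  if (nrow(object@sites) == 0) {
    cat("  neutral (no selected sites)\n")
  } else {
    cat("  ", nrow(object@sites), " selected site(s):\n", sep = "")
    print(object@sites, digits = 4)
    if (any(object@sites$s < 0))
      cat("  note: negative s (selection favoring ancestry 1) present\n")
  }
})

#' @describeIn TransitionSet-class haploid 2x2 transition matrices.
#' @param x a \code{TransitionSet}.
#' @export
haploidTransitions <- function(x) x@haploid

#' @describeIn TransitionSet-class diploid 3x3 transition matrices.
#' @export
diploidTransitions <- function(x) x@diploid

#' @describeIn TransitionSet-class interval table.
#' @export
transitionIntervals <- function(x) x@intervals

setMethod("show", "TransitionSet", function(object) {
  cat("TransitionSet: ", nrow(object@intervals), " intervals (m = ",
      object@m, ", t = ", object@t, ")\n", sep = "")
  cat("  ", sum(object@intervals$nSites > 0),
      " interval(s) influenced by selected sites\n", sep = "")
})

setMethod("show", "AdmixedPopulation", function(object) {
  cat("AdmixedPopulation: N = ", object@N, " diploids, L = ", object@length,
      " M, sampled ", object@generation, " generations after the pulse\n",
      sep = "")
  nt <- mean(lengths(object@anc))
  cat("  mean tracts per chromosome: ", sprintf("%.1f", nt), "\n", sep = "")
})

#' @describeIn FitResult-class fitted model.
#' @param x a \code{FitResult}.
#' @export
fittedModel <- function(x) x@model

#' @describeIn FitResult-class maximized log-likelihood.
#' @export
fitLoglik <- function(x) x@loglik

setMethod("show", "FitResult", function(object) {
  cat("FitResult: loglik = ", sprintf("%.3f", object@loglik), " (",
      object@evaluations, " evaluations, ",
      if (object@converged) "converged" else "evaluation cap reached",
      ")\n", sep = "")
  show(object@model)
  if (length(object@flags))
    cat("  flags: ", paste(object@flags, collapse = "; "), "\n", sep = "")
})
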