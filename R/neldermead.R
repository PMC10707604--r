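## Nelder-Mead simplex minimizer with the two-stage restart-and-stopping
## scheme used for all model fits: reflection 1, contraction 0.5, expansion
## 2, shrinkage 0.5; a search stops when the simplex's objective range falls
## below an absolute threshold AND below a fraction of its initial range, or
## after four consecutive shrink transformations. Stage 1 runs several
## simplex sizes/orientations around the supplied start; stage 2 re-centers
## on the stage-1 optimum with smaller simplexes.

#' Configuration for the two-stage simplex optimizer
#'
#' @param reflection,contraction,expansion,shrinkage standard Nelder-Mead
#'   transformation constants (defaults 1, 0.5, 2, 0.5).
#' @param stage1Sizes,stage2Sizes simplex edge lengths (in transformed
#'   coordinates) for the starts of each stage.
#' @param stage1AbsTol,stage1FracTol stage-1 stop: objective range below
#'   \code{stage1AbsTol} and below \code{stage1FracTol} of the initial range.
#' @param stage2AbsTol,stage2FracTol the same for stage 2 (defaults 0.1 and
#'   1/20).
#' @param maxShrink stop a search after this many consecutive shrink steps
#'   (default 4).
#' @param maxEval evaluation cap per search.
#' @param seed optional integer; when set, start orientations are random
#'   orthogonal rotations drawn reproducibly from it, otherwise axis-aligned
#'   simplexes with deterministic sign flips are used.
#' @return List of class \code{simplexConfig}.
#' @export
simplexConfig <- function(reflection = 1, contraction = 0.5, expansion = 2,
                          shrinkage = 0.5,
                          stage1Sizes = c(0.5, 0.25, 0.1),
                          stage2Sizes = c(0.1, 0.02),
                          stage1AbsTol = 5, stage1FracTol = 0.25,
                          stage2AbsTol = 0.1, stage2FracTol = 0.05,
                          maxShrink = 4, maxEval = 500, seed = NULL) {
  stopifnot(reflection > 0, contraction > 0, expansion > 0, shrinkage > 0,
            stage1AbsTol > 0, stage2AbsTol > 0)
  structure(list(reflection = reflection, contraction = contraction,
                 expansion = expansion, shrinkage = shrinkage,
                 stage1Sizes = stage1Sizes, stage2Sizes = stage2Sizes,
                 stage1AbsTol = stage1AbsTol, stage1FracTol = stage1FracTol,
                 stage2AbsTol = stage2AbsTol, stage2FracTol = stage2FracTol,
                 maxShrink = maxShrink, maxEval = maxEval, seed = seed),
            class = "simplexConfig")
}

.safeEval <- function(fn, x) {
  v <- tryCatch(fn(x), error = function(e) NaN)
  if (!is.finite(v)) 1e10 else v  # NaN vertices are rejected with a penalty
}

# Orientation matrices for the j-th start: identity, then deterministic sign
# flips; with a seed, random rotations via QR of a standard normal matrix.
.orientation <- function(n, j, seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed + j)
    Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    return(Q)
  }
  Q <- diag(n)
  if (j > 1) {
    signs <- 1 - 2 * ((seq_len(n) + j) %% 2)
    Q <- Q * signs
  }
  Q
}

# One simplex search. Returns list(x, value, evals, converged).
.nmSearch <- function(fn, x0, size, orient, cfg, absTol, fracTol) {
  n <- length(x0)
  V <- matrix(rep(x0, n + 1), n + 1, n, byrow = TRUE)
  for (i in seq_len(n)) V[i + 1, ] <- x0 + size * orient[, i]
  f <- apply(V, 1, .safeEval, fn = fn)
  evals <- n + 1L
  if (all(f >= 1e10)) stop("objective is not finite anywhere on the initial simplex")
  initRange <- max(f) - min(f)
  shrinks <- 0L
  converged <- FALSE
  while (evals < cfg$maxEval) {
    ord <- order(f)  # stable: ties broken by insertion order
    V <- V[ord, , drop = FALSE]
    f <- f[ord]
    rng <- f[n + 1] - f[1]
    if ((rng < absTol && rng <= fracTol * max(initRange, .Machine$double.eps)) ||
        shrinks >= cfg$maxShrink) {
      converged <- TRUE
      break
    }
    cen <- colMeans(V[seq_len(n), , drop = FALSE])
    xr <- cen + cfg$reflection * (cen - V[n + 1, ])
    fr <- .safeEval(fn, xr); evals <- evals + 1L
    if (fr < f[1]) {
      xe <- cen + cfg$expansion * (xr - cen)
      fe <- .safeEval(fn, xe); evals <- evals + 1L
      if (fe < fr) { V[n + 1, ] <- xe; f[n + 1] <- fe }
      else { V[n + 1, ] <- xr; f[n + 1] <- fr }
      shrinks <- 0L
    } else if (fr < f[n]) {
      V[n + 1, ] <- xr; f[n + 1] <- fr
      shrinks <- 0L
    } else {
      if (fr < f[n + 1]) {
        xc <- cen + cfg$contraction * (xr - cen)   # outside contraction
      } else {
        xc <- cen - cfg$contraction * (cen - V[n + 1, ])  # inside
      }
      fc <- .safeEval(fn, xc); evals <- evals + 1L
      if (fc < min(fr, f[n + 1])) {
        V[n + 1, ] <- xc; f[n + 1] <- fc
        shrinks <- 0L
      } else {
        for (i in 2:(n + 1)) {
          V[i, ] <- V[1, ] + cfg$shrinkage * (V[i, ] - V[1, ])
          f[i] <- .safeEval(fn, V[i, ])
        }
        evals <- evals + n
        shrinks <- shrinks + 1L
      }
    }
  }
  best <- which.min(f)
  list(x = V[best, ], value = f[best], evals = evals, converged = converged)
}

#' Two-stage Nelder-Mead minimization
#'
#' Minimizes \code{fn} with the staged simplex scheme: stage 1 runs one
#' search per entry of \code{stage1Sizes} centered on \code{start}; stage 2
#' re-centers on the stage-1 optimum with the (smaller) \code{stage2Sizes}.
#' Fully deterministic given the configuration.
#'
#' @param fn objective to minimize (called with a numeric vector).
#' @param start starting point.
#' @param config a \code{\link{simplexConfig}}.
#' @return List with \code{par}, \code{value}, \code{evaluations},
#'   \code{converged} and a per-search \code{trace} data.frame.
#' @examples
#' nelderMead(function(x) sum((x - 3)^2), c(0, 0))$par
#' @export
nelderMead <- function(fn, start, config = simplexConfig()) {
  trace <- data.frame(stage = integer(0), start = integer(0),
                      size = numeric(0), evals = integer(0),
                      value = numeric(0))
  evals <- 0L
  allConv <- TRUE
  best <- list(x = start, value = .safeEval(fn, start))
  evals <- evals + 1L
  for (j in seq_along(config$stage1Sizes)) {
    r <- .nmSearch(fn, start, config$stage1Sizes[j],
                   .orientation(length(start), j, config$seed), config,
                   config$stage1AbsTol, config$stage1FracTol)
    evals <- evals + r$evals
    allConv <- allConv && r$converged
    if (r$value < best$value) best <- r
    trace <- rbind(trace, data.frame(stage = 1L, start = j,
                                     size = config$stage1Sizes[j],
                                     evals = r$evals, value = r$value))
  }
  center <- best$x
  for (j in seq_along(config$stage2Sizes)) {
    r <- .nmSearch(fn, center, config$stage2Sizes[j],
                   .orientation(length(start), j, config$seed), config,
                   config$stage2AbsTol, config$stage2FracTol)
    evals <- evals + r$evals
    allConv <- allConv && r$converged
    if (r$value < best$value) best <- r
    trace <- rbind(trace, data.frame(stage = 2L, start = j,
                                     size = config$stage2Sizes[j],
                                     evals = r$evals, value = r$value))
  }
  list(par = best$x, value = best$value, evaluations = evals,
       converged = allConv, trace = trace)
}
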