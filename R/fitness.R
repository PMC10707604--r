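#' Per-site fitness table
#'
#' Relative diploid fitnesses at one selected site, indexed by the number of
#' ancestry-0 copies: 2 copies -> 1, 1 copy -> 1 - h*s, 0 copies -> 1 - s.
#'
#' @param s selection coefficient (s < 1; negative values favor ancestry 1).
#' @param h dominance coefficient in [0, 1].
#' @return Numeric vector of length 3, names "0", "1", "2" (ancestry-0 dosage).
#' @export
siteFitness <- function(s, h) {
  stopifnot(1 - s > 0, 1 - h * s > 0)
  c("0" = 1 - s, "1" = 1 - h * s, "2" = 1)
}

#' Multiplicative fitness of a diploid ancestry genotype
#'
#' Fitness of a diploid whose two chromosomes carry the given ancestries at
#' every selected site of the model, combining sites multiplicatively.
#' A fully ancestry-0 genotype (or a neutral model) has fitness 1.
#'
#' @param model a \code{SelectionModel}.
#' @param anc1,anc2 integer vectors of ancestries (0 or 1), one entry per
#'   selected site in model order.
#' @return Positive scalar fitness.
#' @examples
#' mod <- SelectionModel(0.2, 100, 1,
#'                       sites = data.frame(position = 0.5, s = 0.1, h = 0.5))
#' genotypeFitness(mod, 1, 0)  # heterozygote: 1 - 0.05
#' @export
genotypeFitness <- function(model, anc1, anc2) {
  sites <- selectedSites(model)
  n <- nrow(sites)
  if (length(anc1) != n || length(anc2) != n)
    stop("ancestry vectors must have one entry per selected site (", n, ")")
  if (any(!anc1 %in% 0:1) || any(!anc2 %in% 0:1))
    stop("ancestries must be 0 or 1")
  if (n == 0) return(1)
  d0 <- (anc1 == 0) + (anc2 == 0)
  w <- ifelse(d0 == 2, 1, ifelse(d0 == 1, 1 - sites$h * sites$s, 1 - sites$s))
  prod(w)
}

#' Deterministic one-locus selection recursion
#'
#' Iterates the standard deterministic allele-frequency recursion
#' p' = (p^2 + p(1-p)(1-hs)) / wbar, with
#' wbar = p^2 + 2p(1-p)(1-hs) + (1-p)^2(1-s), for t generations. This is the
#' marginal dynamic of the haplotype machinery at a single selected position
#' and serves as its oracle.
#'
#' @param p0 initial ancestry-0 frequency in [0, 1].
#' @param s,h selection and dominance coefficients.
#' @param t number of generations (>= 0).
#' @return Numeric vector of length t + 1: the trajectory p_0 ... p_t.
#' @export
oneLocusTrajectory <- function(p0, s, h, t) {
  stopifnot(p0 >= 0, p0 <= 1, t >= 0, 1 - s > 0, 1 - h * s > 0)
  p <- numeric(t + 1)
  p[1] <- p0
  for (g in seq_len(t)) {
    q <- p[g]
    w11 <- 1
    w10 <- 1 - h * s
    w00 <- 1 - s
    wbar <- q^2 * w11 + 2 * q * (1 - q) * w10 + (1 - q)^2 * w00
    p[g + 1] <- (q^2 * w11 + q * (1 - q) * w10) / wbar
  }
  p
}
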