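---
title: "Inferring multi-locus selection from local ancestry in admixed populations"
author: "admixsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multi-locus selection from local ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixsel)
```

## The problem

When two diverged populations mix in a single pulse, the admixed population
carries chromosomes that are mosaics of the two ancestries. Natural
selection on alleles contributed by one ancestry distorts the local
ancestry landscape around the selected sites: favored ancestry rises in
frequency, and linked neutral regions hitchhike with it, so ancestry tracts
are longer and ancestry proportions higher near selected positions. When
*several* selected sites sit on the same chromosome, their dynamics
interact through linkage, and single-site methods systematically
overestimate both the number of selected sites and their selection
coefficients. `admixsel` models an arbitrary set of linked selected sites
jointly, computes the expected ancestry transition structure along the
chromosome under that model, evaluates the model's likelihood on read or
genotype data with a hidden Markov model (HMM), and selects the number,
positions and selection coefficients of sites by an iterative,
simulation-calibrated likelihood-ratio procedure.

## The model

A single admixture pulse happens `t` generations before sampling:
a fraction `m` of founders carry ancestry 0, the rest ancestry 1. Each
selected site `i` has a genetic position (Morgans), a selection coefficient
`s` and a dominance coefficient `h`; diploid genotype fitnesses at the site
are 1, `1 - h*s`, `1 - s` for 2, 1, 0 copies of ancestry 0. In this
parameterization `h` is the dominance of the *disfavored* ancestry:
`h = 0.5` is additive, `h = 0` gives the favored allele a fully dominant
benefit (heterozygote fitness 1), and `h = 1` makes it recessive. Fitness
combines multiplicatively across sites (no epistasis). Positive `s` favors
ancestry 0; selection favoring ancestry 1 is expressed by a negative `s`
(flagged in fitted output), keeping one signed parameter per site. The
admixed population is treated as infinite — genetic drift is not modeled —
and mating is random with no segregation distortion.

### Expected haplotype dynamics

For a pair of adjacent ancestry-informative markers with `n` selected sites
in reach, the package tracks all `2^(n+2)` ancestry haplotypes over the
`n + 2` positions (markers are treated as neutral, `s = 0`). The
distribution starts with only the two unadmixed haplotypes (frequencies `m`
and `1 - m`) and is iterated once per generation: random mating turns the
haplotype vector `H` into a diploid distribution `D` by a tensor product;
the diploid-to-haploid transform `M` folds in selection and recombination
to produce the next generation's gametes; the result is renormalized by the
population mean fitness. `M` is built once per window: the diploid genotype
`(a, b)` with fitness `S` contributes `S * r_j` to each of the two
recombinant haplotypes for a crossover in interval `j` (rate `r_j`,
Morgans), and — a point the construction is explicit about — `S * (1 -
sum(r))` to each parental haplotype for the meioses without a crossover in
the window. Without that complementary term the relative weighting of
genotypes with different fitness would be wrong before normalization; with
it, every row of `M` sums to exactly `2 * S`, which the test suite asserts.

This is a *single-crossover* model: interval rates are used directly as
crossover probabilities, at most one crossover per tracked window per
meiosis, and `sum(r) < 1` is required. This is accurate for the short
windows that arise in practice (a few centimorgans); double crossovers
within a window are ignored. Under neutrality the model reproduces the
junction closed form exactly: the probability that no ancestry junction
separates two positions at distance `d` after `t` generations is
`(1 - d)^t`, which is also the closed form used for intervals out of reach
of every selected site.

After `t` generations the marker-to-marker ancestry transition matrix is
read off the haplotype distribution by marginalizing over the selected-site
bits and dividing by the left-marker marginals. Two speed-ups keep
chromosome-scale computation cheap, both adjustable: a selected site enters
an interval's window only if it lies within a radius `R` of the interval
(default 2 cM) — small radii bias strong-selection fits upward, so `R`
should be increased when `s` is large — and within each contiguous run of
selection-influenced intervals only every `k`-th window is evolved
numerically (default 4), neighboring intervals reusing the nearest
computed matrix. The reuse semantics were chosen over merging intervals
(i.e. thinning the marker set itself) after both were implemented and
compared: merging discards the emissions of the dropped markers, which
measurably destabilizes the attribution of selection between nearby sites,
whereas reuse keeps every marker's data and only approximates transition
matrices that vary smoothly on the sub-centimorgan scale between adjacent
intervals (a matrix is never reused across more than 0.2 cM, so sparse
marker sets fall back to exact per-interval computation automatically). This also matches the observation that moderate `k` barely
affects fitted coefficients. `k = 1` (every window evolved exactly) is
used for final reported fits and decoding.

### Emissions and the HMM

Hidden states are the ancestry-0 dosage (0, 1, 2) of each unphased diploid
sample; the two chromosomes transition independently. The chain starts
from the pulse prior `((1-m)^2, 2m(1-m), m^2)`. Emission probabilities are
a deliberately simple, swappable model: panel allele frequencies are
estimated with 0.5 pseudo-counts; given dosage `z`, each chromosome carries
the A allele with its ancestry's frequency; the three allelic genotypes
are marginalized; and reads are binomial draws with per-read error
`eps` (default 0.01). Genotype observations use a symmetric genotyping
error `gamma` (default 0.01). This ignores finite-panel
(without-replacement) corrections used by full local-ancestry callers; for
the moderately sized panels simulated here the difference is small, and the
emission interface is a single function that can be replaced. The forward
recursion is run with per-marker scaling (not in log space), which is
numerically safe for a three-state chain, and per-sample log-likelihoods
add up. Posterior decoding runs forward-backward with all sites folded in
(`radius = Inf`, `k = 1`); because the transition cost is exponential in
the number of sites per window, decoding refuses models with more than 6
sites unless asked to split the chromosome at the largest inter-site gaps.

## Optimization

All fits maximize the forward log-likelihood with a Nelder-Mead simplex
(reflection 1, contraction 0.5, expansion 2, shrinkage 0.5) run in two
stages: stage 1 centers simplexes on the supplied start, stage 2 on the
stage-1 optimum. A search stops when the simplex's log-likelihood range
falls below 5 *and* below a quarter of its initial range (stage 1), below
0.1 *and* a twentieth (stage 2), or after four consecutive shrink steps.
The number of starts per stage is not prescribed anywhere authoritative,
so the defaults here — stage 1 uses simplex edge lengths 0.5, 0.25, 0.1 in
transformed coordinates with deterministic sign-flipped orientations,
stage 2 uses 0.1 and 0.02 — are configurable via `simplexConfig()`.
Bounded parameters are transformed so the simplex is unconstrained: `s` by
a logit on (-0.95, 0.95), `h` on (0, 1), positions on (0, L), and `t` on a
log scale with per-evaluation rounding to an integer (the recursion is
per-generation, so fractional `t` has no meaning). Vertex ties are broken
by insertion order, making every fit bit-reproducible.

## Model selection

A single-site scan (additive site, position fixed at each grid marker)
produces a likelihood-ratio profile; local maxima over a marker window that
exceed an LLR threshold become candidates (defaults 1400 markers and 15,
matching dense insect-scale data; sparser data warrant e.g. 300 and 40).
Candidates are tested in decreasing LLR order. Because the infinite-
population assumption and read resampling inflate likelihood ratios beyond
the asymptotic chi-squared expectation, each test is calibrated by
simulation: populations are simulated under the current null model at a
finite calibration size (default N = 10,000, a deliberately conservative
choice for large natural populations), reads are resampled at the data's
markers, and both models are refit on each replicate. A candidate is
accepted when its data LLR exceeds the 95th percentile (nearest-rank, so
the maximum of the default 20 replicates) of the simulated null LLRs; the
accepted model becomes the next null. Rejected candidates are not
revisited — the procedure is a single prioritized pass. An optional
refinement pass re-optimizes each accepted site's (position, s) in turn
and then all coefficients jointly.

## The simulator

Validation runs entirely on synthetic data from a tract-based forward
Wright-Fisher simulator: N diploids, round(mN) pure ancestry-0 founders,
fitness-proportional parent sampling, and meiosis with Poisson(L)
crossovers placed uniformly (no interference). Chromosomes are tract lists,
so memory and time scale with the number of junctions, not with marker
count. Parental panels come from a Balding-Nichols model: ancestral
frequencies uniform on (0.05, 0.95), population frequencies
Beta-distributed around them with divergence parameter `F` (default 0.2,
a realistic divergence for the conspecific-population admixture scenarios
this method targets), and panel counts binomially sampled. Read sampling
draws Poisson(depth) totals and binomial allele counts with error `eps`;
genotypes at markers are independent given local ancestry, i.e. the
simulator reproduces exactly the information structure the emission model
assumes, with no background linkage disequilibrium within ancestries. That
match is intentional — it isolates the transition model, which is what the
package contributes — but it means passing validation does not exercise
robustness to within-ancestry LD or panel misspecification found in real
data. Migration after the pulse can be switched on as per-generation
replacement by unadmixed individuals (split equally between sources by
default).

## Validation design and problem sizes

The bundled tests and the acceptance script reproduce, at desk scale, the
method's key behaviors. The standard conditions are m = 0.2, N = 10,000,
75 sampled diploids at about 2x depth, and two additively selected sites
(s = 0.01) one centimorgan apart; chromosomes are 0.3 Morgans with about
2000 ascertained markers. That is still more than tenfold sparser than the
~30,000 informative sites of a typical insect chromosome arm, and the
information density of the data matters beyond statistical noise: the
*magnitude* of the systematic biases under model misspecification (scaled
maps, wrong admixture times) shrinks as markers, coverage or panel
divergence increase, because richer data weight the ancestry-level signal
(which misspecification distorts less) more heavily against the
tract-length signal. Desk-scale results therefore show somewhat larger
biases than fully dense data would. The acceptance script uses 10
replicates per experiment; the test suite reduces some replicate counts
and reuses windows at a coarser stride to stay fast:

* **Recombination-map scaling.** Fitting with the map uniformly inflated
  to 2x (deflated to 0.5x) biases fitted selection coefficients up (down):
  the model must compensate for mis-scaled recombination against the
  observed extent of hitchhiking. Two-site fits here free both position
  and `s`, as position inference is part of the fits this experiment
  mirrors.
* **Time misspecification.** With the analysis `t` set to 0.5-2x the
  truth, fitted coefficients absorb the error; the bias is large for
  recent admixture (t = 100), where `s*t` trades off directly, and much
  smaller at t = 500, where the saturating frequency trajectory and the
  tract-length structure constrain `s` independently of `t`.
* **Dominance.** Fitting an additive (h = 0.5) model to a site whose
  benefit is actually dominant (heterozygote fitness equal to the favored
  homozygote; h = 0 in this package's 1, 1-h\*s, 1-s table, where h is the
  dominance of the *disfavored* ancestry) roughly doubles the fitted
  coefficient at t = 100 and small s: at low ancestry-0 frequency
  selection acts almost entirely through heterozygotes, whose true
  advantage is s but whose modeled additive advantage is s/2.
* **Direction checks.** Power to separate two-site from one-site truth
  grows with `t` and with inter-site distance; single-site fits on
  two-site truth overestimate `s` while two-site fits do not; a third
  true site is worth far more log-likelihood than a spurious fourth; and
  discrimination collapses in small populations (N well below 2000),
  where drift violates the infinite-population assumption.

## Numerical choices and edge cases

* Haplotype vectors are renormalized every generation to prevent
  floating-point drift; all accumulation is in double precision.
* A selected site exactly on a focal marker (or on another site) is
  nudged by +1e-9 Morgans so tracked positions stay strictly increasing.
* A zero left-marker marginal in a transition (impossible under admissible
  `m`, possible in degenerate user input) is reported and replaced by an
  identity row.
* NaN objective values (e.g. inadmissible fitness combinations proposed by
  the simplex) are rejected with a penalty rather than propagated.
* The marginal ancestry frequency at a single selected site evolves
  exactly as the classical one-locus recursion; this, the junction closed
  form, a brute-force gamete enumerator, and an exhaustive-path forward
  oracle anchor the test suite.
* The HMM factorization starts from the neutral pulse prior, so with
  selection near a chromosome end the likelihood is not exactly invariant
  to reversing the marker order (the true end-marker marginal is
  hitchhiked); the discrepancy is small and tested at a loose tolerance,
  and it vanishes under neutrality.

## Known limitations

Only single-pulse demographies are modeled; recurrent migration above
roughly 5e-4 per generation confounds the inference. Drift is not modeled:
populations under about N = 2000, or very recent admixture (t below about
200) with weak selection, are outside the method's comfort zone. Epistasis
is not modeled — interacting pairs are fitted as independent sites with
biased coefficients. Dominance is technically estimable but poorly
identified; treat fitted `h` with caution. The emission model is a
simplification (see above). Cost is exponential in the number of sites per
tracked window, so models beyond ~6 sites must be handled with the radius
speed-up and split decoding.
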