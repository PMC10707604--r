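# admixsel

Inference of **multi-locus natural selection from local ancestry** in
admixed populations.

When two diverged populations mix in a single pulse, selection on alleles
contributed by one ancestry reshapes the local ancestry landscape around
the selected sites, and *linked* selected sites hitchhike on each other.
Methods that model one selected site at a time consequently overestimate
both the number of selected sites on a chromosome and their selection
coefficients. `admixsel` is for population geneticists who have
ancestry-informative marker data (read pileups or genotypes plus two
parental reference panels) from a single-pulse admixed population and want
to identify *how many* linked sites are under selection, *where* they are,
and *how strong* selection is at each, accounting for their interaction
through linkage.

## The model

A pulse `t` generations ago founded the population with a fraction `m` of
ancestry 0. Each selected site has genetic position (Morgans), selection
coefficient `s` and dominance `h`, with diploid fitnesses `1`, `1 - hs`,
`1 - s` for 2, 1, 0 copies of ancestry 0, multiplicative across sites.
For a pair of adjacent markers with `n` selected sites in reach, the
expected distribution over the `2^(n+2)` ancestry haplotypes is evolved
deterministically (infinite population): with `H^g` the haplotype
frequency vector,

    D^g   = H^g (x) H^g                  (random mating)
    H'^{g+1} = D^g M                     (selection + recombination)
    H^{g+1}  = H'^{g+1} / sum(H'^{g+1})  (normalization)

where the diploid-to-haploid transform `M` adds, for diploid `(a, b)` with
fitness `S`, `S*r_j` on the two recombinant haplotypes of a crossover in
interval `j`, and `S*(1 - sum r)` on each parental haplotype. Ancestry
transition probabilities between the two markers are read off `H^t`; under
neutrality they reduce to the junction closed form `(1 - d)^t`. A
three-state HMM over ancestry dosage (forward algorithm, binomial read
emissions from panel allele frequencies) gives the model likelihood, which
is maximized by a two-stage Nelder-Mead scheme. The number of sites is
chosen iteratively: candidates from a single-site scan are accepted only
when their likelihood-ratio exceeds the 95th percentile of ratios refit on
populations simulated under the current null model — simulation-based
calibration, because drift and resampling inflate the ratios beyond the
asymptotic chi-squared expectation.

A tract-based forward Wright-Fisher simulator (selection, recombination,
optional migration, Balding-Nichols parental panels, Poisson read
sampling) generates all validation data.

## Worked example

Simulate a population carrying two linked selected sites and re-infer
their coefficients:

```r
library(admixsel)
set.seed(7)

truth <- SelectionModel(m = 0.2, t = 500, chromosomeLength = 0.3,
                        sites = data.frame(position = c(0.145, 0.155),
                                           s = 0.01, h = 0.5))
sim <- simulateDataset(truth, N = 10000, nMarkers = 1001,
                       nSamples = 75, depth = 2)

tmpl <- SelectionModel(0.2, 500, 0.3,
                       sites = data.frame(position = c(0.145, 0.155),
                                          s = 0.005, h = 0.5))
fit <- twoStageFit(sim$data, tmpl, free = "s")
fit
```

```
FitResult: loglik = -60258.098 (133 evaluations, converged)
SelectionModel: m = 0.2, t = 500, L = 0.3 M, N = Inf
  2 selected site(s):
  position       s   h
1    0.145 0.01555 0.5
2    0.155 0.01000 0.5
```

The coefficients land around the simulated `s = 0.01` (the first is high
in this replicate — estimates at one-centimorgan spacing carry
substantial sampling noise). A single-site fit to the same data
(`free = c("s", "position")`) converges to `s = 0.032` at position 0.148,
between the two true sites: absorbing both signals into one site roughly
sums their coefficients, the overestimation that motivates joint
multi-locus modeling. `expectedLocalAncestry(fit@model, grid)` returns the
model's ancestry curve, `posteriorDecode()` per-sample ancestry dosage
posteriors, and `singleSiteScan()` + `findPeaks()` + `iterativeSelection()`
run the full model-selection pipeline. A command-line wrapper with
`simulate`, `scan`, `select`, `fit`, `decode`, `curve` and `transitions`
subcommands is installed at
`system.file("cli", "admixsel.R", package = "admixsel")`.

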