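---
title: "Inferring consanguinity from runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring consanguinity from runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
library(data.table)
```

## The problem

Offspring of related parents carry long *autozygous* tracts: stretches of the
genome where both haplotypes descend from the same recent common ancestor and
are therefore identical by descent. These tracts are observable as runs of
homozygosity (ROH) in genotype data. In populations with both consanguinity
(close parental kinship) and endogamy (within-group mating over many
generations) the two processes leave different footprints: consanguinity
produces few, very long tracts, while endogamy produces many short ones.
`autozyg` separates them by working only with the longest ROHs, and quantifies
their population-level consequence — an excess of rare homozygous genotypes
over random-mating expectations.

The package has three parts: a generative simulator of autozygous segment
distributions at a given degree of parental relatedness, a summary-likelihood
classifier that assigns each individual a degree of inbreeding, and an
observed/expected rare-homozygote statistic stratified by minor allele
frequency (MAF) and inbreeding class. A synthetic cohort generator makes the
whole pipeline testable without any external data.

## The block-inheritance model

We model an autosome's ancestry as a sequence of blocks. For an individual
whose parents are related through an inheritance path with $G$ total
generations back to the shared ancestors (summed over both parental paths),
block genetic lengths are i.i.d. Exponential with mean $100/G$ cM, and each
block is independently autozygous with probability $F$, the pedigree
inbreeding coefficient. For offspring of first cousins there are 8 possible
ancestral chromosomes on each parental side three generations back, of which
4 are shared; of the $8 \times 8 = 64$ joint inheritance patterns, 4 produce
autozygosity, so $F = 4/64 = 6.25\%$ and $G = 6$.
`first_cousin_autozygosity_enumeration()` performs this enumeration
explicitly and is used as an independent check of the parameter table.

The full degree table (`consanguinity_degrees()`) generalizes this by
standard pedigree theory:

| degree | relationship            | $G$ | $F$   |
|--------|-------------------------|-----|-------|
| 2      | avuncular               | 5   | 1/8   |
| 3      | first cousins           | 6   | 1/16  |
| 4      | first cousins once rem. | 7   | 1/32  |
| 5      | second cousins          | 8   | 1/64  |
| 6      | half second cousins     | 8   | 1/128 |

$F$ halves with each added degree. Only degree 3 has both parameters pinned
by the worked first-cousin argument above; the remaining rows follow from
counting path generations and shared ancestors the same way, and the table is
an ordinary data frame that callers can replace (any list with `G` and `F`
elements is accepted wherever a degree is expected, which is also how the
degenerate test degrees $F=0$ and $F=1$ are expressed).

Simulation choices worth stating:

* **Adjacent autozygous blocks are merged** before anything is measured.
  Observed ROHs are maximal runs; two abutting autozygous blocks are
  indistinguishable in data, so the simulated objects must be maximal too.
* **The last block is truncated** at the chromosome end — no wraparound, no
  rejection sampling.
* **No crossover interference**: block lengths are exactly exponential. This
  is the standard renewal approximation and is what makes the model tractable.
* **Autosomes only.** The default chromosome-length table
  (`default_chrom_lengths()`) holds rounded sex-averaged genetic lengths of
  the 22 human autosomes (about 35.4 Morgans in total). These are literature
  approximations, not map-derived values; any named vector of positive cM
  lengths can be supplied instead, and reference distributions refuse to mix
  with queries built on a different table.

## Reference distributions and the classifier

Each individual is reduced to two summaries computed from its filtered ROH
calls: $N_{10}$, the number of ROHs *strictly longer* than 10 cM, and
$S_{10}$, the summed genetic length of the 10 longest ROHs (all of them when
fewer than 10 exist — the statistic must be defined for outbred genomes).
Restricting attention to the longest ROHs is what gives the method its
robustness to endogamy: background tracts of 1–3 cM barely move either
summary.

ROH calls are consumed from PLINK `.hom` files, converted to genetic lengths
by piecewise-linear interpolation on a user-supplied genetic map
(`interpolate_cM()` clamps positions outside the anchored range to the
terminal anchors), and filtered to a minimum physical length of 500 kb *and*
a minimum genetic length of 1 cM. The 10 cM count threshold is strict
(`> 10`), the 1 cM retention threshold is inclusive (`>= 1`); the same
reduction — including the 1 cM floor — is applied to simulated segments, so
reference and observation are always on the same scale.

`build_reference()` simulates many genomes at one degree (2,000,000 by
default, matching the scale at which the empirical distributions become
smooth) and stores the per-replicate $(N_{10}, S_{10})$ pairs. The
likelihood of an observation under a reference is simply the fraction of
replicates with the same $N_{10}$ and with $S_{10}$ within a relative window
of $\pm 1\%$ — matching $N_{10}$ exactly and windowing only $S_{10}$ is our
reading of a count statistic versus a continuous one. `classify_inbreeding()`
assigns the argmax degree across references for degrees 2–6, reporting degree
6 as `"unrelated"`: half second cousins are the most distant relationship the
summaries can resolve, so sixth-degree serves as the outbred proxy rather
than a separate generative model of complete outbreeding.

Two deterministic rules close the gaps the likelihood itself leaves open:

* **Ties break toward the more distant degree.** This is conservative
  against over-calling consanguinity.
* **Zero-likelihood fallback.** If an observation sits outside all five
  empirical supports, the $S_{10}$ window is doubled and the evaluation
  repeated; from the third widening onward the $N_{10}$ match is also relaxed
  to a growing $\pm k$ window, so the schedule provably terminates. When the
  observed $S_{10}$ is zero a relative window never grows, so widening step
  $k$ instead accepts references with $S_{10} \le 0.01 \cdot 2^k \times 100$
  cM. The tolerance at which a positive likelihood first appeared is recorded
  in the output (`tolerance_used`), so widened calls are auditable.

`stratify_calls()` maps labels to the three analysis strata: `inbred`
(second or third degree — parents first cousins or closer), `outbred`
(`unrelated`), `intermediate` (fourth and fifth).

## Rare-homozygote excess

For each variant, within the analyzed sample subset, we count the minor
allele ($c$ copies among $2n$ called alleles) and the minor-allele
homozygotes, then compare the observed homozygote total in each MAF bin with
its random-mating expectation. Two estimators of the per-variant expectation
are available:

* `pairing` (default): $n\,c(c-1)\,/\,(2n(2n-1))$ — the expectation under
  random union of the $2n$ *observed* gametes without replacement. It is
  exact for the finite sample and correctly gives zero for singletons.
* `p2`: the plug-in $n (c/2n)^2$. It is biased upward for rare variants
  (it lets a lone allele pair with itself), which matters precisely in the
  rarest bins where the excess signal lives; it is retained because it is the
  textbook form and the difference between the two is itself informative.

MAF is always recomputed within the subset being analyzed (population or
inbreeding stratum), the default bins are half-decade edges from 0.0005 to
0.05 with an open top bin to 0.5, variants below a 70% within-stratum call
rate are dropped, and bins whose summed expectation is zero are reported as
undefined (`NA`) rather than zero. Under Hardy–Weinberg equilibrium the
observed/expected ratio is 1 in every bin; consanguinity inflates it, more
strongly at rarer MAF, and inbred strata show systematically higher ratios
than outbred strata — the package's property tests assert exactly these
patterns on synthetic cohorts.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` produce a fully self-contained cohort:
per individual a parental-relatedness category is drawn from a mixture;
autozygous loop tracts come from the block simulator; short background tracts
(Poisson count per genome, lengths uniform on 1–3 cM) crudely mimic endogamy;
genotypes are drawn under HWE from each site's frequency outside tracts and
as a single doubled allele inside tracts; physical coordinates come from a
constant 1 Mb/cM embedding. Defaults: 100 individuals, 20,000 variants with
log-uniform frequencies on $[5\times10^{-4}, 0.5]$ (enriching the rare
variants the excess statistic needs), background rate 2 tracts per genome,
and a mixture (55% unrelated, 25% first cousins or closer) emulating a
strongly consanguineous population of the kind the method was designed for.
A 0.5 cM emission floor models the detectability limit of ROH calling:
shorter tracts are real autozygosity but produce no `.hom` record.

What the generator deliberately does **not** emulate: linkage disequilibrium,
genotyping error, variant-calling artifacts, sex chromosomes, and sex- or
position-dependent recombination. Passing tests therefore demonstrate the
statistical machinery is correct under the model's own assumptions, not that
real cohorts will behave identically; in particular the constant bp-per-cM
embedding makes physical and genetic filters redundant in a way real maps
are not (supplying a non-constant map exercises the interpolation honestly).

## Numerical and testing choices

Identical spec and seed give identical cohorts; references record their seed,
parameters and length table in a JSON sidecar and `classify_inbreeding()`
refuses references built on different tables. The vectorised simulator and a
deliberately naive reimplementation (sample blocks one at a time, label,
scan-merge) are compared by a two-sample Kolmogorov–Smirnov test on $S_{10}$
in the test suite.

The test and example problem sizes are chosen for desk-scale runs:
reference distributions at $2\times10^4$ replicates, recovery cohorts of
100–200 individuals, and the headline first-cousin autozygosity check at
$10^5$ genomes (its Monte-Carlo standard error is then well below 0.01
percentage points, so the 6.25% expectation is sharp). Production use should
keep the 2,000,000-replicate default for references: with $2\times10^4$
replicates the rarest $(N_{10}, S_{10})$ cells are sparsely populated and
the zero-likelihood fallback engages more often than it would at scale.

## Known limitations

* Degree 1 (incest) has no reference; such individuals will be called second
  degree. The category set starts at avuncular because that is where the
  method's intended use begins.
* The classifier is discrete by design; it does not estimate a continuous
  inbreeding coefficient, and individuals whose parents are related through
  multiple loops will be mapped to the single degree whose summary
  distribution fits best.
* The excess-ratio headline numbers reported for real populations depend on
  cohort composition and the exact expectation estimator; on synthetic data
  the package asserts the qualitative structure (ratios $\ge 1$, increasing
  toward rare MAF, inbred $>$ outbred) rather than any fixed multiplier.
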