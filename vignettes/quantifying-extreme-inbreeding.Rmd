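---
title: "Quantifying extreme inbreeding from runs of homozygosity"
author: "ROHmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extreme inbreeding from runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ROHmix)
```

## The problem

Offspring of matings between first-degree relatives (parent--offspring, PO;
full sibs, FS) or second-degree relatives (half sibs, avuncular,
grandparent--grandchild, double first cousins) carry about a quarter or an
eighth of their genome in long homozygous-by-descent (HBD) tracts. Such
extreme inbreeding (EI) is rare, sensitive to ascertain by questionnaire, but
directly visible in SNP genotypes as runs of homozygosity (ROH). The package
implements, on fully synthetic data, the quantitative machinery of an
ROH-based EI study:

* a pedigree recombination simulator with founder-origin tracking, so true
  HBD segments are known exactly;
* a sliding-window ROH caller and the genomic inbreeding coefficients
  `fROH()` (cumulative autosomal ROH length / 2881 Mb), `fROHX()` (X of
  females, / 155 Mb) and `fUNI()` (correlation between uniting gametes);
* threshold classification of EI and mating type with ROC/AUC machinery and
  prevalence arithmetic;
* shifted exponential mixture modelling of segment lengths with BIC model
  selection;
* a maximum-likelihood deconvolution of the proportion of ROH segments
  attributable to PO versus FS mating; and
* inbreeding-depression statistics (covariate-adjusted linear models,
  overdispersed Poisson regression, inbreeding load, extrapolated effects and
  a linearity test) on synthetic phenotypes.

## The synthetic genome

`makeGeneticMap()` builds 22 autosomes whose per-chromosome physical and
genetic lengths follow embedded constants approximating the human genome,
rescaled so the totals are exactly 2881 Mb and 35.9 Morgans. Only these
totals drive the reproduced statistics (segment counts and lengths, F
denominators); per-chromosome detail matters only through the number of
chromosome ends that truncate segments.

Local recombination rates are piecewise constant on 1 Mb tiles. Rate
heterogeneity is modelled by Gamma multipliers with mean 1 and coefficient of
variation `heterogeneity` (default 1), drawn per 30 Mb block
(`rateBlockMb`) rather than per tile. The block structure is deliberate:
segment lengths average local rates over their own span, so independent
per-tile multipliers wash out at the 10--30 Mb scale of HBD segments and the
length distribution collapses to a single exponential. Broad regional rate
variation -- the realistic regime, where chromosome arms and subtelomeric
regions differ severalfold -- is what makes segment lengths a *mixture* of
exponentials, and with the default settings BIC selects two components with
weights and rates close to the values the simulation experiments report. With
`heterogeneity = 0` the map is uniform and single-chromosome segment lengths
are approximately exponential, in which case BIC prefers one component; this
contrast is asserted in the test suite.

`makeSnpPanel()` samples SNP positions uniformly (Poisson counts per
chromosome, default density 301,412 / 2881 Mb, emulating a genotyping array
after quality control) and assigns allele frequencies with minor-allele
frequency uniform on [0.05, 0.5], matching a MAF > 5% filter. Uniform SNP
spacing is an assumption; real arrays cluster SNPs, which would mainly affect
the caller's density and gap rules on toy inputs, not the headline
statistics.

## Meiosis and pedigrees

`sampleGamete()` implements recombination exactly as the Bernoulli scheme:
each map interval independently hosts a breakpoint with probability
min(1, interval length in Morgans) (a 2 cM interval therefore recombines
with probability 0.02), the breakpoint position is uniform within the
interval, and each chromosome starts from a fair-coin haplotype. There is no
crossover interference and no obligate chiasma. The per-interval cap at 1
never binds on the default 1 Mb tiles.

`simulateMating()` runs the eight pedigrees (PO, FS, HS, AV, GP, DC, FC,
UN) from founders drawn out of a `FounderPanel`. PO follows the two-step
construction: a child of two founders is simulated first and then mated back
to one of its parents, chosen at random. True HBD is defined as identity of
founder-haplotype labels between the two inherited chromosomes
(`trueHbdSegments()`), i.e. autozygosity within the simulated pedigree;
background sharing between founders deliberately does not count as true HBD.
No length filter is applied to HBD segments.

The expected number of HBD segments has a closed form under this model:
summing over inbreeding loops, E[N] = F (m L + C) with F the loop's
inbreeding contribution, m the number of meioses in the loop, L the map
length in Morgans and C = 22 chromosomes. With L = 35.9 this gives 32.4 (PO),
41.4 (FS) and 14.8 (FC) segments, which the simulator matches within Monte
Carlo error; the test suite uses this closed form as an independent oracle.

`injectGenotypingErrors()` perturbs a Poisson(rate x SNPs) number of
genotypes per chromosome, replacing each by a uniformly chosen different
dosage. The default overall rate, 4.5e-4, is typical of array genotyping
at quality-controlled SNPs; the replacement rule is a symmetric choice the
data do not constrain, and it is configurable.

## Background relatedness

Real "unrelated" individuals still share distant ancestry, so their
offspring carry a few ROHs > 1.5 Mb. `makeFounders(background =
"calibrated")` emulates this by making each founder haplotype a mosaic of a
small pool of ancestral haplotypes: tract breakpoints are laid down at 25
meioses' worth of recombination density and each tract takes a random
ancestral label from a pool of `poolSize` haplotypes. Two founders then share
tracts of a few cM wherever their mosaics coincide. The pool size is the
calibration constant: the default (100) was fixed by a sweep so that
offspring of random founder pairs average about 4.8 detectable ROHs,
the empirically observed background level; `makeFounders(verify = TRUE)`
re-checks this and fails outside [3.8, 5.8].

The approximation is intentionally minimal. All shared tracts descend from a
single 25-generation-deep pool, so tract ages (hence lengths) are more
homogeneous than under a realistic coalescent, and founder haplotypes carry
no linkage disequilibrium. This matters mostly for statistics driven by the
background ROH count distribution -- the N_ROH-based PO/FS discrimination is
the sensitive one -- and is a known limitation: passing tests show the
machinery behaves correctly under these stated conditions, not that the
background model captures real population structure.

## ROH calling

`callROH()` re-implements the classic sliding-window scan. A window of 50
consecutive SNPs is "homozygous" if it contains at most 1 heterozygous and
at most 5 missing calls; a SNP qualifies if at least 5% of the windows
spanning it are homozygous (the window-hit threshold is the conventional tool
default, the only parameter the standard command line does not pin down);
maximal runs of qualifying SNPs are reported when they span >= 1500 kb and
>= 50 SNPs, contain no gap > 1000 kb, and average <= 50 kb per SNP. Segment
boundaries are the first and last qualifying SNP positions and lengths are
end - start + 1 bp. Missing genotypes never break a run by themselves; they
only count against the window missing limit. On small inputs the caller is
checked segment-for-segment against an exhaustive reference that enumerates
every window and every run constraint directly.

Raising the minimum length (1500 to 2000 to 5000 kb) can only remove
segments, so N_ROH and F_ROH are non-increasing in that parameter -- the
direction the sensitivity analyses rely on.

## Classification and deconvolution

`classifyMating()` applies strict thresholds: EI when F_ROH > 0.1 (the
clinical consanguinity threshold), MT1 when F_ROH > 0.17, and, within MT1,
PO when N_ROH <= 41. The direction of the count rule is a package decision:
PO offspring carry fewer, longer ROHs than FS offspring (three meioses in
the inbreeding loop instead of four), so low counts indicate PO; a strict
`<` variant is available. `rocAuc()` computes the Mann--Whitney rank AUC
(ties share 1/2), the full empirical ROC curve, and the Youden-optimal
operating point; the trapezoidal area under the curve equals the rank AUC to
numerical precision, which the tests assert, with an independent
cross-check against another ROC implementation.

`prevalenceCI()` uses the normal-approximation (Wald) interval by default --
the form that reproduces the printed reciprocal bounds -- with an exact
Clopper--Pearson option. `normalTailProb()` supplies the Gaussian upper-tail
checks (e.g. the probability that first-cousin offspring exceed F_ROH = 0.1
given mean 0.0625 and SD 0.024).

For PO-versus-FS deconvolution, the length density of ROH segments is
modelled as pi f_PO + (1 - pi) f_FS with both reference densities known
two-component shifted exponential mixtures. `estimatePi()` maximizes the
log-likelihood over [0, 1] by bounded univariate optimization (the profile
is concave for such references) and computes the asymptotic standard error
from the one-parameter Fisher information, approximating the expectation by
Monte Carlo draws from the fitted mixture (1e6 by default, plug-in pi-hat);
the confidence interval is pi +/- z se truncated to [0, 1].
`referenceDensities()` ships frozen reference constants estimated from large
mating-type simulations; `fitReferenceDensities()` re-fits them from this
package's own simulations, which is the self-consistent default for synthetic
experiments since the frozen constants originate from simulations on real
haplotypes that this package does not reproduce. `assignMatingGroups()`
labels individuals PO-like (Group2) or FS-like (Group1) by the sign of their
total log-likelihood ratio; exact ties are left unassigned. The X chromosome
provides an orthogonal check (`simulateXFroh()`): only female meioses
recombine the X, so F_ROH-X has expectation 0.5 for daughters of
father--daughter matings versus 0.25 under brother--sister matings.

## Mixture fitting

Because only segments longer than the detection threshold s = 1.5 Mb are
observed, and the truncated tail of an exponential minus s is exponential
with the same rate, `fitExpMixture()` models lengths - s as a K-component
exponential mixture. EM is initialized by a quantile split of log-lengths
plus 5 random-assignment restarts (best likelihood kept); the E/M updates
keep the log-likelihood non-decreasing, convergence is a relative
log-likelihood change below 1e-8 (at most 2000 iterations; non-convergence
is flagged, not raised), component weights are floored at 1e-4 with a
"collapsed" flag, and all-equal input lengths flag a K > 1 fit as
non-identifiable. BIC uses 2K - 1 free parameters (K rates, K - 1 weights);
`selectExpMixtureK()` scans K = 1..10 by default. Components are reported in
decreasing-mean order. A shifted-gamma fit is available purely as a
comparison (`gammaComparisonBIC()`); it is not a supported model.

## Inbreeding depression on synthetic phenotypes

`simulatePhenotypes()` plants a linear decline of quantitative traits in F
(default per-unit-F slopes spanning -3.9 to -1.0 trait SD across ten
traits), generic covariates (two continuous, one categorical, ten structure
components), and an overdispersed count trait with log-mean mu0 - B F
(gamma--Poisson with size 5, i.e. dispersion well above 1 at the default
mean; the planted inbreeding load defaults to B = 1.46).
`fitInbreedingLm()` and `fitInbreedingQuasiPoisson()` wrap ordinary least
squares and quasi-Poisson IRLS (dispersion = Pearson chi-square / df), with
collinearity reported by column name. `extrapolateEffect()` divides a
case--control effect by the F contrast between cases and controls
(approximately 0.169 for EI cases versus controls), and `linearityTest()`
compares the observed case mean with the linear prediction from
control-estimated depression, combining both standard errors in a Wald z.
Trait pre-adjustment follows the fixed order: residualize on covariates,
rank inverse-normal transform, then exclude |z| > 4.

## Numerical choices

* Coordinates: 1-based inclusive SNP positions; segments half-open in bp
  internally, exported as 1-based closed `GRanges`; lengths in Mb.
* The meiosis engine works on a concatenated genome coordinate. Chromosome
  starts and ends are taken from one shared cumulative vector so that phase
  switches land bitwise-exactly on chromosome boundaries; segment tilings
  always retain chromosome-end boundaries and nothing merges across them.
* The first chromosome's starting-haplotype coin flips the base parity
  instead of inserting a switch at coordinate 0, avoiding zero-width
  segments.
* Ties: classification thresholds are strict (`>`), as printed; the PO
  count rule defaults to `<=` with a strict option; likelihood ties in group
  assignment return NA.
* Problem sizes: the test suite reproduces segment-count means from 3000
  replicates per mating type and classification AUCs from 400 genotype-level
  replicates per mating type; `scripts/acceptance.R` uses 19,000 and 500.
  These sizes keep Monte Carlo error comfortably inside the stated
  tolerances (segment-count SE ~0.1 at n = 3000; AUC SE ~0.007 at n = 400
  per class).

## Known limitations

* Founder haplotypes carry no linkage disequilibrium and the background
  model gives shared tracts a single age class; count-based statistics that
  depend on the fine structure of background ROHs transfer only
  approximately to real cohorts.
* No crossover interference, mutation or gene conversion; sex-specific maps
  exist only as the female-only X model.
* The ROH caller follows the window semantics described above; real
  implementations differ in end-trimming details, which shifts segment
  boundaries by a few SNPs.
* Phenotypes are generated under exactly the linear directional-dominance
  model the depression statistics assume; passing recovery tests validates
  the estimators, not the biology.
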