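---
title: "Tetrad analysis of meiotic crossover control: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis of meiotic crossover control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradkit)
```

## The analysis problem

In budding yeast, the four haploid spores of one meiosis can be dissected
and genotyped individually. For a pair of linked markers each tetrad falls
into one of three classes: **parental ditype** (PD — all four spores carry a
parental marker combination), **tetratype** (TT — two parental, two
recombinant) and **non-parental ditype** (NPD — all four recombinant, which
requires a double crossover involving all four chromatids). These counts
support a remarkably rich set of inferences about crossover *frequency*
(map distance), crossover *interference* (the even spacing of crossovers)
and crossover *assurance* (the guarantee that every homolog pair obtains at
least one crossover). tetradkit implements this toolkit, the strain-level
phenotyping that accompanies it (spore viability, meiosis I nondisjunction
detected through disomic spores, gene conversion), the ratio arithmetic
used for quantified recombination intermediates, and a forward meiosis
simulator that serves as the test bed for every estimator.

## Estimators

### Perkins map distance

For an interval with counts (PD, NPD, TT) and $n = PD + NPD + TT$:

$$ \mathrm{cM} = \frac{100\,(6\,\mathrm{NPD} + \mathrm{TT})}{2n} $$

The TT term counts single crossovers; the $6\,\mathrm{NPD}$ term corrects
for double crossovers (an NPD implies, on average, two crossovers in the
interval and signals the two-, three- and four-strand doubles that produce
PDs and TTs as well). The algebraically identical form
$100\,(\mathrm{TT}/2 + 3\,\mathrm{NPD})/n$ is asserted equal in the test
suite. The standard error is the multinomial delta-method value: writing
the estimate as $50\,(6 p_{NPD} + p_{TT})$,

$$ \mathrm{se} = \sqrt{\tfrac{1}{n}\left(50^2 p_{TT} + 300^2 p_{NPD} -
\mathrm{cM}^2\right)}, $$

cross-checked in the tests against a 10,000-replicate multinomial
bootstrap (agreement within 5% relative).

Only tetrads with four viable spores and 2:2 segregation at every map
marker contribute under the default `"paper"` filter policy of
`tally_intervals()` — the classical filter for map distances. A
`"lenient"` per-interval policy and an unfiltered `"none"` policy are
also exposed, because conversion scoring deliberately uses non-Mendelian
tetrads that map estimation excludes. Whether the Mendelian filter should
be chromosome-wide or per interval is genuinely ambiguous in practice;
chromosome-wide is the default here, per-interval remains available.

### NPD ratio (single-interval interference)

Under no interference (and no chromatid interference) the expected NPD
frequency given the observed tetratype frequency $f_T$ is Papazian's

$$ \mathrm{NPD}_{exp} = \tfrac{1}{2}\left[(1 - f_T) -
\left(1 - \tfrac{3 f_T}{2}\right)^{2/3}\right], $$

defined for $0 \le f_T \le 2/3$. `npd_ratio()` reports observed/expected;
values significantly below 1 indicate positive interference. Significance
is a one-sided exact binomial test of the NPD count against the expected
frequency — exact at the small NPD counts typical of real intervals. A
tetratype frequency above $2/3$ is reported as undefined with a warning
rather than clamped: it signals data inconsistency rather than a
computable expectation. No multiple-testing correction is applied across
intervals, matching per-interval reporting conventions; callers can apply
`p.adjust` to the returned column.

### Adjacent-interval interference

`adjacent_interference()` splits tetrads by their class in a reference
interval — AdjCO (TT or NPD) versus AdjPD (PD) — and computes the Perkins
distance of the neighbouring test interval within each subset. The
reported statistic is the mean of the two ratios obtained by swapping the
reference/test roles. Under independence the ratio is 1; positive
interference drives it below 1. Because the sampling distribution of a
ratio of Perkins distances is awkward, significance uses a seeded
permutation test (reference classes permuted across tetrads, preserving
both margins; default 10,000 permutations, with the one-sided p-value
computed as $(k+1)/(B+1)$), with a chi-squared test on the 2×3
AdjCO/AdjPD × PD/TT/NPD table as a distribution-free cross-check.

### Crossover classes, assurance and E0 purging

`crossover_classes()` reconstructs each tetrad's minimal crossover number
as the sum over adjacent intervals of 0 (PD), 1 (TT) or 2 (NPD), and
tabulates exchange classes E0, E1, …. This minimal reconstruction
undercounts intervals containing several crossovers; it is the standard
convention for E-class tallies and is used as such. E0 tetrads — no
detected crossover anywhere on the chromosome — are the non-exchange
class. `assurance_test()` compares the observed E0 fraction with the
Poisson expectation $e^{-\lambda}$, where $\lambda$ is the mean crossover
number per bivalent (`cM_to_mean_CO()`: total cM / 50, since each
crossover involves two of four chromatids). The test is one-sided exact
binomial, with the side chosen by the direction of departure: efficient
assurance gives fewer E0 than Poisson, assurance failure gives more.

When assurance fails, the achiasmate subpopulation contributes PD/PD
coincidences to every interval pair, diluting — and, at high enough E0
fractions, inverting — the genetic signature of interference.
`purge_nonexchange()` partitions the data into exchange and E0 subsets so
interference statistics can be recomputed on exchange tetrads only; the
test suite verifies directionally that the purged analysis detects
stronger interference than the diluted one in a forced-E0 mixture.

For crossover-class tallies, tetrads with any unscorable interval are
dropped (and counted) by default. The conversion cross-tab instead
classifies exchange status on scorable intervals, because a converted
marker makes its flanking intervals unscorable and would otherwise eject
every converted tetrad from the table.

### Phenotypes

`viability_distribution()` tallies tetrads by viable-spore count; a
preponderance of two- and zero-viable-spore tetrads is the signature of
meiosis I nondisjunction, which kills spores in pairs.
`score_disomes()` flags tetrads containing a spore that carries *both*
parental alleles at designated centromere-linked markers; fractions are
reported over genotypable tetrads (at least one scorable viable spore),
matching dissection practice. `conversion_crosstab()` counts 3:1/1:3
segregations as conversions (4:0/0:4 are reported separately as
irregular) and tests the association between conversion and exchange
status with Fisher's exact test — chosen for its validity at the small E0
× conversion cell counts.

### Molecular-ratio arithmetic

`ih_is_ratio()` converts quantified interhomolog and intersister dHJ
signals into the IH/IS ratio and the interhomolog fraction
$r/(1+r)$; censored inputs (detection limits) propagate as explicit
bounds rather than point values. `co_fraction_to_ratio()` and its inverse
convert between crossover fractions and crossover/non-crossover ratios.

`compensation_model()` operationalises the question: *how far can an
increased crossover outcome bias compensate for a loss of interhomolog
template bias, holding event numbers fixed?* With $ihf$ the interhomolog
fraction and $cof$ the crossover fraction, predicted crossover levels are
proportional to $ihf \cdot cof$, so the predicted mutant/wild-type
relative level is $(ihf_m \, cof_m)/(ihf_w \, cof_w)$. Given an observed
fold reduction, the fraction of the apparent compensation attributable to
crossover bias is computed on the log scale as

$$ \frac{\log(\mathrm{bias\ only} / \mathrm{predicted})}
        {\log(\mathrm{bias\ only} / \mathrm{observed})}, $$

where "bias only" is the fold reduction implied by the template-bias
defect alone ($ihf_w/ihf_m$). The remainder is reported as unexplained
compensation, operationally attributed to processes that change event
numbers (e.g. additional DSB formation), which the model deliberately
excludes. With the shipped example quantitation tables this attributes
roughly a third to a half of the apparent compensation to crossover bias
at the two example hotspots — a minority share at both.

## The meiosis simulator

`simulate_tetrads()` generates tetrads on a marker map under a fully
specified generative model (`sim_config()`):

| parameter | meaning | default |
|---|---|---|
| `co_model` | `"poisson"` or `"counting"` (chi-square renewal) | poisson |
| `mean_CO` | mean crossovers per bivalent per meiosis | map cM / 50 |
| `interference_m` | counting-model interference strength $m$ | 0 |
| `obligate_CO` | redraw until ≥ 1 crossover | FALSE |
| `assurance_fail_q` | probability a meiosis is forced achiasmate | 0 |
| `conversion_prob` | per-marker, per-meiosis conversion probability | 0 |
| `backup_efficiency_b` | achiasmate bivalent still disjoins correctly | 1 |
| `spore_death_rate` | independent per-spore death | 0 |
| `disome_viable` | disomic spores survive | TRUE |

The counting model implements crossovers as every $(m+1)$-th event of a
Poisson process on the genetic scale, sampled stationarily by random
phase; $m = 0$ reduces exactly to the Poisson model (asserted by a
two-sample test in the suite) and increasing $m$ strictly decreases the
variance/mean ratio of the crossover count. The counting model was chosen
as the generative interference model because it is the standard renewal
formulation consistent with qualitative interference observations; no
interference parameter is *fitted* anywhere in the package — $m$ is a
simulation knob only. Obligate crossing-over is implemented by rejection
(zero truncation), preserving the count distribution above zero.

Chromatid choice deserves a note. Each crossover, applied in
left-to-right order, joins one chromatid of each homolog chosen uniformly
and independently (no chromatid interference). Crucially, *homolog
identity at a crossover position is the strand's local DNA parentage*:
after an earlier exchange, which strands are sisters changes distal to
that exchange. Choosing strands by centromere parentage instead couples
the tetrad classes of adjacent intervals and manufactures spurious
positive interference; with local parentage, adjacent-interval classes
under the Poisson model are independent, as they must be, and the
marginal tetratype frequency follows the closed form
$f_T = \tfrac{2}{3}(1 - e^{-3y/2})$ for an interval with mean crossover
count $y$ (verified against simulation in the tests, together with the
analogous NPD series).

Assurance failure is modelled as a mixture: with probability $q$ a
meiosis is forced achiasmate, modelling stochastic failure of homolog
engagement upstream of crossover formation. Only achiasmate bivalents can
nondisjoin (probability $1-b$), following the view that exchange
chromosomes are segregated correctly and non-exchange chromosomes depend
on a back-up system; nondisjunction produces two disomic spores (BOTH at
every marker) and two dead nullisomic spores. Disomic spores are viable
by default, reflecting tolerated chromosome III disomy — that viability is
what makes the centromere-linked heteroallele assay possible at all.
Conversions are single-marker flips of one random chromatid without
co-conversion tracts; tract modelling is a documented extension point.

Every simulation returns, alongside the genotype table, a complete truth
record (crossover positions, strand choices, conversions, nondisjunction,
death draws, spore shuffle). Genotypes are *derived from the truth record*
by a deterministic replay (`tetrads_from_truth()`), so truth and emitted
genotypes are consistent by construction, and
`interval_recombinant_fraction()` computes exact interval class
frequencies from truth, bypassing genotype scoring — the independent
oracle used in estimator round-trip tests.

## The default chromosome III map

`chr3_default_map()` provides the nine-marker, eight-interval
configuration used by the analysis scripts: classical chromosome III loci
(HML, CHA1, TRP1, HIS4, CEN3, MAT, THR4, ABP1, HMR) with plausible
round-number spacings summing to 131.6 cM and the centromere at CEN3.
The marker *positions* are a modelling choice — published marker
configurations for such experiments give marker identities and total
genetic lengths, not a per-interval table — so the default map should be
read as "a realistic whole-chromosome scoring configuration", not as
measured data. All estimators take arbitrary maps.

The shipped scenario configs encode two study conditions: a reference
cohort (strong interference $m = 4$, obligate crossover, a ~0.9% residual
achiasmate fraction of which roughly half nondisjoins, 4% spore death)
and an assurance-defective cohort ($q = 0.15$, weak interference
$m = 1$, per-engaged-meiosis mean chosen so the population map length
comes out near 117 cM, ~0.9% per-marker conversion, back-up efficiency
0.9, 29.5% spore death). These values were chosen once, from the
headline observables the conditions are meant to emulate (spore
viability near 70% and 96%, E0 fractions near 15% and 1%, disome
fractions near 1.5% and 0.4%, conversion fraction near 8%).

## What the simulator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
exchangeable tetrads, a single chromosome, interference expressible as a
stationary renewal process, conversion independent of crossover fate,
death independent of genotype. Real data violate several of these in
interesting ways — crossover rates vary along chromosomes
(hotspots/coldspots), conversions co-occur with crossovers and form
tracts, spore death is partly genotype-correlated (nondisjunction of
*other* chromosomes), and interference strength varies regionally. A
passing test suite therefore shows the estimators are correct *under the
stated model*, not that the model captures every feature of real tetrad
data.

## Numerical choices and degenerate inputs

* Genetic coordinates are cM from the left-most marker; crossover
  placement treats intervals as half-open $[left, right)$.
* All computation is at full precision; report writers round only at
  presentation (cM to one decimal, percentages as conventional).
* Estimators refuse empty tallies ($n = 0$), flag undefined ratios
  (empty subsets, zero denominators, out-of-domain $f_T$) rather than
  returning silent zeros, and `ih_is_ratio()` converts zero denominators
  into explicit bound-typed results.
* Permutation tests are seeded; reports record the seed, input hash and
  package version, and regenerate byte-identically from the same inputs.
* Problem sizes: the simulation-based properties in the test suite run at
  n = 50,000 tetrads for distributional checks and n = 2,000–6,000 for
  directional checks; the analysis scripts use n = 3,000 per cohort,
  comparable to real dissection campaigns.

## Known limitations

* **Perkins multi-crossover bias.** The Perkins correction is exact only
  through two crossovers per interval: conditional on $k$ crossovers, the
  estimator's expectation is 50, 100, but then 75 and 87.5 cM for
  $k = 1 \ldots 4$, against true values $50k$. Under an interference-free
  Poisson model this leaves long intervals (≳ 20 cM) measurably short at
  large sample sizes — about 1.9 cM at 30 cM — which is visible in the
  test suite as a deliberate, documented failure of the naive "recovers
  truth within 3 SE at n = 50,000" property for the longest interval,
  alongside a passing check that the estimate matches its analytic
  expectation. Under realistic interference the bias is much smaller
  because multi-crossover intervals are suppressed.
* Fold-change chains computed from rounded summary inputs need not
  reproduce fold changes computed from unrounded source data; the package
  computes from whatever precision the user supplies and does not force
  agreement with published rounded values.
* The minimal-crossover E-class reconstruction undercounts
  multi-crossover intervals by construction (documented convention).
* Mapping-function fits (Haldane/Kosambi) and likelihood-based
  interference estimation are out of scope; the counting model is
  generative only.
* The simulator exposes `assurance_fail_q` and `mean_CO` as independent
  knobs; it does not model a feedback law coupling engagement failure to
  extra DSB formation, since no quantitative form for such feedback is
  established.
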